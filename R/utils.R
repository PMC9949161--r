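#' @keywords internal
"_PACKAGE"

# Named sub-seed streams. Derived seeds are a pure function of (master,
# stream, index) so that e.g. adding an emitter never reshuffles the speckle
# realizations or traces of the others.
.seed_streams <- c(
  master_field = 1L, emitter_field = 2L, traces = 3L, background = 4L,
  movie_noise = 5L, nmf_init = 6L, rank_scan = 7L, ensemble = 8L,
  sweep = 9L
)

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic counter scheme: each consumer of randomness draws from its
#' own named stream so that independently seeded pieces of a simulation stay
#' independent when other pieces are added or removed.
#'
#' @param master integer master seed.
#' @param stream stream name: one of "master_field", "emitter_field",
#'   "traces", "background", "movie_noise", "nmf_init", "rank_scan",
#'   "ensemble", "sweep".
#' @param index nonnegative integer counter within the stream (e.g. emitter
#'   index).
#' @return an integer seed in `[0, 2^31)`.
#' @export
sub_seed <- function(master, stream, index = 0L) {
  sid <- .seed_streams[[match.arg(stream, names(.seed_streams))]]
  # modular arithmetic in double precision; all operands < 2^31 so the
  # products stay exactly representable below 2^53
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + sid * 69621 + as.numeric(index) * 16807) %% m
  as.integer(s)
}

# quadrant swap so that the zero-lag / DC bin sits at the center pixel
# (floor(n/2) + 1 along each axis)
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(seq(floor(h / 2) + 1L, h), seq_len(floor(h / 2)))
  ci <- c(seq(floor(w / 2) + 1L, w), seq_len(floor(w / 2)))
  m[ri, ci, drop = FALSE]
}

# center pixel convention used throughout (matches fftshift2)
center_px <- function(shape) floor(shape / 2) + 1L

# circular integer shift of a matrix: out[r, c] = m[r - dr, c - dc]
# (content moves down by dr rows and right by dc columns)
circshift2 <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  dr <- ((dr %% h) + h) %% h
  dc <- ((dc %% w) + w) %% w
  if (dr > 0) m <- m[c((h - dr + 1L):h, 1L:(h - dr)), , drop = FALSE]
  if (dc > 0) m <- m[, c((w - dc + 1L):w, 1L:(w - dc)), drop = FALSE]
  m
}

# flatten a frame to a pixel vector, row-major (pixel index = (row-1)*W + col);
# this fixed convention ties the movie matrix rows to image pixels
flatten_frame <- function(frame) as.vector(t(frame))

unflatten_frame <- function(v, shape) {
  t(matrix(v, nrow = shape[2], ncol = shape[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
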