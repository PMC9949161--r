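# Preprocessing: per-frame background-envelope removal and contrast metrics.
#
# The recorded frames are low-contrast speckle riding on a smooth
# fluorescence envelope; an unsharp mask (frame minus Gaussian blur)
# removes the envelope while keeping grain-scale structure, and negative
# residuals are clipped (or offset) to restore the nonnegativity the
# factorization requires.

# dense separable blur operator: row-stochastic truncated Gaussian with
# replicate-edge renormalization; blur(F) = Ky %*% F %*% t(Kx)
blur_operator <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (i in idx) {
    j <- max(1L, i - half):min(n, i + half)
    wts <- exp(-((j - i)^2) / (2 * sigma^2))
    K[i, j] <- wts / sum(wts)
  }
  K
}

#' Remove the smooth background envelope from one frame
#'
#' Unsharp mask: `frame - G_sigma(frame)` with a truncated,
#' replicate-renormalized Gaussian blur, followed by nonnegativity
#' restoration: either clipping negatives at 0 (default; preserves sparsity)
#' or offsetting by the global minimum.
#'
#' @param frame 2-D nonnegative image.
#' @param sigma_px Gaussian blur standard deviation in pixels (> 0);
#'   sensible default is about 4 times the speckle grain.
#' @param mode `"clip"` (default) or `"offset"`.
#' @return filtered frame, same shape, all values >= 0.
#' @export
highpass_frame <- function(frame, sigma_px, mode = c("clip", "offset")) {
  mode <- match.arg(mode)
  if (!(sigma_px > 0)) stopf("sigma_px must be > 0")
  check_finite(frame, "frame")
  Ky <- blur_operator(nrow(frame), sigma_px)
  Kx <- blur_operator(ncol(frame), sigma_px)
  out <- frame - Ky %*% frame %*% t(Kx)
  if (mode == "clip") out[out < 0] <- 0 else out <- out - min(out)
  out
}

#' Preprocess a whole movie for factorization
#'
#' Applies [highpass_frame()] to every frame with a shared blur operator.
#'
#' @param movie a `speckle_movie`.
#' @param sigma_px blur standard deviation in pixels.
#' @param mode negative-value handling, see [highpass_frame()].
#' @return a preprocessed `speckle_movie`.
#' @export
preprocess_movie <- function(movie, sigma_px, mode = c("clip", "offset")) {
  mode <- match.arg(mode)
  stopifnot(inherits(movie, "speckle_movie"))
  if (!(sigma_px > 0)) stopf("sigma_px must be > 0")
  d <- dim(movie$frames)
  Ky <- blur_operator(d[2], sigma_px)
  Kxt <- t(blur_operator(d[3], sigma_px))
  hw <- aperm(movie$frames, c(2, 3, 1))  # (row, col, t): contiguous frames
  for (k in seq_len(d[1])) {
    f <- hw[, , k]
    g <- f - Ky %*% f %*% Kxt
    if (mode == "clip") g[g < 0] <- 0 else g <- g - min(g)
    hw[, , k] <- g
  }
  speckle_movie(aperm(hw, c(3, 1, 2)), pixel_pitch_um = movie$pixel_pitch_um,
                frame_period_s = movie$frame_period_s)
}

#' Per-frame speckle contrast
#'
#' Contrast is sd/mean over pixels; fully developed single-source speckle
#' has contrast 1 and an incoherent sum of N independent patterns about
#' `1/sqrt(N)`.
#'
#' @param movie a `speckle_movie` (or a `T x H x W` array).
#' @return numeric vector of per-frame contrasts.
#' @export
movie_contrast <- function(movie) {
  frames <- if (inherits(movie, "speckle_movie")) movie$frames else movie
  tt <- dim(frames)[1]
  vapply(seq_len(tt), function(k) {
    f <- frames[k, , ]
    m <- mean(f)
    if (m == 0) stopf("zero-mean frame %d: contrast undefined", k)
    stats::sd(f) / m
  }, numeric(1))
}
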