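# Synthetic speckle-movie generator.
#
# Emulates the forward model the inverse pipeline assumes: N point-like
# emitters behind a thin scatterer, each casting a speckle fingerprint on
# the sensor; fingerprints of nearby emitters are laterally shifted copies
# of each other (optical memory effect), decorrelating with distance; all
# fingerprints add incoherently, weighted by nonnegative calcium-like
# temporal traces, on top of an optional temporally constant out-of-focus
# background speckle, with shot and read noise.

#' Emitter ensemble description
#'
#' @param positions_um N x 2 matrix of (x, y) emitter positions in
#'   micrometers in the object plane (x maps to image columns, y to rows).
#' @param pixel_pitch_um micrometers per camera pixel (object-plane
#'   equivalent); lateral memory-effect shifts are `delta_position / pitch`
#'   pixels.
#' @return an `emitter_ensemble` object.
#' @export
emitter_ensemble <- function(positions_um, pixel_pitch_um = 1) {
  positions_um <- as.matrix(positions_um)
  if (ncol(positions_um) != 2L || nrow(positions_um) < 1L)
    stopf("positions_um must be an N x 2 matrix with N >= 1")
  check_finite(positions_um, "positions_um")
  if (anyDuplicated(positions_um)) stopf("emitter positions must be distinct")
  if (!is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stopf("pixel_pitch_um must be > 0")
  structure(list(positions_um = positions_um,
                 pixel_pitch_um = pixel_pitch_um,
                 n_sources = nrow(positions_um)),
            class = "emitter_ensemble")
}

#' Scattering-medium model
#'
#' Phenomenological description of a thin scatterer: the only physics kept
#' is the memory effect (fingerprints of displaced emitters are shifted
#' copies, with correlation decaying as `exp(-(d / me_range_um)^2)`) and a
#' characteristic speckle grain size.
#'
#' @param me_range_um memory-effect decorrelation length in micrometers.
#' @param speckle_grain_px mean speckle grain size in pixels (>= 2).
#' @param frame_shape integer (H, W) of the sensor frame; both >= 64.
#' @param master_seed integer master seed; all randomness in a simulation is
#'   derived from it via [sub_seed()].
#' @return a `scatter_model` object.
#' @export
scatter_model <- function(me_range_um, speckle_grain_px = 4,
                          frame_shape = c(128L, 128L), master_seed = 1L) {
  if (!is.finite(me_range_um) || me_range_um <= 0) stopf("me_range_um must be > 0")
  if (speckle_grain_px < 2) stopf("speckle_grain_px must be >= 2")
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 64L))
    stopf("frame_shape must be two dims, each >= 64")
  structure(list(me_range_um = me_range_um,
                 speckle_grain_px = speckle_grain_px,
                 frame_shape = frame_shape,
                 master_seed = as.integer(master_seed)),
            class = "scatter_model")
}

#' Calcium-indicator-like trace model
#'
#' Traces are `baseline + amplitude * (Poisson spike train convolved with a
#' one-sided exponential decay)`: brief rises with longer decays, mimicking
#' genetically encoded calcium indicator dynamics.
#'
#' @param n_frames number of movie frames T (>= 2).
#' @param spike_rate_per_frame Poisson rate lambda of spikes per frame.
#' @param decay_frames exponential decay constant tau, in frames.
#' @param baseline nonnegative resting fluorescence level.
#' @param amplitude spike amplitude (fluorescence units per spike).
#' @return a `trace_model` object.
#' @export
trace_model <- function(n_frames, spike_rate_per_frame = 0.02,
                        decay_frames = 10, baseline = 0.1, amplitude = 1) {
  if (n_frames < 2L) stopf("n_frames must be >= 2")
  if (spike_rate_per_frame <= 0) stopf("spike_rate_per_frame must be > 0")
  if (decay_frames <= 0) stopf("decay_frames must be > 0")
  if (baseline < 0) stopf("baseline must be >= 0")
  structure(list(n_frames = as.integer(n_frames),
                 spike_rate_per_frame = spike_rate_per_frame,
                 decay_frames = decay_frames, baseline = baseline,
                 amplitude = amplitude),
            class = "trace_model")
}

#' Constant out-of-focus background model
#'
#' @param sbr target signal-to-background ratio (total time-averaged signal
#'   energy over total background energy; dimensionless). `Inf` disables the
#'   background.
#' @param bg_seed integer seed index for the background speckle realization.
#' @return a `background_model` object.
#' @export
background_model <- function(sbr = Inf, bg_seed = 0L) {
  if (!(sbr > 0)) stopf("sbr must be > 0 (use Inf to disable the background)")
  structure(list(sbr = sbr, bg_seed = as.integer(bg_seed)),
            class = "background_model")
}

# complex speckle field: uniform random phase on a centered elliptical
# pupil in Fourier space, inverse transform.  |field|^2 is fully developed
# speckle with unit contrast; the pupil radius sets the grain size
# (grain ~ n / (2 * radius) pixels along each axis).
speckle_field <- function(shape, grain_px, seed) {
  h <- shape[1]; w <- shape[2]
  set.seed(seed)
  fy <- (seq_len(h) - 1 - floor(h / 2)) / (h / 2)
  fx <- (seq_len(w) - 1 - floor(w / 2)) / (w / 2)
  pupil <- outer(fy^2, fx^2, `+`) <= (1 / grain_px)^2
  phase <- matrix(stats::runif(h * w, 0, 2 * pi), h, w)
  spec <- ifelse(pupil, exp(1i * phase), 0 + 0i)
  field <- stats::fft(fftshift2(spec), inverse = TRUE)
  field / sqrt(mean(Mod(field)^2))
}

#' Generate one fully developed speckle intensity pattern
#'
#' Standard synthesis: uniform random phase on a circular pupil in Fourier
#' space, inverse FFT, squared modulus. The result has unit mean, contrast
#' (sd/mean) close to 1, and autocorrelation width close to
#' `speckle_grain_px`.
#'
#' @param model a [scatter_model()].
#' @param seed integer seed.
#' @return an `H x W` nonnegative matrix with mean 1.
#' @export
generate_master_speckle <- function(model, seed) {
  stopifnot(inherits(model, "scatter_model"))
  Mod(speckle_field(model$frame_shape, model$speckle_grain_px, seed))^2
}

#' Fingerprint of one emitter relative to a reference emitter
#'
#' The fingerprint equals the reference (master) speckle pattern translated
#' by `(position - reference) / pixel_pitch` pixels, progressively
#' decorrelated with the emitter distance `d = |position - reference|`: the
#' Pearson correlation with the shifted master is `alpha(d) =
#' exp(-(d / me_range_um)^2)`. Decorrelation is implemented in the complex
#' field domain (`field = sqrt(g) * shifted_master_field + sqrt(1 - g) *
#' independent_field` with `g = sqrt(alpha)`), which for circular Gaussian
#' speckle fields yields an intensity correlation of exactly `g^2 = alpha`.
#' Shifts are applied on a padded canvas and cropped so no wrap-around
#' enters the frame.
#'
#' @param master_field_seed seed of the reference emitter's speckle field.
#' @param model a [scatter_model()].
#' @param position,reference (x, y) positions in micrometers.
#' @param pixel_pitch_um micrometers per pixel.
#' @param emitter_seed seed for the independent field component.
#' @return an `H x W` nonnegative fingerprint, normalized to mean 1.
#' @export
fingerprint_for_emitter <- function(master_field_seed, model, position,
                                    reference, pixel_pitch_um = 1,
                                    emitter_seed = master_field_seed + 1L) {
  stopifnot(inherits(model, "scatter_model"))
  dpx <- round((position - reference) / pixel_pitch_um)
  shift_rc <- c(dpx[2], dpx[1])  # (row, col) <- (y, x)
  d <- sqrt(sum((position - reference)^2))
  alpha <- exp(-(d / model$me_range_um)^2)
  g <- sqrt(alpha)
  # model-fixed canvas: the master realization must not depend on the
  # emitter distance, so the pad is half the frame, not the actual shift
  pad <- min(model$frame_shape) %/% 2L
  if (max(abs(shift_rc)) > pad)
    stopf("shift %d px exceeds supported range (%d px)", max(abs(shift_rc)), pad)
  canvas <- model$frame_shape + 2L * pad
  mf <- speckle_field(canvas, model$speckle_grain_px, master_field_seed)
  ef <- speckle_field(canvas, model$speckle_grain_px, emitter_seed)
  fld <- g * circshift2(mf, shift_rc[1], shift_rc[2]) + sqrt(1 - g^2) * ef
  w <- Mod(fld)^2
  w <- w[(pad + 1L):(pad + model$frame_shape[1]),
         (pad + 1L):(pad + model$frame_shape[2]), drop = FALSE]
  w / mean(w)
}

# Jointly generate all N fingerprints of an ensemble with the correct
# *pairwise* memory-effect correlation structure: the complex fields are a
# Gaussian-process mixture over emitter positions with field covariance
# K_ij = exp(-d_ij^2 / (2 R^2)), so every pair's intensity correlation is
# K_ij^2 = exp(-(d_ij / R)^2) regardless of the reference choice; each
# emitter's mixture is then shifted by its own memory-effect displacement.
generate_fingerprints <- function(ensemble, model) {
  stopifnot(inherits(ensemble, "emitter_ensemble"),
            inherits(model, "scatter_model"))
  n <- ensemble$n_sources
  pos <- ensemble$positions_um
  shifts <- round(sweep(pos, 2, pos[1, ]) / ensemble$pixel_pitch_um)
  shifts_rc <- cbind(row = shifts[, 2], col = shifts[, 1])
  pad <- max(abs(shifts_rc), 0)
  canvas <- model$frame_shape + 2L * as.integer(pad)
  if (any(t(abs(shifts_rc)) >= model$frame_shape))
    stopf("memory-effect shifts exceed the frame; enlarge frame_shape")
  D <- as.matrix(stats::dist(pos))
  K <- exp(-D^2 / (2 * model$me_range_um^2))
  L <- t(chol(K + diag(1e-10, n)))
  basis <- lapply(seq_len(n), function(m)
    speckle_field(canvas, model$speckle_grain_px,
                  sub_seed(model$master_seed, "emitter_field", m)))
  h <- model$frame_shape[1]; w <- model$frame_shape[2]
  fps <- array(0, dim = c(n, h, w))
  for (s in seq_len(n)) {
    fld <- matrix(0 + 0i, canvas[1], canvas[2])
    for (m in seq_len(s)) if (L[s, m] != 0) fld <- fld + L[s, m] * basis[[m]]
    fld <- circshift2(fld, shifts_rc[s, 1], shifts_rc[s, 2])
    ww <- Mod(fld)^2
    ww <- ww[(pad + 1L):(pad + h), (pad + 1L):(pad + w), drop = FALSE]
    fps[s, , ] <- ww / mean(ww)
  }
  list(fingerprints = fps, positions_px = shifts_rc)
}

#' Generate independent calcium-like temporal traces
#'
#' @param model a [trace_model()].
#' @param n_sources number of traces.
#' @param seed integer seed (per-trace sub-seeds are derived from it).
#' @return an `activity_set`: list with `traces`, an `n_sources x T`
#'   nonnegative matrix.
#' @export
generate_traces <- function(model, n_sources, seed) {
  stopifnot(inherits(model, "trace_model"))
  tr <- matrix(0, n_sources, model$n_frames)
  decay <- exp(-1 / model$decay_frames)
  for (s in seq_len(n_sources)) {
    set.seed(sub_seed(seed, "traces", s))
    spikes <- stats::rpois(model$n_frames, model$spike_rate_per_frame)
    conv <- stats::filter(spikes, decay, method = "recursive")
    tr[s, ] <- model$baseline + model$amplitude * as.numeric(conv)
  }
  activity_set(tr)
}

#' @rdname generate_traces
#' @param traces an `N x T` nonnegative matrix of temporal activities.
#' @export
activity_set <- function(traces) {
  traces <- as.matrix(traces)
  if (any(traces < 0)) stopf("traces must be nonnegative")
  structure(list(traces = traces), class = "activity_set")
}

#' Container for per-source speckle fingerprints
#'
#' @param patterns `N x H x W` nonnegative array, one fingerprint per source.
#' @param normalization scale convention tag (`"mean1"` for generator
#'   output, `"l2"` for factorization output).
#' @return a `fingerprint_set` object.
#' @export
fingerprint_set <- function(patterns, normalization = "mean1") {
  if (length(dim(patterns)) != 3L) stopf("patterns must be N x H x W")
  if (any(patterns < 0)) stopf("fingerprints must be nonnegative")
  structure(list(patterns = patterns, normalization = normalization),
            class = "fingerprint_set")
}

#' Simulate a ground-truth-annotated speckle movie
#'
#' Full forward model: memory-effect-correlated fingerprints, independent
#' calcium-like traces, optional constant background speckle scaled to a
#' target signal-to-background ratio, shot noise at a photon budget, and
#' Gaussian read noise.
#'
#' @param ensemble an [emitter_ensemble()].
#' @param scatter a [scatter_model()].
#' @param traces a [trace_model()].
#' @param background a [background_model()] (default: no background).
#' @param photon_budget mean photons per pixel per frame for shot noise;
#'   `Inf` (default) disables shot noise.
#' @param read_noise_sd Gaussian read noise standard deviation, in photons;
#'   0 disables.
#' @param frame_period_s frame period in seconds (metadata only).
#' @return a list with `movie` (a `speckle_movie`) and `gt` (a
#'   `ground_truth`: `fingerprints`, `traces`, `positions_px` relative to
#'   source 1, `background_frame`, and the models).
#' @export
simulate_movie <- function(ensemble, scatter, traces,
                           background = background_model(Inf),
                           photon_budget = Inf, read_noise_sd = 0,
                           frame_period_s = 0.5) {
  stopifnot(inherits(traces, "trace_model"),
            inherits(background, "background_model"))
  fp <- generate_fingerprints(ensemble, scatter)
  acts <- generate_traces(traces, ensemble$n_sources, scatter$master_seed)
  bg <- make_background(fp$fingerprints, acts$traces, scatter, background)
  gt <- structure(list(
    fingerprints = fingerprint_set(fp$fingerprints),
    traces = acts,
    positions_px = fp$positions_px,
    background_frame = bg,
    ensemble = ensemble, scatter = scatter, trace_model = traces,
    background_model = background,
    photon_budget = photon_budget, read_noise_sd = read_noise_sd
  ), class = "ground_truth")
  movie <- assemble_movie(gt, noise = list(photon_budget = photon_budget,
                                           read_noise_sd = read_noise_sd),
                          seed = sub_seed(scatter$master_seed, "movie_noise"),
                          frame_period_s = frame_period_s,
                          pixel_pitch_um = ensemble$pixel_pitch_um)
  list(movie = movie, gt = gt)
}

# constant background speckle, scaled so that
# sum(time-averaged signal) / sum(background) == sbr
make_background <- function(fingerprints, traces, scatter, background) {
  h <- dim(fingerprints)[2]; w <- dim(fingerprints)[3]
  if (!is.finite(background$sbr)) return(matrix(0, h, w))
  raw <- generate_master_speckle(
    scatter, sub_seed(scatter$master_seed, "background", background$bg_seed))
  mean_h <- rowMeans(traces)
  signal_energy <- sum(vapply(seq_len(dim(fingerprints)[1]),
                              function(s) sum(fingerprints[s, , ]) * mean_h[s],
                              numeric(1)))
  raw * (signal_energy / (background$sbr * sum(raw)))
}

#' Assemble a movie from ground truth
#'
#' Frame k is `sum_s w_s * h_s(t_k) + background`; with a finite photon
#' budget the frame is Poisson-sampled (the movie is scaled so its mean
#' pixel value equals `photon_budget` photons, sampled, and scaled back),
#' then Gaussian read noise is added and negative values clipped to 0.
#'
#' @param gt a `ground_truth` object.
#' @param noise list with `photon_budget` and `read_noise_sd`.
#' @param seed integer seed for the noise draws.
#' @param frame_period_s,pixel_pitch_um movie metadata.
#' @return a `speckle_movie`.
#' @export
assemble_movie <- function(gt, noise = list(photon_budget = Inf, read_noise_sd = 0),
                           seed = 0L, frame_period_s = 0.5, pixel_pitch_um = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  fps <- gt$fingerprints$patterns
  H <- gt$traces$traces
  n <- dim(fps)[1]; h <- dim(fps)[2]; w <- dim(fps)[3]; tt <- ncol(H)
  if (nrow(H) != n) stopf("fingerprint/trace source counts differ")
  Wmat <- matrix(0, h * w, n)
  for (s in seq_len(n)) Wmat[, s] <- flatten_frame(fps[s, , ])
  V <- Wmat %*% H
  V <- V + flatten_frame(gt$background_frame)
  pb <- noise$photon_budget %||% Inf
  rn <- noise$read_noise_sd %||% 0
  if (is.finite(pb) || rn > 0) set.seed(seed)
  scale <- if (is.finite(pb)) pb / mean(V) else 1
  if (is.finite(pb))
    V <- matrix(stats::rpois(length(V), as.vector(V) * scale), nrow(V)) / scale
  if (rn > 0)
    V <- V + matrix(stats::rnorm(length(V), 0, rn), nrow(V)) / scale
  V[V < 0] <- 0
  # columns are row-major-flattened frames: (col, row, t) -> (t, row, col)
  frames <- aperm(array(V, dim = c(w, h, tt)), c(3, 2, 1))
  speckle_movie(frames, pixel_pitch_um = pixel_pitch_um,
                frame_period_s = frame_period_s)
}

#' Speckle movie container
#'
#' @param frames `T x H x W` nonnegative intensity array.
#' @param pixel_pitch_um micrometers per pixel (object-plane equivalent).
#' @param frame_period_s frame period in seconds.
#' @return a `speckle_movie` object.
#' @export
speckle_movie <- function(frames, pixel_pitch_um = 1, frame_period_s = 0.5) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 2L)
    stopf("frames must be a T x H x W array with T >= 2")
  check_finite(frames, "frames")
  if (any(frames < 0)) stopf("frames must be nonnegative")
  structure(list(frames = frames, pixel_pitch_um = pixel_pitch_um,
                 frame_period_s = frame_period_s),
            class = "speckle_movie")
}

#' @export
print.speckle_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_movie: %d frames of %d x %d px (pitch %.3g um, period %.3g s)\n",
              d[1], d[2], d[3], x$pixel_pitch_um, x$frame_period_s))
  invisible(x)
}

#' Measure the signal-to-background ratio of a ground truth
#'
#' Primary readout (`per_source = FALSE`): total time-averaged signal energy
#' summed over pixels and sources, divided by total background energy per
#' frame. Secondary readout (`per_source = TRUE`): one ratio per source,
#' each source's time-averaged energy over the background energy.
#'
#' @param gt a `ground_truth` with a background present.
#' @param per_source return the per-source variant.
#' @return a scalar (or a length-N vector).
#' @export
measure_sbr <- function(gt, per_source = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  bg <- sum(gt$background_frame)
  if (bg <= 0) stopf("background absent; SBR undefined")
  fps <- gt$fingerprints$patterns
  mean_h <- rowMeans(gt$traces$traces)
  per <- vapply(seq_len(dim(fps)[1]),
                function(s) sum(fps[s, , ]) * mean_h[s], numeric(1)) / bg
  if (per_source) per else sum(per)
}

#' Generate emitter ensembles for simulated experiments
#'
#' `path_ensemble()` spreads emitters along the field diagonal with lateral
#' jitter, guaranteeing a chain whose nearest-neighbor spacing is about
#' `span_um / (n - 1)` while the full extent reaches `span_um` — the
#' geometry used to exercise stitching beyond the memory-effect range.
#' `random_ensemble()` draws positions uniformly in a centered square of
#' side `span_um`, rejecting draws closer than `min_spacing_um` to an
#' accepted one.
#'
#' @param n number of emitters.
#' @param span_um extent of the ensemble (square side for
#'   `random_ensemble`, end-to-end path length for `path_ensemble`),
#'   micrometers.
#' @param min_spacing_um minimum pairwise distance, micrometers.
#' @param jitter_um lateral jitter amplitude about the path.
#' @param seed integer seed.
#' @param pixel_pitch_um passed through to [emitter_ensemble()].
#' @return an `emitter_ensemble`.
#' @export
path_ensemble <- function(n, span_um, jitter_um = span_um / 8, seed = 1L,
                          pixel_pitch_um = 1) {
  set.seed(sub_seed(seed, "ensemble", 1L))
  tt <- seq(-0.5, 0.5, length.out = n)
  ax <- span_um / sqrt(2)
  pos <- cbind(tt * ax + stats::runif(n, -jitter_um, jitter_um),
               tt * ax + stats::runif(n, -jitter_um, jitter_um))
  # normalize so the realized extent equals the requested span exactly
  pos <- pos * (span_um / max(stats::dist(pos)))
  pos <- round(sweep(pos, 2, colMeans(pos)))
  emitter_ensemble(pos, pixel_pitch_um)
}

#' @rdname path_ensemble
#' @export
random_ensemble <- function(n, span_um, min_spacing_um = 0, seed = 1L,
                            pixel_pitch_um = 1) {
  set.seed(sub_seed(seed, "ensemble"))
  pos <- matrix(NA_real_, n, 2)
  accepted <- 0L
  for (try in seq_len(20000L)) {
    p <- stats::runif(2, -span_um / 2, span_um / 2)
    if (accepted == 0L ||
        min(sqrt(colSums((t(pos[seq_len(accepted), , drop = FALSE]) - p)^2))) >=
          min_spacing_um) {
      accepted <- accepted + 1L
      pos[accepted, ] <- p
      if (accepted == n) break
    }
  }
  if (accepted < n)
    stopf("could not place %d emitters with spacing %g in span %g",
          n, min_spacing_um, span_um)
  emitter_ensemble(round(pos), pixel_pitch_um)
}
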