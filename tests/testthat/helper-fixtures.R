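# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

small_scatter <- function(me_range_um = 30, frame = 64L, seed = 1L,
                          grain = 4) {
  scatter_model(me_range_um = me_range_um, speckle_grain_px = grain,
                frame_shape = c(frame, frame), master_seed = seed)
}

small_trace <- function(T = 120L, rate = 0.05) {
  trace_model(n_frames = T, spike_rate_per_frame = rate, decay_frames = 8,
              baseline = 0.1, amplitude = 1)
}

# a tiny noise-free simulation used by several files
tiny_sim <- function(positions = rbind(c(0, 0), c(20, 0), c(0, 20)),
                     seed = 3L, frame = 64L, me = 40, T = 120L, ...) {
  simulate_movie(emitter_ensemble(positions, 1),
                 small_scatter(me_range_um = me, frame = frame, seed = seed),
                 small_trace(T = T), ...)
}

# Independent shift oracle: brute-force argmax of the circular
# cross-correlation over a window of candidate integer shifts.  Computed by
# direct shifted inner products -- no FFT, no shared code with the
# deconvolution path.
xcorr_shift_oracle <- function(a, b, smax = 12L) {
  a <- a - mean(a); b <- b - mean(b)
  best <- -Inf; arg <- c(NA_integer_, NA_integer_)
  for (dr in -smax:smax) for (dc in -smax:smax) {
    # score of hypothesis "b is a shifted by (dr, dc)"
    v <- sum(a * circshift_ref(b, -dr, -dc))
    if (v > best) { best <- v; arg <- c(dr, dc) }
  }
  arg
}

# reference circular shift, written independently of the package internals
circshift_ref <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - dr) %% h) + 1
  ci <- ((seq_len(w) - 1 - dc) %% w) + 1
  m[ri, ci, drop = FALSE]
}

# translation-aligned localization error per source (NA for unplaced)
aligned_errors <- function(rec, gt, placed = rep(TRUE, nrow(rec))) {
  off <- colMeans(rec[placed, , drop = FALSE] - gt[placed, , drop = FALSE])
  err <- sqrt(rowSums((sweep(rec, 2, off) - gt)^2))
  err[!placed] <- NA_real_
  err
}
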