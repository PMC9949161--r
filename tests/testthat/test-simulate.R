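test_that("model constructors validate their invariants", {
  expect_error(scatter_model(-1), "me_range_um")
  expect_error(scatter_model(10, speckle_grain_px = 1), "speckle_grain_px")
  expect_error(scatter_model(10, frame_shape = c(32, 64)), "frame_shape")
  expect_error(trace_model(1), "n_frames")
  expect_error(trace_model(10, baseline = -1), "baseline")
  expect_error(background_model(0), "sbr")
  expect_error(emitter_ensemble(rbind(c(0, 0), c(0, 0))), "distinct")
  expect_error(emitter_ensemble(matrix(1, 1, 3)), "N x 2")
})

test_that("simulation is deterministic given the configuration", {
  s1 <- tiny_sim(seed = 9, T = 40)
  s2 <- tiny_sim(seed = 9, T = 40)
  expect_identical(s1$movie$frames, s2$movie$frames)
  expect_identical(s1$gt$fingerprints$patterns, s2$gt$fingerprints$patterns)
  expect_identical(s1$gt$traces$traces, s2$gt$traces$traces)
  s3 <- tiny_sim(seed = 10, T = 40)
  expect_false(identical(s1$movie$frames, s3$movie$frames))
  # noisy assembly is seeded too
  n1 <- tiny_sim(seed = 9, T = 40, photon_budget = 500, read_noise_sd = 1)
  n2 <- tiny_sim(seed = 9, T = 40, photon_budget = 500, read_noise_sd = 1)
  expect_identical(n1$movie$frames, n2$movie$frames)
})

test_that("single speckle patterns are fully developed (contrast ~ 1)", {
  sm <- small_scatter(frame = 128)
  cs <- vapply(1:20, function(s) {
    p <- generate_master_speckle(sm, s)
    expect_true(all(p >= 0))
    sd(p) / mean(p)
  }, numeric(1))
  expect_true(all(abs(cs - 1) < 0.1))
  # determinism
  expect_identical(generate_master_speckle(sm, 5),
                   generate_master_speckle(sm, 5))
})

test_that("incoherent sums follow the 1/sqrt(N) contrast law", {
  sm <- small_scatter(frame = 128)
  contrast_of_sum <- function(n, off = 0) {
    p <- Reduce(`+`, lapply(seq_len(n) + off, function(s)
      generate_master_speckle(sm, s)))
    sd(p) / mean(p)
  }
  c25 <- contrast_of_sum(25)
  expect_lt(abs(c25 - 0.2) / 0.2, 0.2)  # 1/sqrt(25), 20% relative
  cs <- vapply(c(1, 4, 16, 64), contrast_of_sum, numeric(1), off = 100)
  expect_true(all(diff(cs) < 0))  # monotone decrease with N
  for (i in 2:4)
    expect_lt(abs(cs[i] - 1 / sqrt(c(1, 4, 16, 64)[i])) * sqrt(c(1, 4, 16, 64)[i]),
              0.2)
})

test_that("fingerprint correlation follows the memory-effect decay", {
  sm <- small_scatter(me_range_um = 30, frame = 128)
  corr_at <- function(d, seeds = 1:10) {
    vapply(seeds, function(s) {
      w0 <- fingerprint_for_emitter(s, sm, c(0, 0), c(0, 0),
                                    emitter_seed = s + 999)
      w <- fingerprint_for_emitter(s, sm, c(d, 0), c(0, 0),
                                   emitter_seed = s + 999)
      dc <- round(d)
      valid <- (dc + 1):128  # exclude the wrapped strip
      cor(as.vector(w[, valid]),
          as.vector(circshift_ref(w0, 0, dc)[, valid]))
    }, numeric(1))
  }
  expect_equal(mean(corr_at(0, 1:3)), 1, tolerance = 1e-12)  # identical at d=0
  expect_lt(abs(mean(corr_at(30)) - exp(-1)), 0.1)
  expect_lt(max(abs(corr_at(60, 1:5))), 0.2)
  sm5 <- small_scatter(me_range_um = 10, frame = 128)
  expect_lt(mean(abs(corr_at_d5 <- vapply(1:5, function(s) {
    w0 <- fingerprint_for_emitter(s, sm5, c(0, 0), c(0, 0), emitter_seed = s + 999)
    w <- fingerprint_for_emitter(s, sm5, c(50, 0), c(0, 0), emitter_seed = s + 999)
    cor(as.vector(w[, 51:128]), as.vector(circshift_ref(w0, 0, 50)[, 51:128]))
  }, numeric(1)))), 0.05)
})

test_that("traces match a direct-convolution oracle and are independent", {
  tm <- trace_model(200, spike_rate_per_frame = 0.05, decay_frames = 8,
                    baseline = 0.2, amplitude = 1.5)
  acts <- generate_traces(tm, 3, seed = 11)
  expect_true(all(acts$traces >= 0))
  # oracle: re-draw the same spikes and convolve by direct summation
  for (s in 1:3) {
    set.seed(sub_seed(11, "traces", s))
    spikes <- rpois(200, 0.05)
    expected <- vapply(seq_len(200), function(t)
      0.2 + 1.5 * sum(spikes[seq_len(t)] * exp(-(t - seq_len(t)) / 8)),
      numeric(1))
    expect_equal(acts$traces[s, ], expected, tolerance = 1e-10)
  }
  # near-zero rate: trace collapses to the baseline
  flat <- generate_traces(trace_model(50, spike_rate_per_frame = 1e-12,
                                      decay_frames = 5, baseline = 0.7),
                          1, seed = 1)
  expect_equal(flat$traces[1, ], rep(0.7, 50))
  # independence: mean |pairwise correlation| small over many sources
  big <- generate_traces(trace_model(500, spike_rate_per_frame = 0.02,
                                     decay_frames = 10, baseline = 0.1),
                         19, seed = 5)
  C <- cor(t(big$traces))
  expect_lt(mean(abs(C[upper.tri(C)])), 0.3)
})

test_that("assembled movies obey the linear forward model", {
  # noise off, background off, N=1, constant trace: every frame equals w1
  sm <- small_scatter(frame = 64, seed = 2)
  w1 <- generate_master_speckle(sm, 8)
  gt <- structure(list(
    fingerprints = fingerprint_set(array(w1, c(1, 64, 64))),
    traces = activity_set(matrix(1, 1, 5)),
    positions_px = cbind(row = 0, col = 0),
    background_frame = matrix(0, 64, 64)), class = "ground_truth")
  mv <- assemble_movie(gt, frame_period_s = 1)
  for (k in 1:5) expect_equal(mv$frames[k, , ], w1, tolerance = 1e-12)

  # noise-free movie matrix has numerical rank N (SVD oracle)
  sim <- tiny_sim(T = 60)
  sv <- svd(movie_to_matrix(sim$movie), nu = 0, nv = 0)$d
  expect_lt(sv[4] / sv[1], 1e-6)
  expect_gt(sv[3] / sv[1], 1e-6)
})

test_that("SBR round-trips through the generator and measurement", {
  sim <- tiny_sim(T = 60, background = background_model(sbr = 1.6))
  expect_equal(measure_sbr(sim$gt), 1.6, tolerance = 0.05)
  sim3 <- tiny_sim(T = 60, background = background_model(sbr = 3))
  expect_equal(measure_sbr(sim3$gt), 3, tolerance = 0.05 * 3)
  # doubling the background halves the ratio
  gt2 <- sim3$gt
  gt2$background_frame <- 2 * gt2$background_frame
  expect_equal(measure_sbr(gt2), 1.5, tolerance = 0.05 * 1.5)
  # background equal to the time-averaged signal -> exactly 1
  gt1 <- sim3$gt
  fps <- gt1$fingerprints$patterns
  mh <- rowMeans(gt1$traces$traces)
  gt1$background_frame <- Reduce(`+`, lapply(1:3, function(s) fps[s, , ] * mh[s]))
  expect_equal(measure_sbr(gt1), 1, tolerance = 1e-10)
  # per-source readout sums to the total
  expect_equal(sum(measure_sbr(sim3$gt, per_source = TRUE)),
               measure_sbr(sim3$gt), tolerance = 1e-12)
  # absent background is signalled
  expect_error(measure_sbr(tiny_sim(T = 10)$gt), "background")
})

test_that("movie contrast decreases monotonically with source count", {
  contrasts <- vapply(c(1, 4, 16), function(n) {
    set.seed(n)
    pos <- cbind(round(runif(n, -12, 12)), round(runif(n, -12, 12)))
    while (anyDuplicated(pos))
      pos[anyDuplicated(pos), ] <- round(runif(2, -12, 12))
    sim <- simulate_movie(emitter_ensemble(pos, 1),
                          small_scatter(me_range_um = 1e6, frame = 64),
                          small_trace(T = 30))
    mean_frame <- apply(sim$movie$frames, c(2, 3), mean)
    sd(mean_frame) / mean(mean_frame)
  }, numeric(1))
  expect_true(all(diff(contrasts) < 0))
})

test_that("generated fingerprints carry the exact ground-truth shift", {
  sm <- small_scatter(me_range_um = 40, frame = 64, seed = 6)
  # d <= 0.3 * me_range: cross-correlation argmax equals the true shift
  for (d in list(c(8, 0), c(0, -10), c(7, 9))) {
    ens <- emitter_ensemble(rbind(c(0, 0), d), 1)
    fp <- generate_fingerprints(ens, sm)
    sh <- xcorr_shift_oracle(fp$fingerprints[1, , ], fp$fingerprints[2, , ])
    expect_identical(sh, as.integer(fp$positions_px[2, ]))
    expect_identical(as.integer(fp$positions_px[2, ]),
                     as.integer(c(d[2], d[1])))  # (row, col) <- (y, x)
  }
})
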