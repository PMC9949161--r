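test_that("deconvolution recovers constructed translations exactly", {
  sm <- small_scatter(frame = 128)
  w <- generate_master_speckle(sm, 5)
  # self-deconvolution: peak at the center, very high confidence
  pk0 <- extract_peak(deconvolve_pair(w, w))
  expect_equal(pk0$shift, c(0, 0))
  expect_gt(pk0$confidence, 20)
  expect_true(pk0$correlated)

  # pure translations: deconvolution equals the brute-force
  # cross-correlation argmax oracle, exactly, under the sign convention
  set.seed(4)
  for (trial in 1:6) {
    d <- sample(-10:10, 2, replace = TRUE)
    ws <- circshift_ref(w, d[1], d[2])
    pk <- extract_peak(deconvolve_pair(w, ws))
    expect_equal(pk$shift, d)
    expect_equal(pk$shift, as.numeric(xcorr_shift_oracle(w, ws)))
  }

  # two independent speckles: low confidence, no correlation
  w2 <- generate_master_speckle(sm, 6)
  pk2 <- extract_peak(deconvolve_pair(w, w2))
  expect_lt(pk2$confidence, 3)
  expect_false(pk2$correlated)

  expect_error(deconvolve_pair(w, w2[1:64, 1:64]), "equal shapes")
  expect_error(deconvolve_pair(w * 0, w), "all-zero")
})

test_that("peak extraction flags deltas and rejects flat images", {
  img <- matrix(0, 65, 65)
  img[33, 33] <- 1  # center pixel for a 65 x 65 image
  pk <- extract_peak(img)
  expect_equal(pk$shift, c(0, 0))
  expect_true(pk$correlated)
  expect_gt(pk$confidence, 100)

  set.seed(1)
  flat <- matrix(rnorm(65 * 65, 0, 1e-6), 65, 65)
  expect_false(extract_peak(flat)$correlated)
})

test_that("simulated pairs within the memory-effect range localize to 1 px", {
  sm <- small_scatter(me_range_um = 30, frame = 128)
  for (seed in 1:5) {
    smx <- small_scatter(me_range_um = 30, frame = 128, seed = seed)
    ens <- emitter_ensemble(rbind(c(0, 0), c(11, -9)), 1)  # d ~ 0.5 R
    fp <- generate_fingerprints(ens, smx)
    pk <- extract_peak(deconvolve_pair(fp$fingerprints[1, , ],
                                       fp$fingerprints[2, , ]))
    expect_true(pk$correlated)
    expect_lte(max(abs(pk$shift - fp$positions_px[2, ])), 1)
  }
})

test_that("pairwise shifts are antisymmetric for correlated pairs", {
  sm <- small_scatter(me_range_um = 30, frame = 128, seed = 3)
  ens <- emitter_ensemble(rbind(c(0, 0), c(14, 3), c(-2, 12), c(9, -11)), 1)
  fp <- generate_fingerprints(ens, sm)
  g <- measure_shifts(fp$fingerprints)
  cg <- g[g$correlated, ]
  expect_gt(nrow(cg), 0)
  for (k in seq_len(nrow(cg))) {
    rev_ <- g[g$i == cg$j[k] & g$j == cg$i[k], ]
    expect_true(rev_$correlated)
    expect_lte(abs(cg$drow[k] + rev_$drow), 1)
    expect_lte(abs(cg$dcol[k] + rev_$dcol), 1)
  }
})

test_that("partial maps show each source's neighborhood", {
  # single source: one central peak
  sm <- small_scatter(frame = 128)
  w <- generate_master_speckle(sm, 1)
  m1 <- build_partial_map(1, array(w, c(1, dim(w))))
  pk <- extract_peak(m1)
  expect_equal(pk$shift, c(0, 0))

  # three collinear sources within range: map of the middle one has peaks
  # at both neighbors' ground-truth offsets
  smc <- small_scatter(me_range_um = 40, frame = 128, seed = 9)
  ens <- emitter_ensemble(rbind(c(-14, 0), c(0, 0), c(14, 0)), 1)
  fp <- generate_fingerprints(ens, smc)
  m2 <- build_partial_map(2, fp$fingerprints)
  ctr <- floor(dim(m2) / 2) + 1
  for (i in c(1, 3)) {
    off <- fp$positions_px[i, ] - fp$positions_px[2, ]
    window <- m2[ctr[1] + off[1] + (-1:1), ctr[2] + off[2] + (-1:1)]
    # the neighbor peak dominates everything outside the self/neighbor spots
    masked <- m2
    for (j in 1:3) {
      o <- fp$positions_px[j, ] - fp$positions_px[2, ]
      masked[ctr[1] + o[1] + (-3:3), ctr[2] + o[2] + (-3:3)] <- -Inf
    }
    expect_gt(max(window), max(masked))
  }

  # an isolated source contributes no off-center peak
  smf <- small_scatter(me_range_um = 10, frame = 128, seed = 2)
  ensf <- emitter_ensemble(rbind(c(0, 0), c(50, 0)), 1)
  fpf <- generate_fingerprints(ensf, smf)
  mf <- build_partial_map(1, fpf$fingerprints)
  pkf <- extract_peak(mf)
  expect_equal(pkf$shift, c(0, 0))  # only the self-peak stands out
})

test_that("global positions compose shifts over the graph", {
  mk_graph <- function(df, n) {
    df$peak <- 1; df$noise_floor <- 0.1
    df$correlated <- TRUE
    attr(df, "n_sources") <- n
    class(df) <- c("shift_graph", class(df))
    df
  }
  # chain 1 -> 2 -> 3: exact path composition
  g <- mk_graph(data.frame(i = c(1, 2), j = c(2, 3),
                           drow = c(2, 3), dcol = c(0, 0),
                           confidence = 10), 3)
  sol <- solve_global_positions(g, reference = 1)
  expect_equal(sol$positions,
               cbind(row = c(0, 2, 5), col = c(0, 0, 0)), tolerance = 1e-10)
  expect_equal(sol$residual, 0, tolerance = 1e-12)

  # consistent triangle: identical to path composition
  g2 <- mk_graph(data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                            drow = c(2, 3, 5), dcol = c(1, 0, 1),
                            confidence = 10), 3)
  sol2 <- solve_global_positions(g2, reference = 1)
  expect_equal(sol2$positions,
               cbind(row = c(0, 2, 5), col = c(0, 1, 1)), tolerance = 1e-10)

  # perturbed triangle: matches a brute-force normal-equation solve
  g3 <- mk_graph(data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                            drow = c(2, 3, 6), dcol = c(1, 0, 1),
                            confidence = c(4, 2, 1)), 3)
  sol3 <- solve_global_positions(g3, reference = 1, prune_px = Inf)
  # independent solve: minimize sum w_e ||p_j - p_i - s_e||^2 for p2, p3
  # unknowns x = (p2r, p3r): A from edges (1,2), (2,3), (1,3)
  A <- rbind(c(1, 0) * sqrt(4), c(-1, 1) * sqrt(2), c(0, 1) * sqrt(1))
  br <- c(2 * sqrt(4), 3 * sqrt(2), 6 * sqrt(1))
  bc <- c(1 * sqrt(4), 0 * sqrt(2), 1 * sqrt(1))
  expect_equal(sol3$positions[2:3, 1], qr.solve(A, br), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sol3$positions[2:3, 2], qr.solve(A, bc), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lte(max(abs(sol3$positions - sol2$positions)), 1)
  expect_gt(sol3$residual, 0)

  # disconnected graph: the far node is reported unplaced
  g4 <- mk_graph(data.frame(i = 1, j = 2, drow = 2, dcol = 0,
                            confidence = 10), 4)
  sol4 <- solve_global_positions(g4, reference = 1)
  expect_identical(sol4$unplaced, c(3L, 4L))
  expect_true(all(is.na(sol4$positions[3:4, ])))
})

test_that("an inconsistent high-confidence edge is pruned, not absorbed", {
  mk_graph <- function(df, n) {
    df$peak <- 1; df$noise_floor <- 0.1; df$correlated <- TRUE
    attr(df, "n_sources") <- n
    class(df) <- c("shift_graph", class(df))
    df
  }
  # square with consistent edges plus one wildly wrong diagonal
  g <- mk_graph(data.frame(
    i = c(1, 2, 3, 1, 1), j = c(2, 3, 4, 4, 3),
    drow = c(10, 0, -10, 0, 30), dcol = c(0, 10, 0, 10, -20),
    confidence = c(10, 10, 10, 10, 8)), 4)
  sol <- solve_global_positions(g, reference = 1)
  expect_equal(sol$positions,
               cbind(row = c(0, 10, 10, 0), col = c(0, 0, 10, 10)),
               tolerance = 1e-8)
})

test_that("the stitched map is consistent with the position list", {
  sm <- small_scatter(me_range_um = 40, frame = 128, seed = 12)
  ens <- emitter_ensemble(rbind(c(-13, -4), c(0, 0), c(12, 8)), 1)
  fp <- generate_fingerprints(ens, sm)
  loc <- localize_fingerprints(fp$fingerprints, reference = 2)
  expect_true(all(loc$positions$placed))
  # map argmax set matches the discrete positions within 1 px
  map <- loc$map$map_image
  for (s in 1:3) {
    p <- round(loc$map$positions_px[s, ]) + loc$map$origin
    window <- map[p[1] + (-1:1), p[2] + (-1:1)]
    expect_gt(max(window), quantile(map, 0.999))
  }
  # single source: map equals its partial map
  w <- array(generate_master_speckle(sm, 44), c(1, 128, 128))
  loc1 <- localize_fingerprints(w)
  expect_equal(loc1$map$map_image, build_partial_map(1, w), tolerance = 1e-12)
})

test_that("recovered geometry is equivariant under rigid translation", {
  sm <- small_scatter(me_range_um = 40, frame = 128, seed = 21)
  base <- rbind(c(0, 0), c(15, 2), c(-3, 14))
  rel <- function(positions) sweep(positions, 2, positions[1, ])
  locs <- lapply(list(base, base + 7), function(pos) {
    fp <- generate_fingerprints(emitter_ensemble(pos, 1), sm)
    loc <- localize_fingerprints(fp$fingerprints, reference = 1,
                                 render = FALSE)
    rel(loc$positions$positions)
  })
  expect_equal(locs[[1]], locs[[2]], tolerance = 1e-8)
})

test_that("pair evidence and placement degrade monotonically with spacing", {
  R <- 30
  spacings <- c(0.3, 0.6, 0.9, 1.2) * R
  conf <- vapply(spacings, function(d) {
    mean(vapply(1:4, function(seed) {
      sm <- small_scatter(me_range_um = R, frame = 128, seed = seed)
      fp <- generate_fingerprints(
        emitter_ensemble(rbind(c(0, 0), c(d, 0)), 1), sm)
      extract_peak(deconvolve_pair(fp$fingerprints[1, , ],
                                   fp$fingerprints[2, , ]))$confidence
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(conf) < 0))
  # chains at increasing nearest-neighbor spacing: the fraction placed
  # within 2 px never recovers once it starts dropping
  frac <- vapply(spacings, function(d) {
    mean(vapply(1:4, function(seed) {
      sm <- small_scatter(me_range_um = R, frame = 192, seed = seed)
      ens <- emitter_ensemble(cbind(round((0:4) * d) - round(2 * d), 0), 1)
      fp <- generate_fingerprints(ens, sm)
      loc <- tryCatch(
        localize_fingerprints(fp$fingerprints, render = FALSE),
        error = function(e) NULL)
      if (is.null(loc)) return(0)
      err <- aligned_errors(loc$positions$positions, fp$positions_px,
                            loc$positions$placed)
      mean(loc$positions$placed & !is.na(err) & err <= 2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], 1)
})

test_that("dense chains stitch beyond the memory-effect range", {
  # nearest-neighbor spacing <= 0.5 R, span up to 2 R: >= 95% of sources
  # placed within 2 px across seeds
  R <- 30
  placed_ok <- 0L; total <- 0L
  for (seed in 1:10) {
    sm <- small_scatter(me_range_um = R, frame = 128, seed = seed)
    ens <- path_ensemble(9, span_um = 2 * R, jitter_um = 4, seed = seed)
    fp <- generate_fingerprints(ens, sm)
    loc <- localize_fingerprints(fp$fingerprints, render = FALSE)
    rec <- loc$positions$positions
    pl <- loc$positions$placed
    err <- aligned_errors(rec, fp$positions_px, pl)
    placed_ok <- placed_ok + sum(pl & err <= 2, na.rm = TRUE)
    total <- total + nrow(rec)
  }
  expect_gte(placed_ok / total, 0.95)
})
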