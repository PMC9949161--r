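# Demixing: sparse non-negative matrix factorization of the movie matrix.
#
# The movie is reshaped to a pixels x frames matrix V (pixel rows in
# row-major order, one column per frame) and factorized as V ~ W %*% H with
# W, H >= 0: columns of W are per-source speckle fingerprints, rows of H the
# temporal activities.  Multiplicative updates minimize
# 0.5 * ||V - W H||_F^2 + lambda_W ||W||_1 + lambda_H ||H||_1,
# which is non-increasing under the updates.  The number of sources is
# estimated non-invasively by scanning candidate ranks and locating the
# elbow of the residual curve.

#' Reshape a speckle movie to its matrix form
#'
#' Each column is one frame, flattened row-major (pixel index =
#' `(row - 1) * W + col`). The inverse of the per-column reshape is
#' available through the internal frame helpers; the convention is fixed so
#' fingerprints and movie rows always align.
#'
#' @param movie a `speckle_movie` or a `T x H x W` array.
#' @return a `(H*W) x T` matrix.
#' @export
movie_to_matrix <- function(movie) {
  frames <- if (inherits(movie, "speckle_movie")) movie$frames else movie
  d <- dim(frames)
  # (t, row, col) -> (col, row, t); column-major flatten of the first two
  # dims is exactly the row-major pixel order
  matrix(aperm(frames, c(3, 2, 1)), d[2] * d[3], d[1])
}

# Nonnegative double-SVD initialization (deterministic).  The leading
# singular pairs are computed from the small T x T Gram matrix; each pair is
# split into its positive and negative parts and the dominant part kept.
nndsvd_init <- function(V, k) {
  G <- crossprod(V)                      # T x T
  eg <- eigen(G, symmetric = TRUE)
  d2 <- pmax(eg$values[seq_len(k)], 0)
  sv <- sqrt(d2)
  Vk <- eg$vectors[, seq_len(k), drop = FALSE]
  Uk <- V %*% Vk
  Uk <- sweep(Uk, 2, pmax(sv, .Machine$double.eps), "/")
  W0 <- matrix(0, nrow(V), k); H0 <- matrix(0, k, ncol(V))
  for (j in seq_len(k)) {
    u <- Uk[, j]; v <- Vk[, j]
    if (j == 1L) {
      # leading pair of a nonnegative matrix is nonnegative up to sign
      if (sum(u) < 0) { u <- -u; v <- -v }
      W0[, 1] <- sv[1] * pmax(u, 0); H0[1, ] <- pmax(v, 0)
      next
    }
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg) {
      if (npos > 0) { W0[, j] <- sv[j] * up; H0[j, ] <- vp }
    } else {
      W0[, j] <- sv[j] * un; H0[j, ] <- vn
    }
  }
  eps <- mean(V) * 1e-6
  W0[W0 <= 0] <- eps; H0[H0 <= 0] <- eps
  list(W = W0, H = H0)
}

#' Factorize a speckle movie into fingerprints and activities
#'
#' Multiplicative-update NMF with Frobenius loss and elementwise L1
#' penalties on both factors. The temporal penalty defaults stronger than
#' the spatial one: calcium-like traces are sparse in time, and a little
#' spatial sparsity yields higher-contrast fingerprints. Sparsity weights
#' are relative to the mean movie intensity, so they are scale-free.
#'
#' @param movie a `speckle_movie`, or a pixels x frames matrix.
#' @param rank number of sources N (>= 1).
#' @param w_sparsity,h_sparsity L1 weights for W and H, relative units.
#' @param seed integer seed (used only for `init = "random"`).
#' @param max_iter maximum multiplicative updates.
#' @param tol relative objective-change convergence tolerance.
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @param frame_shape required when `movie` is a plain matrix.
#' @return a `factorization_result`: `fingerprints` (unit-L2 patterns),
#'   `activities` (scale folded in), `rank`, `residual` (relative Frobenius
#'   reconstruction error), `objective` trace, `n_iter`, `converged`, and
#'   the configuration snapshot.
#' @export
factorize <- function(movie, rank, w_sparsity = 0.001, h_sparsity = 0.01,
                      seed = 1L, max_iter = 200L, tol = 1e-5,
                      init = c("nndsvd", "random"), frame_shape = NULL) {
  init <- match.arg(init)
  if (inherits(movie, "speckle_movie")) {
    frame_shape <- dim(movie$frames)[2:3]
    V <- movie_to_matrix(movie)
  } else {
    V <- movie
    if (is.null(frame_shape)) frame_shape <- c(nrow(V), 1L)
  }
  if (rank < 1L) stopf("rank must be >= 1")
  if (rank > min(dim(V))) stopf("rank %d exceeds min(pixels, frames) = %d",
                                rank, min(dim(V)))
  if (any(V < 0)) stopf("movie must be nonnegative (preprocess first)")
  vscale <- mean(V)
  if (vscale <= 0) stopf("movie is identically zero")
  V <- V / vscale
  lw <- w_sparsity; lh <- h_sparsity
  if (init == "nndsvd") {
    f0 <- nndsvd_init(V, rank)
    W <- f0$W; H <- f0$H
  } else {
    set.seed(sub_seed(seed, "nmf_init"))
    W <- matrix(stats::runif(nrow(V) * rank, 0, 1), ncol = rank)
    H <- matrix(stats::runif(rank * ncol(V), 0, 1), nrow = rank)
  }
  eps <- .Machine$double.eps
  v2 <- sum(V^2)
  obj <- numeric(0)
  prev <- Inf
  n_iter <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # HALS sweeps: each row of H (column of W) is minimized exactly given
    # the others, so the objective is non-increasing per half-sweep
    WtV <- crossprod(W, V)                       # k x T
    WtW <- crossprod(W)
    for (j in seq_len(rank)) {
      if (WtW[j, j] <= 1e-12) { H[j, ] <- 0; next }  # dead component
      num <- WtV[j, ] - WtW[j, -j, drop = FALSE] %*% H[-j, , drop = FALSE] - lh
      H[j, ] <- pmax(num / WtW[j, j], 0)
    }
    # exact objective for (W, H_new) from small matrices
    HHt <- tcrossprod(H)
    o <- 0.5 * (v2 - 2 * sum(H * WtV) +
                  sum(WtW * HHt)) + lw * sum(W) + lh * sum(H)
    VHt <- V %*% t(H)                            # p x k
    for (j in seq_len(rank)) {
      if (HHt[j, j] <= 1e-12) { W[, j] <- 0; next }
      num <- VHt[, j] - W[, -j, drop = FALSE] %*% HHt[-j, j, drop = FALSE] - lw
      W[, j] <- pmax(num / HHt[j, j], 0)
    }
    obj <- c(obj, o)
    if (is.finite(prev) && abs(prev - o) <= tol * abs(prev)) {
      n_iter <- it; converged <- TRUE
      break
    }
    prev <- o
  }
  if (!converged)
    warning(sprintf("NMF did not converge within %d iterations", max_iter))
  # final residual (exact, via trace identities)
  WtV <- crossprod(W, V); WtW <- crossprod(W); HHt <- tcrossprod(H)
  rss <- max(v2 - 2 * sum(H * WtV) + sum(WtW * HHt), 0)
  residual <- sqrt(rss / v2)
  # fold scales: unit-L2 columns of W, movie scale into H
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- sweep(H, 1, nrm, "*") * vscale
  pats <- array(0, dim = c(rank, frame_shape[1], frame_shape[2]))
  for (s in seq_len(rank))
    pats[s, , ] <- unflatten_frame(W[, s], frame_shape)
  structure(list(
    fingerprints = fingerprint_set(pats, normalization = "l2"),
    activities = activity_set(H),
    rank = rank, residual = residual, objective = obj * vscale^2,
    n_iter = n_iter, converged = converged,
    config = list(w_sparsity = w_sparsity, h_sparsity = h_sparsity,
                  seed = seed, max_iter = max_iter, tol = tol, init = init)
  ), class = "factorization_result")
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf(
    "factorization_result: rank %d, residual %.3g, %d iterations%s\n",
    x$rank, x$residual, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Estimate the number of sources by a residual scan over candidate ranks
#'
#' Runs [factorize()] at each candidate rank and picks the elbow of the
#' residual-vs-rank curve: the first rank beyond which the relative residual
#' improvement falls below `epsilon` (or whose residual is already below
#' `res_tol`, the noise-free floor). If the curve is degenerate
#' (non-decreasing), the argmin is returned with a warning.
#'
#' For speed the scan may run on a random subset of pixel rows
#' (`subsample_px`), which preserves the rank structure of the movie.
#'
#' @param movie a `speckle_movie` or pixels x frames matrix.
#' @param rank_grid increasing integer vector of candidate ranks.
#' @param seed integer seed (pixel subsampling and any random init).
#' @param epsilon relative-improvement elbow threshold (default 0.05).
#' @param res_tol residual floor below which a rank is accepted outright.
#' @param subsample_px optional number of pixel rows to scan on.
#' @param max_iter NMF iterations per candidate (scan precision, not final
#'   fit quality).
#' @param ... passed to [factorize()].
#' @return list with `rank` (the estimate), `grid`, `residuals`.
#' @export
estimate_rank <- function(movie, rank_grid, seed = 1L, epsilon = 0.05,
                          res_tol = 1e-3, subsample_px = NULL,
                          max_iter = 100L, ...) {
  if (length(rank_grid) < 1L) stopf("rank_grid must be nonempty")
  rank_grid <- as.integer(sort(rank_grid))
  V <- if (inherits(movie, "speckle_movie")) movie_to_matrix(movie) else movie
  if (!is.null(subsample_px) && subsample_px < nrow(V)) {
    set.seed(sub_seed(seed, "rank_scan"))
    keep <- sort(sample.int(nrow(V), subsample_px))
    V <- V[keep, , drop = FALSE]
  }
  res <- vapply(rank_grid, function(k)
    suppressWarnings(factorize(V, k, seed = seed, max_iter = max_iter,
                               ...))$residual,
    numeric(1))
  sel <- NA_integer_
  for (i in seq_along(rank_grid)) {
    if (res[i] < res_tol) { sel <- rank_grid[i]; break }
    if (i > 1L) {
      improve <- (res[i - 1] - res[i]) / max(res[i - 1], .Machine$double.eps)
      if (improve < epsilon) { sel <- rank_grid[i - 1]; break }
    }
  }
  if (is.na(sel)) sel <- rank_grid[length(rank_grid)]
  if (is.unsorted(rev(res))) {
    # residual should decrease with rank; a non-decreasing stretch that
    # *precedes* the selection indicates a degenerate curve
    first_bad <- which(diff(res) > 0)[1]
    if (!is.na(first_bad) && rank_grid[first_bad] < sel) {
      warning("degenerate residual curve; returning argmin residual")
      sel <- rank_grid[which.min(res)]
    }
  }
  list(rank = sel, grid = rank_grid, residuals = res)
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for the minimal
# assignment of a square cost matrix; returns col index assigned to each row.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' Match factorization output to ground truth
#'
#' NMF recovers sources up to permutation and scale; this resolves the
#' permutation by the optimal one-to-one assignment maximizing the summed
#' Pearson correlation between recovered and true fingerprints, and reports
#' scale-invariant per-source accuracy.
#'
#' @param result a `factorization_result`.
#' @param gt a `ground_truth` with the same number of sources.
#' @return list with `permutation` (`permutation[s]` is the recovered
#'   component matched to true source `s`), `fingerprint_cor`, `trace_cor`
#'   (per true source).
#' @export
match_to_ground_truth <- function(result, gt) {
  stopifnot(inherits(result, "factorization_result"),
            inherits(gt, "ground_truth"))
  n <- dim(gt$fingerprints$patterns)[1]
  if (result$rank < n)
    stopf("rank mismatch: result has %d components, ground truth %d sources",
          result$rank, n)
  Wr <- apply(result$fingerprints$patterns, 1, as.vector)   # px x rank
  Wt <- apply(gt$fingerprints$patterns, 1, as.vector)
  C <- suppressWarnings(stats::cor(Wt, Wr))                  # true x recovered
  C[!is.finite(C)] <- 0                                      # dead components
  # surplus components (e.g. a background component at rank > N) are
  # absorbed by zero-cost dummy rows in the square assignment
  if (result$rank > n)
    C <- rbind(C, matrix(0, result$rank - n, result$rank))
  perm <- hungarian(-C)[seq_len(n)]
  fp_cor <- C[cbind(seq_len(n), perm)]
  tr_cor <- vapply(seq_len(n), function(s) {
    a <- gt$traces$traces[s, ]; b <- result$activities$traces[perm[s], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  list(permutation = perm, fingerprint_cor = fp_cor, trace_cor = tr_cor)
}
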