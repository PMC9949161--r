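# Localization: pairwise Wiener deconvolution of fingerprints, partial
# location maps, and global map stitching.
#
# Within the memory-effect range two fingerprints are laterally shifted
# copies of each other, so their regularized deconvolution is a delta-like
# peak offset from the image center by the shift; beyond the range it is a
# low-amplitude noise-like image.  Pairwise shifts with confidences form a
# graph; confidence-weighted least-squares shift synchronization yields
# positions relative to a reference, valid beyond the memory-effect range
# as long as nearest neighbors stay within it.

# 1-D Tukey (tapered cosine) window
tukey1 <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / alpha + 1)))
  w
}

# mean-subtract and apodize a fingerprint before FFT deconvolution
prep_pattern <- function(w, alpha = 0.25) {
  (w - mean(w)) * outer(tukey1(nrow(w), alpha), tukey1(ncol(w), alpha))
}

#' Wiener deconvolution of one fingerprint by another
#'
#' Computes a regularized frequency-domain deconvolution of `w_j` by `w_i`
#' (both mean-subtracted and Tukey-apodized internally). If
#' `w_i(x) = w_j(x - delta)` — `w_i` is `w_j` translated by `delta` — then
#' `deconvolve_pair(w_j, w_i)` has a dominant peak at `+delta` from the
#' image center. For uncorrelated fingerprints the output is a
#' low-amplitude noise-like image.
#'
#' @param w_i reference fingerprint (the one deconvolved *by*).
#' @param w_j fingerprint whose shift relative to `w_i` is sought.
#' @param balance Wiener regularization, relative to the mean power of
#'   `w_i`'s spectrum (default 0.1).
#' @param alpha Tukey window taper fraction.
#' @return a real matrix, same shape, zero shift at the center pixel
#'   `floor(shape/2) + 1`.
#' @export
deconvolve_pair <- function(w_i, w_j, balance = 0.1, alpha = 0.25) {
  if (!all(dim(w_i) == dim(w_j))) stopf("fingerprints must have equal shapes")
  if (all(w_i == 0) || all(w_j == 0)) stopf("all-zero fingerprint")
  A <- stats::fft(prep_pattern(w_i, alpha))
  B <- stats::fft(prep_pattern(w_j, alpha))
  p <- Mod(A)^2
  D <- Conj(A) * B / (p + balance * mean(p))
  fftshift2(Re(stats::fft(D, inverse = TRUE))) / length(D)
}

#' Extract the shift measurement from a deconvolution image
#'
#' The shift is the argmax location minus the image center; the noise floor
#' is `median + 3 * MAD` of the image excluding a window around the peak,
#' and the pair is flagged `correlated` when `peak / floor` exceeds the
#' threshold.
#'
#' @param decon_image output of [deconvolve_pair()].
#' @param threshold confidence threshold for the `correlated` flag.
#' @param exclude_radius half-width of the window excluded around the peak
#'   when estimating the noise floor.
#' @return list with `shift` (row, col), `peak_amplitude`, `noise_floor`,
#'   `confidence`, `correlated`.
#' @export
extract_peak <- function(decon_image, threshold = 5, exclude_radius = 5L) {
  check_finite(decon_image, "deconvolution image")
  idx <- which.max(decon_image)
  pr <- (idx - 1L) %% nrow(decon_image) + 1L
  pc <- (idx - 1L) %/% nrow(decon_image) + 1L
  ctr <- center_px(dim(decon_image))
  peak <- decon_image[pr, pc]
  mask <- matrix(TRUE, nrow(decon_image), ncol(decon_image))
  rr <- max(1L, pr - exclude_radius):min(nrow(decon_image), pr + exclude_radius)
  cc <- max(1L, pc - exclude_radius):min(ncol(decon_image), pc + exclude_radius)
  mask[rr, cc] <- FALSE
  rest <- decon_image[mask]
  floor_ <- stats::median(rest) + 3 * stats::mad(rest)
  conf <- if (peak <= 0) 0 else if (floor_ > 0) peak / floor_ else Inf
  list(shift = c(pr, pc) - ctr, peak_amplitude = peak, noise_floor = floor_,
       confidence = conf, correlated = conf > threshold)
}

#' Measure all pairwise shifts between fingerprints
#'
#' Deconvolves every ordered pair (i, j), i != j, and extracts the peak;
#' the `shift` column convention is such that for sources within the
#' memory-effect range `shift(i, j) = position(j) - position(i)` in pixels.
#'
#' @param fingerprints a `fingerprint_set` or `N x H x W` array.
#' @param balance Wiener regularization (see [deconvolve_pair()]).
#' @param threshold correlated-pair confidence threshold.
#' @param alpha Tukey taper fraction.
#' @param common_mode subtract the across-source mean fingerprint before
#'   deconvolving (suppresses spurious zero-shift peaks caused by shared
#'   residual structure; the estimate leaks `1/n` of each true pattern, so
#'   it is applied only when five or more sources are present).
#' @return a `shift_graph`: data frame with columns `i`, `j`, `drow`,
#'   `dcol`, `peak`, `noise_floor`, `confidence`, `correlated`; attribute
#'   `n_sources`.
#' @export
measure_shifts <- function(fingerprints, balance = 0.1, threshold = 5,
                           alpha = 0.25, common_mode = TRUE) {
  fps <- if (inherits(fingerprints, "fingerprint_set"))
    fingerprints$patterns else fingerprints
  n <- dim(fps)[1]
  # factorization components share any structure the factorization could
  # not attribute to a single source (residual background, baseline mix);
  # this common mode produces spurious zero-shift deconvolution peaks, so
  # it is projected out before the pairwise analysis.  The estimate (the
  # across-component mean) leaks 1/n of each true pattern, so it is only
  # subtracted when enough components are present
  cm <- if (common_mode && n >= 5L) colMeans(fps, dims = 1) else 0
  # cache spectra of the prepped patterns
  specs <- lapply(seq_len(n), function(s)
    stats::fft(prep_pattern(fps[s, , ] - cm, alpha)))
  pows <- lapply(specs, function(A) Mod(A)^2)
  dead <- vapply(pows, function(p) mean(p) <= 0, logical(1))
  rows <- vector("list", n * (n - 1L))
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (dead[i] || dead[j]) {
      # an all-zero (dead) component carries no shift information
      k <- k + 1L
      rows[[k]] <- data.frame(i = i, j = j, drow = 0, dcol = 0, peak = 0,
                              noise_floor = 0, confidence = 0,
                              correlated = FALSE)
      next
    }
    D <- Conj(specs[[i]]) * specs[[j]] / (pows[[i]] + balance * mean(pows[[i]]))
    img <- fftshift2(Re(stats::fft(D, inverse = TRUE))) / length(D)
    pk <- extract_peak(img, threshold = threshold)
    k <- k + 1L
    rows[[k]] <- data.frame(i = i, j = j, drow = pk$shift[1], dcol = pk$shift[2],
                            peak = pk$peak_amplitude,
                            noise_floor = pk$noise_floor,
                            confidence = pk$confidence,
                            correlated = pk$correlated)
  }
  out <- if (k > 0L) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), drow = numeric(0),
               dcol = numeric(0), peak = numeric(0), noise_floor = numeric(0),
               confidence = numeric(0), correlated = logical(0))
  attr(out, "n_sources") <- n
  class(out) <- c("shift_graph", class(out))
  out
}

#' Partial location map of one source
#'
#' The sum of the deconvolutions of source `s`'s fingerprint against every
#' fingerprint (itself included): correlated neighbors produce peaks at
#' their relative offsets, uncorrelated sources only add a low noise floor.
#'
#' @param s source index.
#' @param fingerprints a `fingerprint_set` or `N x H x W` array.
#' @param balance,alpha see [deconvolve_pair()].
#' @return a 2-D map image centered on source `s`.
#' @export
build_partial_map <- function(s, fingerprints, balance = 0.1, alpha = 0.25) {
  fps <- if (inherits(fingerprints, "fingerprint_set"))
    fingerprints$patterns else fingerprints
  n <- dim(fps)[1]
  Reduce(`+`, lapply(seq_len(n), function(i)
    deconvolve_pair(fps[s, , ], fps[i, , ], balance = balance, alpha = alpha)))
}

# connected components by breadth-first search over an undirected edge list
graph_components <- function(n, edges) {
  comp <- integer(n)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
    }
  }
  comp
}

#' Solve global source positions from pairwise shifts
#'
#' Confidence-weighted least-squares shift synchronization: positions `p`
#' minimize `sum over correlated edges of conf * ||(p_j - p_i) - shift_ij||^2`
#' with the reference source pinned at (0, 0). On a tree this reproduces
#' exact path composition. Sources outside the reference's connected
#' component are reported unplaced (`NA` positions).
#'
#' @param graph a `shift_graph` from [measure_shifts()].
#' @param reference reference source id (position (0, 0)).
#' @param prune_px prune correlated edges whose residual against the
#'   least-squares solution exceeds this many pixels (iteratively, worst
#'   first, never disconnecting the graph); set `Inf` to disable.
#' @return list with `positions` (N x 2 matrix, row/col px), `placed`
#'   logical vector, `unplaced` ids, and the weighted RMS edge `residual`.
#' @export
solve_global_positions <- function(graph, reference = 1L, prune_px = 3) {
  n <- attr(graph, "n_sources")
  if (is.null(n)) n <- max(graph$i, graph$j)
  ed <- graph[graph$correlated & graph$i != graph$j, , drop = FALSE]
  if (nrow(ed) == 0L && n > 1L)
    stopf("no correlated pairs; cannot place any source")
  repeat {
    sol <- solve_positions_once(n, ed, reference)
    if (!is.finite(prune_px) || nrow(ed) == 0L) return(sol)
    # residual of each edge against the current solution
    r <- vapply(seq_len(nrow(ed)), function(k) {
      pi_ <- sol$positions[ed$i[k], ]; pj <- sol$positions[ed$j[k], ]
      if (any(is.na(pi_)) || any(is.na(pj))) return(0)
      sqrt(sum(((pj - pi_) - c(ed$drow[k], ed$dcol[k]))^2))
    }, numeric(1))
    if (max(r) <= prune_px) return(sol)
    # drop the worst inconsistent undirected pair unless that disconnects
    # any currently placed node
    ord <- order(r, decreasing = TRUE)
    dropped <- FALSE
    for (k in ord) {
      if (r[k] <= prune_px) break
      keep <- !((ed$i == ed$i[k] & ed$j == ed$j[k]) |
                  (ed$i == ed$j[k] & ed$j == ed$i[k]))
      comp_new <- graph_components(n, ed[keep, , drop = FALSE])
      same_comp <- comp_new[sol$placed] == comp_new[reference]
      if (all(same_comp)) { ed <- ed[keep, , drop = FALSE]; dropped <- TRUE; break }
    }
    if (!dropped) return(sol)
  }
}

solve_positions_once <- function(n, ed, reference) {
  comp <- graph_components(n, ed)
  placed <- comp == comp[reference]
  ids <- which(placed)
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  if (length(ids) == 1L) {
    pos[reference, ] <- c(0, 0)
  } else {
    idx <- match(seq_len(n), ids)          # node -> unknown index
    m <- length(ids)
    L <- matrix(0, m, m)
    b <- matrix(0, m, 2)
    for (k in seq_len(nrow(ed))) {
      i <- idx[ed$i[k]]; j <- idx[ed$j[k]]
      if (is.na(i) || is.na(j)) next
      wgt <- ed$confidence[k]
      L[i, i] <- L[i, i] + wgt; L[j, j] <- L[j, j] + wgt
      L[i, j] <- L[i, j] - wgt; L[j, i] <- L[j, i] - wgt
      s <- c(ed$drow[k], ed$dcol[k])
      b[j, ] <- b[j, ] + wgt * s
      b[i, ] <- b[i, ] - wgt * s
    }
    r <- idx[reference]
    keep <- setdiff(seq_len(m), r)
    sol <- solve(L[keep, keep, drop = FALSE], b[keep, , drop = FALSE])
    full <- matrix(0, m, 2)
    full[keep, ] <- sol
    pos[ids, ] <- full
  }
  res2 <- 0; wsum <- 0
  for (k in seq_len(nrow(ed))) {
    pi_ <- pos[ed$i[k], ]; pj <- pos[ed$j[k], ]
    if (any(is.na(pi_)) || any(is.na(pj))) next
    dv <- (pj - pi_) - c(ed$drow[k], ed$dcol[k])
    res2 <- res2 + ed$confidence[k] * sum(dv^2)
    wsum <- wsum + ed$confidence[k]
  }
  list(positions = pos, placed = placed, unplaced = which(!placed),
       residual = if (wsum > 0) sqrt(res2 / wsum) else 0,
       reference = reference)
}

#' Render the stitched global location map
#'
#' Accumulates each source's partial map translated by its solved position
#' (Eq.-style shifted accumulation), on a canvas large enough to hold the
#' whole ensemble, and reports the discrete position list alongside.
#'
#' @param positions output of [solve_global_positions()].
#' @param partial_maps list of 2-D partial maps, one per source (unplaced
#'   sources may be `NULL`).
#' @return a `location_map`: `map_image`, `positions_px` (relative to the
#'   reference), `reference_id`, `origin` (canvas pixel of position (0,0)).
#' @export
render_map <- function(positions, partial_maps) {
  pos <- positions$positions
  placed <- which(positions$placed)
  if (!length(placed)) stopf("no sources placed")
  shp <- dim(partial_maps[[placed[1]]])
  rmin <- floor(min(pos[placed, 1])); rmax <- ceiling(max(pos[placed, 1]))
  cmin <- floor(min(pos[placed, 2])); cmax <- ceiling(max(pos[placed, 2]))
  canvas <- c(shp[1] + (rmax - rmin), shp[2] + (cmax - cmin))
  map <- matrix(0, canvas[1], canvas[2])
  for (s in placed) {
    dr <- round(pos[s, 1]) - rmin; dc <- round(pos[s, 2]) - cmin
    map[(1:shp[1]) + dr, (1:shp[2]) + dc] <-
      map[(1:shp[1]) + dr, (1:shp[2]) + dc] + partial_maps[[s]]
  }
  structure(list(map_image = map, positions_px = pos,
                 reference_id = positions$reference,
                 origin = center_px(shp) - c(rmin, cmin)),
            class = "location_map")
}

#' @export
print.location_map <- function(x, ...) {
  cat(sprintf("location_map: %d x %d px canvas, %d/%d sources placed (ref %d)\n",
              nrow(x$map_image), ncol(x$map_image),
              sum(stats::complete.cases(x$positions_px)), nrow(x$positions_px),
              x$reference_id))
  invisible(x)
}

#' Localize all sources from their fingerprints
#'
#' Full localization chain: pairwise deconvolutions, shift graph, global
#' least-squares positions, stitched map.
#'
#' @param fingerprints a `fingerprint_set` or `N x H x W` array.
#' @param balance Wiener regularization.
#' @param threshold correlated-pair confidence threshold.
#' @param reference reference source id, or `"auto"` (the node with the
#'   highest summed edge confidence).
#' @param render build the stitched map image (set `FALSE` to skip the
#'   partial-map accumulation and keep only positions).
#' @return list with `graph`, `positions` (from
#'   [solve_global_positions()]), and `map` (a `location_map` or `NULL`).
#' @export
localize_fingerprints <- function(fingerprints, balance = 0.1, threshold = 5,
                                  reference = "auto", render = TRUE) {
  fps <- if (inherits(fingerprints, "fingerprint_set"))
    fingerprints$patterns else fingerprints
  n <- dim(fps)[1]
  graph <- measure_shifts(fps, balance = balance, threshold = threshold)
  if (identical(reference, "auto")) {
    ed <- graph[graph$correlated, , drop = FALSE]
    score <- vapply(seq_len(n), function(s)
      sum(ed$confidence[ed$i == s | ed$j == s]), numeric(1))
    reference <- which.max(score)
  }
  if (n == 1L) {
    positions <- list(positions = matrix(0, 1, 2,
                                         dimnames = list(NULL, c("row", "col"))),
                      placed = TRUE, unplaced = integer(0), residual = 0,
                      reference = 1L)
  } else {
    positions <- solve_global_positions(graph, reference = reference)
  }
  map <- NULL
  if (render) {
    pmaps <- lapply(seq_len(n), function(s)
      if (positions$placed[s]) build_partial_map(s, fps, balance = balance)
      else NULL)
    map <- render_map(positions, pmaps)
  }
  list(graph = graph, positions = positions, map = map)
}
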