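# End-to-end orchestration: configuration, simulate -> preprocess ->
# rank estimation -> factorization -> localization -> evaluation, plus a
# parameter-sweep harness.

#' Build a run configuration
#'
#' Returns the full nested configuration for [run_pipeline()], optionally
#' starting from one of three named experiment presets that mirror the
#' package's reference simulations at desk scale:
#' \describe{
#'   \item{"plain"}{19 sources, 500 frames, 256 x 256 px, all within the
#'     memory-effect range, moderate shot noise, no background.}
#'   \item{"background"}{10 sources, 500 frames, 128 x 128 px, constant
#'     background speckle at signal-to-background ratio 1.6.}
#'   \item{"beyond-me"}{8 sources along a jittered chain spanning 1.7x the
#'     memory-effect range, nearest-neighbor spacing well inside it.}
#' }
#'
#' @param preset `NULL` (small default run) or one of `"plain"`,
#'   `"background"`, `"beyond-me"`.
#' @param seed master seed for the whole run.
#' @param ... named overrides applied on top, using dotted paths (e.g.
#'   `simulate.sbr = 4`, `demix.rank = 10`).
#' @return a `run_config` (nested named list).
#' @export
run_config <- function(preset = NULL, seed = 1L, ...) {
  cfg <- list(
    experiment = preset %||% "default",
    seed = as.integer(seed),
    simulate = list(
      n_sources = 5L, n_frames = 200L, frame_shape = c(128L, 128L),
      me_range_um = 40, speckle_grain_px = 4, pixel_pitch_um = 1,
      geometry = "random", span_um = 26, min_spacing_um = 6,
      jitter_um = 4,
      spike_rate_per_frame = 0.02, decay_frames = 10, baseline = 0.1,
      amplitude = 1, sbr = Inf, photon_budget = Inf, read_noise_sd = 0,
      frame_period_s = 0.5
    ),
    # offset mode in the pipeline: the synthetic world has no smooth
    # envelope, and clipping half the filtered values is a nonlinearity
    # that can push the factorization into poor optima (see vignette)
    preprocess = list(enabled = TRUE, sigma_px = 16, clip_mode = "offset"),
    demix = list(rank = "auto", rank_grid = NULL, w_sparsity = 0.001,
                 h_sparsity = 0.01, max_iter = 200L, tol = 1e-5,
                 scan_max_iter = 60L, scan_subsample_px = 8192L,
                 epsilon = 0.05, init = "nndsvd"),
    localize = list(balance = 0.1, threshold = 5, reference = "auto",
                    render = TRUE),
    evaluate = list(placement_tol_px = 2),
    output_dir = NULL
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("plain", "background", "beyond-me"))
    ov <- switch(preset,
      plain = list(simulate.n_sources = 19L, simulate.n_frames = 500L,
                   simulate.frame_shape = c(256L, 256L),
                   simulate.me_range_um = 55, simulate.span_um = 36,
                   simulate.min_spacing_um = 6,
                   simulate.photon_budget = 1000, simulate.read_noise_sd = 2),
      background = list(simulate.n_sources = 10L, simulate.n_frames = 500L,
                        simulate.frame_shape = c(128L, 128L),
                        simulate.me_range_um = 40, simulate.span_um = 26,
                        simulate.min_spacing_um = 6, simulate.sbr = 1.6,
                        simulate.photon_budget = 1000,
                        simulate.read_noise_sd = 2),
      `beyond-me` = list(simulate.n_sources = 8L, simulate.n_frames = 300L,
                         simulate.frame_shape = c(128L, 128L),
                         simulate.me_range_um = 30,
                         simulate.geometry = "path",
                         simulate.span_um = 51, simulate.jitter_um = 6,
                         simulate.photon_budget = 1000,
                         simulate.read_noise_sd = 2))
    cfg <- set_config(cfg, ov)
  }
  cfg <- set_config(cfg, list(...))
  class(cfg) <- "run_config"
  cfg
}

# apply named dotted-path overrides to a nested list
set_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg[[path]] <- overrides[[nm]]
  }
  cfg
}

#' Write / read a run configuration as JSON
#'
#' Round-trips exactly: `read_config(write_config(cfg, path))` compares
#' equal to `cfg`.
#'
#' @param cfg a `run_config`.
#' @param path file path (conventionally `config.json`).
#' @return `write_config`: `path` invisibly; `read_config`: a `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has no Inf: jsonlite writes it as string
  for (f in c("sbr", "photon_budget"))
    cfg$simulate[[f]] <- as.numeric(cfg$simulate[[f]])
  cfg$simulate$frame_shape <- as.integer(cfg$simulate$frame_shape)
  if (!is.null(cfg$demix$rank_grid))
    cfg$demix$rank_grid <- as.integer(cfg$demix$rank_grid)
  class(cfg) <- "run_config"
  cfg
}

# build simulation inputs from a config
simulate_from_config <- function(cfg) {
  sc <- cfg$simulate
  ens <- if (identical(sc$geometry, "path")) {
    path_ensemble(sc$n_sources, sc$span_um, jitter_um = sc$jitter_um,
                  seed = cfg$seed, pixel_pitch_um = sc$pixel_pitch_um)
  } else {
    random_ensemble(sc$n_sources, sc$span_um,
                    min_spacing_um = sc$min_spacing_um, seed = cfg$seed,
                    pixel_pitch_um = sc$pixel_pitch_um)
  }
  scat <- scatter_model(sc$me_range_um, sc$speckle_grain_px, sc$frame_shape,
                        master_seed = cfg$seed)
  tm <- trace_model(sc$n_frames, sc$spike_rate_per_frame, sc$decay_frames,
                    sc$baseline, sc$amplitude)
  bg <- background_model(sc$sbr %||% Inf)
  simulate_movie(ens, scat, tm, background = bg,
                 photon_budget = sc$photon_budget,
                 read_noise_sd = sc$read_noise_sd,
                 frame_period_s = sc$frame_period_s)
}

#' Run the full pipeline on a configuration
#'
#' Simulates (or loads) a movie, preprocesses it, estimates the rank if
#' requested, factorizes, localizes, and — when ground truth is available —
#' evaluates recovery. When `cfg$output_dir` is set, all artifacts (movie
#' and fingerprints as multi-page TIFF, traces/shifts/positions as CSV,
#' report as JSON, the exact configuration next to them) are written there.
#'
#' @param cfg a `run_config` from [run_config()].
#' @param movie optionally, a pre-made `speckle_movie` to analyze instead
#'   of simulating one.
#' @param gt optional `ground_truth` matching `movie`.
#' @param verbose print per-stage progress.
#' @return an `evaluation_report`: per-source trace correlations and
#'   localization errors (px and um), `fraction_placed`, `rank_estimated`
#'   vs `rank_true`, `sbr_measured`, per-stage `runtime_s`, plus the
#'   factorization and localization objects.
#' @export
run_pipeline <- function(cfg, movie = NULL, gt = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- tic()
  if (is.null(movie)) {
    say("simulate: N=%d, T=%d", cfg$simulate$n_sources, cfg$simulate$n_frames)
    sim <- simulate_from_config(cfg)
    movie <- sim$movie; gt <- sim$gt
  }
  times["simulate"] <- tic() - t0

  t0 <- tic()
  work <- movie
  if (isTRUE(cfg$preprocess$enabled)) {
    say("preprocess: sigma=%g", cfg$preprocess$sigma_px)
    work <- preprocess_movie(movie, cfg$preprocess$sigma_px,
                             mode = cfg$preprocess$clip_mode)
  }
  times["preprocess"] <- tic() - t0

  t0 <- tic()
  dm <- cfg$demix
  rank_scan <- NULL
  if (identical(dm$rank, "auto")) {
    n_hint <- if (!is.null(gt)) dim(gt$fingerprints$patterns)[1] else 8L
    grid <- dm$rank_grid %||% seq(max(1L, n_hint - 4L), n_hint + 4L)
    say("estimate_rank: grid %s", paste(range(grid), collapse = ":"))
    # rank is a property of the recorded dataset: scan the movie as
    # recorded, not the clipped high-passed version (clipping is a
    # nonlinearity that inflates numerical rank)
    rank_scan <- estimate_rank(movie, grid, seed = cfg$seed,
                               epsilon = dm$epsilon,
                               subsample_px = dm$scan_subsample_px,
                               max_iter = dm$scan_max_iter,
                               w_sparsity = dm$w_sparsity,
                               h_sparsity = dm$h_sparsity, init = dm$init)
    rank <- rank_scan$rank
  } else rank <- as.integer(dm$rank)
  times["rank"] <- tic() - t0

  t0 <- tic()
  say("factorize: rank %d", rank)
  fact <- suppressWarnings(
    factorize(work, rank, w_sparsity = dm$w_sparsity,
              h_sparsity = dm$h_sparsity, seed = cfg$seed,
              max_iter = dm$max_iter, tol = dm$tol, init = dm$init))
  times["factorize"] <- tic() - t0

  t0 <- tic()
  lc <- cfg$localize
  say("localize: %d components", rank)
  loc <- localize_fingerprints(fact$fingerprints, balance = lc$balance,
                               threshold = lc$threshold,
                               reference = lc$reference, render = lc$render)
  times["localize"] <- tic() - t0

  report <- evaluate_run(fact, loc, gt, rank_scan = rank_scan,
                         placement_tol_px = cfg$evaluate$placement_tol_px %||% 2,
                         pixel_pitch_um = movie$pixel_pitch_um)
  report$runtime_s <- times
  report$config <- cfg
  report$factorization <- fact
  report$localization <- loc
  report$movie <- movie
  report$gt <- gt
  class(report) <- "evaluation_report"
  if (!is.null(cfg$output_dir)) write_artifacts(report, cfg)
  report
}

# compare recovered factors/positions with ground truth (when present)
evaluate_run <- function(fact, loc, gt, rank_scan = NULL,
                         placement_tol_px = 2, pixel_pitch_um = 1) {
  rep <- list(rank_estimated = fact$rank,
              rank_scan = rank_scan,
              residual = fact$residual,
              fraction_placed = mean(loc$positions$placed))
  if (is.null(gt)) return(rep)
  n <- dim(gt$fingerprints$patterns)[1]
  rep$rank_true <- n
  rep$sbr_measured <- if (sum(gt$background_frame) > 0) measure_sbr(gt) else Inf
  if (fact$rank >= n) {
    m <- match_to_ground_truth(fact, gt)
    rep$match <- m
    rep$trace_cor <- m$trace_cor
    rep$fingerprint_cor <- m$fingerprint_cor
    # localization error of the matched components, translation-aligned
    rec <- loc$positions$positions[m$permutation, , drop = FALSE]
    placed <- loc$positions$placed[m$permutation]
    rep$fraction_placed <- mean(placed)
    gt_pos <- gt$positions_px
    if (sum(placed) >= 1) {
      off <- colMeans(rec[placed, , drop = FALSE] -
                        gt_pos[placed, , drop = FALSE])
      err <- sqrt(rowSums((sweep(rec, 2, off) - gt_pos)^2))
      err[!placed] <- NA_real_
      rep$position_error_px <- err
      rep$position_error_um <- err * pixel_pitch_um
      rep$all_placed_within_tol <-
        all(placed) && all(err <= placement_tol_px)
    } else {
      rep$position_error_px <- rep(NA_real_, n)
      rep$position_error_um <- rep(NA_real_, n)
      rep$all_placed_within_tol <- FALSE
    }
  } else {
    rep$all_placed_within_tol <- FALSE
  }
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: rank %d%s, residual %.3g, %.0f%% placed\n",
              x$rank_estimated,
              if (!is.null(x$rank_true)) sprintf(" (true %d)", x$rank_true) else "",
              x$residual, 100 * x$fraction_placed))
  if (!is.null(x$trace_cor))
    cat(sprintf("  trace correlation: min %.3f median %.3f\n",
                min(x$trace_cor), stats::median(x$trace_cor)))
  if (!is.null(x$position_error_px) && any(is.finite(x$position_error_px)))
    cat(sprintf("  position error: max %.2f px (aligned); within tol: %s\n",
                max(x$position_error_px, na.rm = TRUE),
                x$all_placed_within_tol))
  cat(sprintf("  runtime: %.1f s total\n", sum(x$runtime_s)))
  invisible(x)
}

# write movie/fingerprints (TIFF), traces/shift table/positions (CSV),
# report (JSON) and the exact configuration into cfg$output_dir
write_artifacts <- function(report, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(f) file.path(cfg$output_dir, f)
  write_config(cfg, od("config.json"))
  write_tiff(report$movie$frames, od("movie.tif"))
  write_tiff(report$factorization$fingerprints$patterns, od("fingerprints.tif"))
  utils::write.csv(report$factorization$activities$traces, od("traces.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$localization$graph), od("shifts.csv"),
                   row.names = FALSE)
  pos <- report$localization$positions
  utils::write.csv(data.frame(source_id = seq_len(nrow(pos$positions)),
                              row_px = pos$positions[, 1],
                              col_px = pos$positions[, 2],
                              placed = pos$placed),
                   od("positions.csv"), row.names = FALSE)
  if (!is.null(report$localization$map))
    write_tiff(report$localization$map$map_image, od("location_map.tif"))
  if (!is.null(report$gt)) {
    utils::write.csv(report$gt$traces$traces, od("gt_traces.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(source_id = seq_len(nrow(report$gt$positions_px)),
                                x_um = report$gt$ensemble$positions_um[, 1],
                                y_um = report$gt$ensemble$positions_um[, 2],
                                row_px_shift = report$gt$positions_px[, 1],
                                col_px_shift = report$gt$positions_px[, 2]),
                     od("gt_positions.csv"), row.names = FALSE)
  }
  summary_fields <- c("rank_estimated", "rank_true", "residual",
                      "fraction_placed", "sbr_measured", "trace_cor",
                      "position_error_px", "all_placed_within_tol")
  jsonlite::write_json(report[intersect(summary_fields, names(report))],
                       od("report.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(cfg$output_dir)
}

#' Sweep one configuration parameter over a set of values
#'
#' Runs [run_pipeline()] for the cross-product of `values` and `seeds` and
#' returns a tidy long-format table (one row per run), suitable for
#' success-vs-SBR or error-vs-span curves.
#'
#' @param cfg template `run_config`.
#' @param parameter dotted path into the config (e.g. `"simulate.sbr"`).
#' @param values vector of values to sweep.
#' @param seeds integer vector of per-run master seeds.
#' @param verbose print progress.
#' @return a data frame with columns `parameter`, `value`, `seed`,
#'   `rank_estimated`, `rank_true`, `fraction_placed`, `success` (all
#'   sources placed within tolerance), `min_trace_cor`, `max_position_error_px`,
#'   `sbr_measured`, `runtime_s`.
#' @export
sweep_parameter <- function(cfg, parameter, values, seeds = 1L,
                            verbose = FALSE) {
  rows <- list()
  for (v in values) for (sd in seeds) {
    cfg_i <- set_config(cfg, stats::setNames(list(v), parameter))
    cfg_i$seed <- as.integer(sd)
    class(cfg_i) <- "run_config"
    rep <- tryCatch(run_pipeline(cfg_i, verbose = verbose),
                    error = function(e) e)
    if (inherits(rep, "error")) {
      # a failed point is a failed point, not a failed sweep
      warning(sprintf("run (%s = %g, seed %d) failed: %s", parameter, v, sd,
                      conditionMessage(rep)))
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parameter, value = v, seed = sd,
        rank_estimated = NA_integer_, rank_true = NA_integer_,
        fraction_placed = 0, success = FALSE, min_trace_cor = NA_real_,
        max_position_error_px = NA_real_, sbr_measured = NA_real_,
        runtime_s = NA_real_)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = parameter, value = v, seed = sd,
      rank_estimated = rep$rank_estimated,
      rank_true = rep$rank_true %||% NA_integer_,
      fraction_placed = rep$fraction_placed,
      success = isTRUE(rep$all_placed_within_tol),
      min_trace_cor = if (!is.null(rep$trace_cor)) min(rep$trace_cor) else NA_real_,
      max_position_error_px =
        if (!is.null(rep$position_error_px) &&
            any(is.finite(rep$position_error_px)))
          max(rep$position_error_px, na.rm = TRUE) else NA_real_,
      sbr_measured = rep$sbr_measured %||% NA_real_,
      runtime_s = sum(rep$runtime_s))
  }
  do.call(rbind, rows)
}
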