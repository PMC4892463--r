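# Umbrella pipeline: simulate (optional) -> detect -> link -> evaluate
# (when ground truth is available) -> analyse, writing every artefact to
# disk. Fixed seed implies identical outputs.

#' Run the full tracking pipeline
#'
#' Stages, in order: synthetic-movie generation (optional), particle
#' detection (with optional adaptive parameter refinement and per-frame
#' carry-over of the expected particle count), trajectory linking,
#' evaluation against ground truth (when supplied or simulated), and
#' trajectory motion analysis. Each stage logs its parameters and counts;
#' artefacts are written under `config$output_dir`.
#'
#' @param config a `pipeline_config` ([read_config()]).
#' @param quiet suppress stage logging.
#' @return named list of the artefact paths written, invisibly; the loaded
#'   objects are attached as attributes `stack`, `detections`, `tracks`,
#'   `report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  truth <- NULL
  order_of <- c(simulate = 1L, detect = 2L, link = 3L, evaluate = 4L,
                analyze = 5L)
  stop_at <- order_of[[config$stop_after]]

  # --- simulate or load ---
  if (isTRUE(config$simulate$enabled)) {
    sim <- tryCatch({
      sc <- config$simulate
      motion <- motion_spec(sc$motion, step_sd = sc$step_sd,
                            drift = sc$drift, cage_radius = sc$cage_radius)
      noise <- if (isTRUE(sc$noise$enabled)) {
        do.call(noise_spec, sc$noise[setdiff(names(sc$noise), "enabled")])
      } # else NULL: noise-free movie using the amplitude directly
      simulate_movie(sc$n_tracks, sc$n_frames, sc$shape, motion,
                     seed = config$seed,
                     snr = if (is.null(noise)) NULL else sc$snr,
                     background = sc$background, noise = noise,
                     psf_sigma = sc$psf_sigma, amplitude = sc$amplitude)
    }, error = function(e) fail("simulate", e))
    stack <- sim$stack
    truth <- sim$truth
    paths$movie <- file.path(config$output_dir, "movie.tif")
    paths$truth <- file.path(config$output_dir, "truth.csv")
    write_stack(stack, paths$movie)
    write_truth(truth, paths$truth)
    log_msg("simulate", "%d tracks, %d frames, %dx%d px -> %s",
            config$simulate$n_tracks, config$simulate$n_frames,
            config$simulate$shape[1L], config$simulate$shape[2L],
            paths$movie)
  } else {
    if (is.null(config$input)) stop("config$input required when not simulating")
    stack <- tryCatch(read_stack(config$input),
                      error = function(e) fail("input", e))
    if (!is.null(config$truth)) truth <- read_truth(config$truth)
    log_msg("input", "%d frames from %s", length(stack$frames), config$input)
  }
  if (stop_at < order_of[["detect"]]) {
    return(invisible(structure(paths, stack = stack)))
  }

  # --- detect ---
  dc <- config$detect
  params <- detection_params(dc$S, dc$s, dc$N, dc$density, dc$snr)
  log_msg("detect", "S=%g s=%g N=%g density=%s snr=%g F=%.3f adaptive=%s",
          params$S, params$s, params$N, params$density, params$snr,
          params$F, dc$adaptive)
  detections <- tryCatch(
    detect_stack(stack, params, adaptive = isTRUE(dc$adaptive),
                 carry_n = isTRUE(dc$carry_n)),
    error = function(e) fail("detect", e))
  paths$detections <- file.path(config$output_dir, "detections.csv")
  write_detections(detections, paths$detections)
  log_msg("detect", "%d detections over %d frames -> %s", nrow(detections),
          length(stack$frames), paths$detections)
  if (stop_at < order_of[["link"]]) {
    return(invisible(structure(paths, stack = stack, detections = detections)))
  }

  # --- link ---
  lc <- config$link
  lp <- link_params(max_dist = lc$max_dist, min_length = lc$min_length,
                    max_gap = lc$max_gap, lambda = lc$lambda,
                    meas_sd = lc$meas_sd)
  tracks <- tryCatch(link_tracks(detections, lp),
                     error = function(e) fail("link", e))
  paths$tracks <- file.path(config$output_dir, "tracks.csv")
  write_tracks(tracks, paths$tracks)
  log_msg("link", "%d tracks (min length %d) -> %s",
          length(unique(tracks$track_id)), lp$min_length, paths$tracks)

  # --- evaluate ---
  report <- NULL
  if (!is.null(truth) && stop_at >= order_of[["evaluate"]]) {
    radius <- config$evaluate$radius
    if (is.null(radius)) radius <- 2 * sqrt(config$detect$S / pi)
    spec <- matching_spec(radius = radius, theta = config$evaluate$theta)
    report <- tryCatch(evaluate_tracking(tracks, truth, spec),
                       error = function(e) fail("evaluate", e))
    paths$report <- file.path(config$output_dir, "report.json")
    write_report(report, paths$report)
    log_msg("evaluate", "TPR=%.3f FPR=%.3f RMSE=%.3f JSC=%.3f -> %s",
            report$tpr, report$fpr, report$rmse, report$jsc, paths$report)
  }
  if (stop_at < order_of[["analyze"]]) {
    return(invisible(structure(paths, stack = stack, detections = detections,
                               tracks = tracks, report = report)))
  }

  # --- analyse ---
  if (isTRUE(config$analyze$enabled) && nrow(tracks) > 0L) {
    nb <- config$analyze$n_angle_bins
    sa <- step_angles(tracks)
    th2 <- switch_angles(tracks)
    rose1 <- rose_histogram(sa$theta1, sa$length, n_angle_bins = nb,
                            domain = c(0, 360))
    rose2 <- rose_histogram(th2$theta2, n_angle_bins = max(4L, nb %/% 2L),
                            domain = c(0, 180))
    shape <- dim(stack$frames[[1L]])
    dens <- track_density(tracks, shape)
    paths$rose_theta1 <- file.path(config$output_dir, "rose_theta1.csv")
    paths$rose_theta2 <- file.path(config$output_dir, "rose_theta2.csv")
    paths$density <- file.path(config$output_dir, "track_density.tif")
    write_rose(rose1, paths$rose_theta1)
    write_rose(rose2, paths$rose_theta2)
    write_stack(frame_stack(list(dens), bit_depth = 16L), paths$density)
    log_msg("analyze", "%d steps, %d switch angles, density max %d",
            sum(rose1$counts), sum(rose2$counts), max(dens))
  }
  invisible(structure(paths, stack = stack, detections = detections,
                      tracks = tracks, report = report))
}

#' Write a rose histogram as CSV (bin edges plus counts)
#'
#' @param rose a `rose_histogram`.
#' @param path output path.
#' @export
write_rose <- function(rose, path) {
  nb <- nrow(rose$counts); nl <- ncol(rose$counts)
  df <- data.frame(
    angle_lo = rep(rose$angle_edges[seq_len(nb)], nl),
    angle_hi = rep(rose$angle_edges[seq_len(nb) + 1L], nl),
    length_lo = rep(rose$length_edges[seq_len(nl)], each = nb),
    length_hi = rep(rose$length_edges[seq_len(nl) + 1L], each = nb),
    count = as.vector(rose$counts))
  write_csv_atomic(df, path)
}
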