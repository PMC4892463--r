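# File formats: multi-page TIFF movies, CSV interchange for ground truth,
# detections and tracks, ISBI-challenge-style XML track export/import, and
# YAML/JSON pipeline configuration. All writes are atomic
# (write-temp-then-rename).

#' @keywords internal
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path path to an 8- or 16-bit greyscale TIFF.
#' @return a `frame_stack` with grey levels on their native integer scale.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1L]])
  bits <- info$bits.per.sample
  if (is.null(bits)) bits <- 8L
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      stop("format error: TIFF has ", dim(p)[3L],
           " channels; greyscale required")
    }
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  frame_stack(frames, bit_depth = as.integer(bits))
}

#' Write a frame stack as a multi-page TIFF
#'
#' Values are clipped to the bit-depth range and rounded.
#'
#' @param stack a `frame_stack`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  top <- 2^stack$bit_depth - 1
  norm <- lapply(stack$frames, function(f) {
    round(pmin(pmax(f, 0), top)) / top
  })
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(norm, tmp, bits.per.sample = stack$bit_depth,
                    compression = "none")
  })
}

#' @keywords internal
write_csv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' @keywords internal
read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, " file ", path,
         ": missing column(s) ", paste(missing, collapse = ", "))
  }
  df
}

#' Read / write ground-truth tables
#'
#' CSV schema: `track_id,frame,x,y,amplitude,sigma`.
#'
#' @param path file path.
#' @param truth a `ground_truth` table.
#' @name truth_io
#' @export
read_truth <- function(path) {
  df <- read_csv_checked(path, c("track_id", "frame", "x", "y"), "ground truth")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ground_truth", "data.frame")
  df
}

#' @rdname truth_io
#' @export
write_truth <- function(truth, path) {
  write_csv_atomic(as.data.frame(truth), path)
}

#' Read / write detection tables
#'
#' CSV schema: `frame,x,y,area,circularity,major_axis,minor_axis,
#' mean_intensity,peak_intensity`.
#'
#' @param path file path.
#' @param detections a `detections` table.
#' @name detections_io
#' @export
read_detections <- function(path) {
  df <- read_csv_checked(path, c("frame", "x", "y"), "detections")
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("detections", "data.frame")
  df
}

#' @rdname detections_io
#' @export
write_detections <- function(detections, path) {
  write_csv_atomic(as.data.frame(detections), path)
}

#' Read / write track tables
#'
#' CSV schema: `track_id,frame,x,y,interpolated,area,mean_intensity,
#' model_rw,model_cv,model_ca`. Rows are normalised to (track_id, frame)
#' order on read.
#'
#' @param path file path.
#' @param tracks a `tracks` table.
#' @name tracks_io
#' @export
read_tracks <- function(path) {
  df <- read_csv_checked(path, c("track_id", "frame", "x", "y"), "tracks")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  if ("interpolated" %in% names(df)) {
    df$interpolated <- as.logical(df$interpolated)
  }
  class(df) <- c("tracks", "data.frame")
  df
}

#' @rdname tracks_io
#' @export
write_tracks <- function(tracks, path) {
  write_csv_atomic(as.data.frame(tracks), path)
}

#' Export / import tracks in ISBI-challenge-style XML
#'
#' Layout: `<root><TrackContestISBI2012><particle><detection t= x= y= z=0/>
#' ...</particle>...</TrackContestISBI2012></root>`. Frame indices are
#' 0-based in the XML (`t = frame - 1`).
#'
#' @param tracks a tracks-like table (`track_id, frame, x, y`).
#' @param path file path.
#' @name isbi_io
#' @export
write_tracks_xml <- function(tracks, path) {
  doc <- xml2::xml_new_root("root")
  contest <- xml2::xml_add_child(doc, "TrackContestISBI2012")
  for (p in split(tracks, tracks$track_id)) {
    part <- xml2::xml_add_child(contest, "particle")
    for (k in seq_len(nrow(p))) {
      xml2::xml_add_child(part, "detection",
                          t = format(p$frame[k] - 1L),
                          x = format(p$x[k], digits = 12),
                          y = format(p$y[k], digits = 12),
                          z = "0")
    }
  }
  atomic_write(path, function(tmp) xml2::write_xml(doc, tmp))
}

#' @rdname isbi_io
#' @export
read_tracks_xml <- function(path) {
  doc <- xml2::read_xml(path)
  parts <- xml2::xml_find_all(doc, ".//particle")
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    dets <- xml2::xml_find_all(parts[[i]], ".//detection")
    out[[i]] <- data.frame(
      track_id = i,
      frame = as.integer(xml2::xml_attr(dets, "t")) + 1L,
      x = as.numeric(xml2::xml_attr(dets, "x")),
      y = as.numeric(xml2::xml_attr(dets, "y")))
  }
  res <- do.call(rbind, out)
  class(res) <- c("tracks", "data.frame")
  res
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report` ([evaluate_tracking()]).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(unclass(report), tmp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
}

# ---- pipeline configuration ----

#' @keywords internal
default_config <- function() {
  list(
    seed = 1L,
    input = NULL, truth = NULL, output_dir = ".",
    simulate = list(enabled = FALSE, n_tracks = 100L, n_frames = 50L,
                    shape = c(256L, 256L), snr = 4, background = 10,
                    amplitude = 100, motion = "brownian", step_sd = 1,
                    drift = c(0, 0), cage_radius = NULL, psf_sigma = 1.2,
                    noise = list(enabled = TRUE, poisson = TRUE, m = 5,
                                 sd = 30, bit_depth = 8L)),
    detect = list(S = 12, s = 4, N = 100L, density = "low", snr = 4,
                  adaptive = TRUE, carry_n = TRUE),
    link = list(max_dist = 5, min_length = 3L, max_gap = 1L, lambda = 0.5,
                meas_sd = 0.5),
    evaluate = list(radius = NULL, theta = 0.8),
    analyze = list(enabled = TRUE, n_angle_bins = 36L),
    stop_after = "analyze")
}

#' Read and validate a pipeline configuration
#'
#' YAML or JSON (by file extension). Unknown keys are rejected; missing keys
#' fall back to the built-in defaults.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @param overrides named list merged on top (e.g. CLI flags).
#' @return a validated `pipeline_config` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  merge_into <- function(base, new, where) {
    for (nm in names(new)) {
      if (!nm %in% names(base)) {
        stop("unknown configuration key '", nm, "' in ", where)
      }
      if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]],
                                 paste0(where, "$", nm))
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      stop("unsupported config format: .", ext)
    }
    cfg <- merge_into(cfg, user, "config")
  }
  if (length(overrides) > 0L) cfg <- merge_into(cfg, overrides, "overrides")
  stopifnot(cfg$stop_after %in% c("simulate", "detect", "link", "evaluate",
                                  "analyze"))
  class(cfg) <- "pipeline_config"
  cfg
}
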