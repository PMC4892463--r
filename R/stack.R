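# The 2D+t movie container.

#' Create a frame stack
#'
#' A `frame_stack` holds a list of equally sized 2D grey-level matrices plus
#' acquisition metadata. Values are stored in grey levels (not normalised).
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param bit_depth sensor bit depth (8 or 16).
#' @param frame_interval optional frame interval, seconds.
#' @param pixel_size optional pixel size, nanometres.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, bit_depth = 8L, frame_interval = NULL,
                        pixel_size = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, is.matrix, logical(1))))
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1L && any(dims != dims[, 1L])) {
    stop("all frames must share one shape")
  }
  stopifnot(bit_depth %in% c(8L, 16L))
  structure(list(frames = frames, bit_depth = as.integer(bit_depth),
                 frame_interval = frame_interval, pixel_size = pixel_size),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("frame_stack: %d frame(s), %d x %d px, %d-bit\n",
              length(x$frames), d[1L], d[2L], x$bit_depth))
  rng <- range(vapply(x$frames, range, numeric(2)))
  cat(sprintf("  value range: [%.3g, %.3g]\n", rng[1L], rng[2L]))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)
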