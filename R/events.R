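#' Single-event multichannel image
#'
#' One detected object from an imaging flow cytometer (or the synthetic
#' generator): a set of aligned 2D intensity rasters, one per channel, plus
#' the pixel scale. All channels share the same shape; intensities are
#' finite and non-negative.
#'
#' @param event_id Character identifier, unique within an event set.
#' @param channels Named list of numeric matrices (a.u.), identical dims.
#' @param pixel_size Physical pixel size (um/px), > 0.
#' @return An object of class `image_event`.
#' @export
image_event <- function(event_id, channels, pixel_size) {
  stopifnot(is.character(event_id), length(event_id) == 1L, nzchar(event_id))
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same shape", call. = FALSE)
  for (ch in names(channels)) {
    m <- channels[[ch]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("channel '", ch, "' is not a numeric matrix", call. = FALSE)
    if (any(!is.finite(m)) || any(m < 0))
      stop("channel '", ch, "' has non-finite or negative intensities",
           call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  structure(list(event_id = event_id, channels = channels,
                 pixel_size = pixel_size),
            class = "image_event")
}

#' @export
print.image_event <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_event> %s: %d x %d px (%.3g um/px), channels: %s\n",
              x$event_id, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
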