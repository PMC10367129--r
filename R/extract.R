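#' Feature-extraction configuration
#'
#' Collects the knobs of the feature layer: which channel is segmented for
#' the mask, which channels get per-channel intensity/texture features,
#' the GLCM quantization and offset distance, the mask closing/dilation
#' radii, and the channel pair scored for bright-detail colocalization.
#'
#' @param mask_channel Channel segmented by [object_mask()].
#' @param channels Channels to compute intensity/texture features for. The
#'   first is reported under the canonical (unprefixed) column names; any
#'   further channel `ch` is reported as `ch_<feature>`.
#' @param glcm_levels,glcm_granularity GLCM quantization levels and offset
#'   distance (px).
#' @param close_radius,dilate_radius Mask morphology radii (px).
#' @param bds_pair Length-2 character: channels scored by
#'   [bright_detail_similarity_r3()] (set `NULL` to skip).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(mask_channel = "membrane",
                           channels = c("membrane", "reporter"),
                           glcm_levels = 32L, glcm_granularity = 2L,
                           close_radius = 3L, dilate_radius = 0L,
                           bds_pair = c("membrane", "reporter")) {
  structure(list(mask_channel = mask_channel, channels = channels,
                 glcm_levels = as.integer(glcm_levels),
                 glcm_granularity = as.integer(glcm_granularity),
                 close_radius = as.integer(close_radius),
                 dilate_radius = as.integer(dilate_radius),
                 bds_pair = bds_pair),
            class = "feature_config")
}

extract_features_one <- function(event, config) {
  for (ch in unique(c(config$mask_channel, config$channels, config$bds_pair)))
    if (!ch %in% names(event$channels))
      stop("configured channel '", ch, "' missing in event ",
           event$event_id, call. = FALSE)
  mask <- object_mask(event, config$mask_channel,
                      dilate_radius = config$dilate_radius,
                      close_radius = config$close_radius)
  row <- list(event_id = event$event_id, mask_empty = mask$empty)
  geo <- geometry_features(mask, event$pixel_size)
  row <- c(row, geo)
  for (k in seq_along(config$channels)) {
    ch <- config$channels[k]
    pre <- if (k == 1L) "" else paste0(ch, "_")
    feats <- c(intensity_features(event, mask, ch),
               haralick_features(event, mask, ch,
                                 levels = config$glcm_levels,
                                 granularity = config$glcm_granularity))
    names(feats) <- paste0(pre, names(feats))
    row <- c(row, feats)
  }
  if (!is.null(config$bds_pair))
    row$bds_r3 <- bright_detail_similarity_r3(event, mask,
                                              config$bds_pair[1],
                                              config$bds_pair[2])
  row
}

#' Extract the full feature table for an event set
#'
#' Runs the mask and every feature operation on each event and assembles a
#' feature table with one row per event and a stable column order. Events
#' with an empty mask are kept and flagged (`mask_empty = TRUE`, features
#' `NA`), never dropped silently.
#'
#' @param events A single [image_event()] or a list of them.
#' @param config A [feature_config()].
#' @return A data.frame, one row per event.
#' @export
extract_features <- function(events, config = feature_config()) {
  if (inherits(events, "image_event")) events <- list(events)
  stopifnot(length(events) >= 1L)
  rows <- lapply(events, extract_features_one, config = config)
  cols <- names(rows[[1]])
  out <- as.data.frame(
    stats::setNames(lapply(cols, function(cn)
      unlist(lapply(rows, function(r) r[[cn]]), use.names = FALSE)), cols),
    stringsAsFactors = FALSE)
  out
}
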