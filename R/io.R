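# Event-set I/O: one multi-page 16-bit TIFF per event (one page per
# channel) plus a CSV manifest, CSV truth/feature/label tables, JSON
# reports and PNG montage galleries. All writes are atomic
# (temp-then-rename) so a crashed run never leaves half-written outputs.

TIFF_MAX <- 65535

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp-",
                  basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE))
}

#' Write an event set as TIFF tiles plus a manifest
#'
#' Each event becomes one multi-page 16-bit unsigned TIFF (one page per
#' channel, in a fixed channel order); intensities are stored as rounded
#' detector units. A `manifest.csv` (event_id, file, channels, pixel_size)
#' and, when given, a `truth.csv` accompany the tiles.
#'
#' @param events List of [image_event()].
#' @param dir Output directory (created if needed).
#' @param truth Optional truth data.frame to store alongside.
#' @return The manifest path, invisibly.
#' @export
write_event_set <- function(events, dir, truth = NULL) {
  if (inherits(events, "image_event")) events <- list(events)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- names(events[[1]]$channels)
  rows <- vector("list", length(events))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (!identical(names(ev$channels), channels))
      stop("inconsistent channel sets in event set", call. = FALSE)
    fn <- paste0(ev$event_id, ".tif")
    pages <- lapply(ev$channels, function(m) {
      if (max(m) > TIFF_MAX)
        stop("intensity exceeds 16-bit range in event ", ev$event_id,
             call. = FALSE)
      round(m) / TIFF_MAX
    })
    atomic_write(file.path(dir, fn), function(tmp)
      tiff::writeTIFF(pages, tmp, bits.per.sample = 16,
                      compression = "none"))
    rows[[i]] <- data.frame(event_id = ev$event_id, file = fn,
                            channels = paste(channels, collapse = ";"),
                            pixel_size = ev$pixel_size,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$event_id))
    stop("duplicate event_ids in event set", call. = FALSE)
  write_csv_atomic(manifest, file.path(dir, "manifest.csv"))
  if (!is.null(truth))
    write_csv_atomic(truth, file.path(dir, "truth.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

read_one_event <- function(row, dir) {
  path <- file.path(dir, row$file)
  if (!file.exists(path))
    stop("cannot load event ", row$event_id, ": missing file ", row$file,
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  chans <- strsplit(row$channels, ";", fixed = TRUE)[[1]]
  if (length(pages) != length(chans))
    stop("event ", row$event_id, ": ", length(pages),
         " TIFF pages but ", length(chans), " declared channels",
         call. = FALSE)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      stop("event ", row$event_id, ": TIFF page is not a single-channel ",
           "2D raster", call. = FALSE)
    round(p * TIFF_MAX)
  })
  names(mats) <- chans
  image_event(row$event_id, mats, row$pixel_size)
}

#' Read an event set from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_event_set()].
#' @return List of [image_event()] in manifest order.
#' @export
read_event_set <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i)
    read_one_event(manifest[i, ], dir))
}

#' Batch-wise reader over a manifest
#'
#' Returns a reader object that lazily loads events in manifest order in
#' batches of `batch_size` rows (mirroring sequential batch analysis of
#' very large acquisitions): call `$next_batch()` repeatedly until it
#' returns `NULL`; `$reset()` rewinds.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @param batch_size Rows per batch (default 100,000).
#' @return An object of class `event_set_reader`.
#' @export
event_set_reader <- function(manifest_path, batch_size = 100000L) {
  stopifnot(batch_size >= 1L)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  pos <- 0L
  obj <- list(
    n_events = nrow(manifest),
    batch_size = as.integer(batch_size),
    next_batch = function() {
      if (pos >= nrow(manifest)) return(NULL)
      idx <- seq(pos + 1L, min(pos + batch_size, nrow(manifest)))
      pos <<- pos + length(idx)
      lapply(idx, function(i) read_one_event(manifest[i, ], dir))
    },
    reset = function() pos <<- 0L)
  class(obj) <- "event_set_reader"
  obj
}

#' @export
print.event_set_reader <- function(x, ...) {
  cat(sprintf("<event_set_reader> %d events, batch size %d\n",
              x$n_events, x$batch_size))
  invisible(x)
}

#' Write analysis outputs (features, labels, report, montage)
#'
#' Writes the feature table and per-event labels as CSV, and a JSON report
#' with per-level label counts; all writes are atomic. Empty tables give
#' valid empty files with headers.
#'
#' @param features Feature table (may be `NULL`).
#' @param labels Labels data.frame (may be `NULL`).
#' @param summary An `lg_population_summary` (or `NULL`).
#' @param dir Output directory.
#' @param gating_result Optional `lg_gating_result` whose per-stage counts
#'   go into the report.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(features, labels, summary, dir,
                          gating_result = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  if (!is.null(features)) {
    p <- file.path(dir, "features.csv")
    write_csv_atomic(features, p); out["features"] <- p
  }
  if (!is.null(labels)) {
    p <- file.path(dir, "labels.csv")
    write_csv_atomic(labels, p); out["labels"] <- p
  }
  rep_ <- list()
  if (!is.null(summary)) {
    for (lv in setdiff(names(summary), c("n_events", "size_cut"))) {
      df <- summary[[lv]]
      rep_[[lv]] <- stats::setNames(as.list(df$n), df$label)
      rep_[[paste0(lv, "_fraction")]] <-
        stats::setNames(as.list(df$fraction), df$label)
    }
    rep_$n_events <- summary$n_events
  }
  if (!is.null(gating_result)) {
    rep_$stages <- lapply(seq_len(nrow(gating_result$stages)), function(i)
      as.list(gating_result$stages[i, ]))
  }
  p <- file.path(dir, "report.json")
  atomic_write(p, function(tmp)
    jsonlite::write_json(rep_, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  out["report"] <- p
  invisible(out)
}

#' Write a PNG montage gallery of example events per class
#'
#' Emulates per-phenotype image galleries: up to `per_class` example tiles
#' per label, one row per class, channels summed and contrast-stretched
#' per tile.
#'
#' @param events List of [image_event()].
#' @param labels Character vector of labels aligned with `events`.
#' @param path Output PNG path.
#' @param per_class Examples per class.
#' @param channel Channel to display (default: first channel).
#' @return Path, invisibly.
#' @export
write_montage <- function(events, labels, path, per_class = 8,
                          channel = NULL) {
  stopifnot(length(events) == length(labels))
  keep <- !is.na(labels)
  events <- events[keep]; labels <- labels[keep]
  if (!length(events)) stop("no labeled events to display", call. = FALSE)
  classes <- sort(unique(labels))
  d <- dim(events[[1]]$channels[[1]])
  sep <- 2L
  nc <- per_class
  canvas <- matrix(1, length(classes) * (d[1] + sep) - sep,
                   nc * (d[2] + sep) - sep)
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])[seq_len(per_class)]
    idx <- idx[!is.na(idx)]
    for (j in seq_along(idx)) {
      ev <- events[[idx[j]]]
      ch <- if (is.null(channel)) names(ev$channels)[1] else channel
      m <- ev$channels[[ch]]
      rng <- range(m)
      m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
      r0 <- (i - 1L) * (d[1] + sep)
      c0 <- (j - 1L) * (d[2] + sep)
      canvas[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- m
    }
  }
  atomic_write(path, function(tmp) png::writePNG(canvas, tmp))
  invisible(path)
}
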