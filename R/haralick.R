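# Gray-level co-occurrence (GLCM) texture statistics.
#
# Pixels inside the mask are quantized to `levels` gray levels between the
# mask minimum and maximum. For each of the four offsets (right, down,
# down-right, down-left) at the chosen granularity, a symmetric normalized
# co-occurrence matrix is built from pixel pairs that both lie inside the
# mask, and four statistics are computed per offset:
#
#   homogeneity  sum p / (1 + |i - j|)
#   correlation  sum p (i - mu)(j - mu) / sigma^2   (0 when sigma = 0)
#   entropy      -sum p ln p
#   contrast     sum p (i - j)^2
#
# The reported features are the mean and standard deviation of each
# statistic across the four offsets (direction-dependent textures such as
# rods show large across-offset spread).

glcm_offsets <- function(g) {
  list(c(0L, g), c(g, 0L), c(g, g), c(g, -g))
}

glcm_stats_one <- function(q, mask, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
  clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi) return(NULL)
  r1 <- rlo:rhi
  c1 <- clo:chi
  m1 <- mask[r1, c1, drop = FALSE]
  m2 <- mask[r1 + dr, c1 + dc, drop = FALSE]
  ok <- m1 & m2
  n <- sum(ok)
  if (n < 1) return(NULL)
  a <- q[r1, c1, drop = FALSE][ok]
  b <- q[r1 + dr, c1 + dc, drop = FALSE][ok]
  counts <- tabulate(a * levels + b + 1L, nbins = levels * levels) +
    tabulate(b * levels + a + 1L, nbins = levels * levels)
  p <- counts / (2 * n)
  pm <- matrix(p, levels, levels)
  iv <- 0:(levels - 1L)
  io <- matrix(iv, levels, levels)
  jo <- t(io)
  homog <- sum(pm / (1 + abs(io - jo)))
  contr <- sum(pm * (io - jo)^2)
  pi_m <- rowSums(pm)
  mu <- sum(iv * pi_m)
  sig2 <- sum((iv - mu)^2 * pi_m)
  corr <- if (sig2 <= 0) 0 else (sum(pm * io * jo) - mu^2) / sig2
  pp <- p[p > 0]
  entr <- -sum(pp * log(pp))
  c(homogeneity = homog, correlation = corr, entropy = entr,
    contrast = contr)
}

#' GLCM (Haralick-style) texture features over a mask
#'
#' @param event An [image_event()].
#' @param mask An [object_mask()] result.
#' @param channel Channel name.
#' @param levels Number of quantization gray levels.
#' @param granularity Offset distance in px.
#' @return Named list `h_homogeneity_mean/std`, `h_correlation_mean/std`,
#'   `h_entropy_mean/std`, `h_contrast_mean/std`. A constant image gives
#'   homogeneity 1, contrast 0, entropy 0 and correlation 0 (by the
#'   sigma = 0 convention); masks with no valid pixel pair give `NA`.
#' @export
haralick_features <- function(event, mask, channel, levels = 32L,
                              granularity = 1L) {
  img <- event$channels[[channel]]
  region <- mask$region
  out_names <- as.vector(outer(
    c("h_homogeneity", "h_correlation", "h_entropy", "h_contrast"),
    c("mean", "std"), paste, sep = "_"))
  na_out <- stats::setNames(as.list(rep(NA_real_, 8)), out_names)
  if (mask$empty || sum(region) < 2) return(na_out)

  vals <- img[region]
  mn <- min(vals); mx <- max(vals)
  if (mx - mn <= 0) {
    q <- matrix(0L, nrow(img), ncol(img))
  } else {
    q <- pmin(as.integer(floor((img - mn) / (mx - mn) * levels)),
              levels - 1L)
    q[q < 0L] <- 0L
    q <- matrix(q, nrow(img))
  }
  per <- lapply(glcm_offsets(as.integer(granularity)), function(o)
    glcm_stats_one(q, region, o[1], o[2], as.integer(levels)))
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) return(na_out)
  tab <- do.call(rbind, per)
  res <- list()
  for (s in c("homogeneity", "correlation", "entropy", "contrast")) {
    v <- tab[, s]
    res[[paste0("h_", s, "_mean")]] <- mean(v)
    res[[paste0("h_", s, "_std")]] <- if (length(v) > 1) stats::sd(v) else 0
  }
  res
}
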