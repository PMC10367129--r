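# Scalar per-event image features: the gating vocabulary.
#
# All features are computed over the object mask. Intensity features are
# background-subtracted with a robust background (median outside the mask).
# Focus/texture normalizations are scale-free: multiplying a channel (and
# its background) by a constant leaves gradient RMS, contrast, the GLCM
# statistics and aspect ratio unchanged.

CIRCULARITY_CAP <- 100

shift_mat <- function(m, dr, dc) {
  # shift with zero fill; m[r, c] <- m[r + dr, c + dc]
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs + dr; csrc <- cs + dc
  rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

conv3 <- function(m, k) {
  # 3x3 correlation via shifts, zero boundary
  out <- matrix(0, nrow(m), ncol(m))
  for (i in 1:3) for (j in 1:3) {
    w <- k[i, j]
    if (w != 0) out <- out + w * shift_mat(m, i - 2L, j - 2L)
  }
  out
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- conv3(img, kx)
  gy <- conv3(img, t(kx))
  sqrt(gx^2 + gy^2)
}

laplacian_magnitude <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  abs(conv3(img, k))
}

#' Geometric features of a mask
#'
#' Computes area (px count times pixel area), equivalent-circle diameter,
#' aspect ratio (minor/major axis of the mask's second-moment ellipse, in
#' (0, 1]), and circularity (mean boundary-to-centroid distance divided by
#' the standard deviation of those distances; high for near-circular masks,
#' capped at 100 as the sd approaches zero).
#'
#' @param mask An [object_mask()] result (or logical matrix).
#' @param pixel_size um/px.
#' @return Named list: `area` (um2), `diameter` (um), `aspect_ratio`,
#'   `circularity`. All `NA` for an empty mask.
#' @export
geometry_features <- function(mask, pixel_size) {
  region <- if (inherits(mask, "event_mask")) mask$region else mask
  na <- list(area = NA_real_, diameter = NA_real_,
             aspect_ratio = NA_real_, circularity = NA_real_)
  if (!any(region)) return(na)
  idx <- which(region, arr.ind = TRUE)
  npx <- nrow(idx)
  area <- npx * pixel_size^2
  diameter <- 2 * sqrt(area / pi)

  ctr <- colMeans(idx)
  dr <- idx[, 1] - ctr[1]; dc <- idx[, 2] - ctr[2]
  # second moments with the 1/12 term for finite square pixels
  mrr <- mean(dr^2) + 1 / 12; mcc <- mean(dc^2) + 1 / 12; mrc <- mean(dr * dc)
  tr <- mrr + mcc
  det_ <- mrr * mcc - mrc^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  aspect <- if (l1 <= 0) 1 else sqrt(l2 / l1)

  er <- as_mat(EBImage::erode(EBImage::Image(region * 1),
                              matrix(1, 3, 3))) > 0.5
  boundary <- region & !er
  bidx <- which(boundary, arr.ind = TRUE)
  if (nrow(bidx) < 3) {
    circ <- CIRCULARITY_CAP
  } else {
    d <- sqrt((bidx[, 1] - ctr[1])^2 + (bidx[, 2] - ctr[2])^2)
    mu <- mean(d); sdv <- stats::sd(d)
    circ <- if (sdv < mu / CIRCULARITY_CAP) CIRCULARITY_CAP else mu / sdv
  }
  list(area = area, diameter = diameter, aspect_ratio = aspect,
       circularity = circ)
}

#' Intensity, focus and concentration features over a mask
#'
#' Background is estimated as the median intensity outside the mask.
#' Features:
#' \describe{
#'   \item{intensity}{sum of background-subtracted pixels over the mask,
#'     floored at 0.}
#'   \item{max_pixel}{largest background-subtracted pixel in the mask.}
#'   \item{std_dev}{standard deviation of raw mask pixels; a texture
#'     measure.}
#'   \item{gradient_rms}{RMS Sobel gradient magnitude over the mask,
#'     normalized by the mean mask intensity, x100; a focus/sharpness
#'     metric that drops as the image blurs.}
#'   \item{contrast}{RMS 3x3-Laplacian magnitude over the mask with the same
#'     normalization; sensitive to thin sharp structures.}
#'   \item{compactness}{r_eq / r_gyr, where r_gyr is the
#'     background-subtracted intensity-weighted radius of gyration about the
#'     intensity centroid and r_eq = sqrt(area/pi); higher means the signal
#'     is more condensed toward a point.}
#' }
#'
#' @param event An [image_event()].
#' @param mask An [object_mask()] result.
#' @param channel Channel name.
#' @return Named list of the features above (`NA` for an empty mask).
#' @export
intensity_features <- function(event, mask, channel) {
  na <- list(intensity = NA_real_, max_pixel = NA_real_, std_dev = NA_real_,
             gradient_rms = NA_real_, contrast = NA_real_,
             compactness = NA_real_)
  region <- mask$region
  if (mask$empty || !any(region)) return(na)
  img <- event$channels[[channel]]
  bg <- stats::median(img[!region])
  vals <- img[region]
  sub <- vals - bg
  intensity <- max(sum(sub), 0)
  max_pixel <- max(sub)
  std_dev <- stats::sd(vals)
  mean_int <- mean(vals)

  if (mean_int <= 0) {
    grms <- 0; contr <- 0
  } else {
    gm <- sobel_magnitude(img)
    grms <- sqrt(mean(gm[region]^2)) / mean_int * 100
    lm <- laplacian_magnitude(img)
    contr <- sqrt(mean(lm[region]^2)) / mean_int * 100
  }

  w <- pmax(sub, 0)
  tot <- sum(w)
  if (tot <= 0) {
    compactness <- NA_real_
  } else {
    idx <- which(region, arr.ind = TRUE)
    cr <- sum(w * idx[, 1]) / tot; cc <- sum(w * idx[, 2]) / tot
    r_gyr <- sqrt(sum(w * ((idx[, 1] - cr)^2 + (idx[, 2] - cc)^2)) / tot)
    r_eq <- sqrt(nrow(idx) / pi)
    compactness <- if (r_gyr < r_eq / 100) 100 else r_eq / r_gyr
  }
  list(intensity = intensity, max_pixel = max_pixel, std_dev = std_dev,
       gradient_rms = grms, contrast = contr, compactness = compactness)
}

#' Bright detail similarity (radius 3) between two channels
#'
#' Colocalization score of the small bright structures of two channels
#' within a shared mask. Each channel's "bright detail" image is the channel
#' minus its grayscale morphological opening with a disc of radius 3 px,
#' floored at 0, which removes everything wider than ~6 px and keeps puncta
#' and thin rims. The score is the log-transformed Pearson correlation of
#' the two bright-detail images over the mask:
#' `-log10(1 - min(rho, 1 - 1e-6))`, floored at 0 for `rho <= 0` (so the
#' score caps at 6 for identical detail and sits near 0 for independent
#' signals). A zero-variance bright-detail image gives 0 by convention.
#'
#' @param event An [image_event()].
#' @param mask An [object_mask()] result.
#' @param channel_a,channel_b Channel names.
#' @param radius Opening disc radius in px.
#' @return Scalar score (`NA` for an empty mask).
#' @export
bright_detail_similarity_r3 <- function(event, mask, channel_a = "membrane",
                                        channel_b = "reporter", radius = 3L) {
  if (mask$empty || !any(mask$region)) return(NA_real_)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
  detail <- function(ch) {
    img <- event$channels[[ch]]
    mx <- max(img)
    if (mx <= 0) return(img)
    op <- as_mat(EBImage::opening(EBImage::Image(img / mx), brush)) * mx
    pmax(img - op, 0)
  }
  a <- detail(channel_a)[mask$region]
  b <- detail(channel_b)[mask$region]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  rho <- stats::cor(a, b)
  if (rho <= 0) return(0)
  -log10(1 - min(rho, 1 - 1e-6))
}

#' Number of molecules in a spherical lumen
#'
#' Converts a molar concentration and a vesicle diameter into an absolute
#' copy number: `concentration * (pi/6) d^3 * N_A`, with the diameter in um
#' (1 um3 = 1e-15 L). Used to express detection limits as molecule counts;
#' e.g. 500 nM in a 4-um vesicle is about ten thousand molecules.
#'
#' @param concentration Molar concentration (mol/L), >= 0.
#' @param diameter Vesicle diameter (um), > 0.
#' @return Expected number of molecules.
#' @examples
#' molecules_in_sphere(500e-9, 4)
#' @export
molecules_in_sphere <- function(concentration, diameter) {
  if (any(concentration < 0)) stop("concentration must be >= 0",
                                   call. = FALSE)
  if (any(diameter <= 0)) stop("diameter must be > 0", call. = FALSE)
  avogadro <- 6.02214076e23
  volume_l <- pi / 6 * diameter^3 * 1e-15
  concentration * volume_l * avogadro
}
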