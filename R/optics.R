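#' Optical model for synthetic event rendering
#'
#' Describes the idealised imaging system used by [render_event()]: the pixel
#' scale of the camera, the tile size cut out around each event, the in-focus
#' point-spread-function width, and the noise model (Poisson shot noise on
#' expected photons followed by additive Gaussian read noise over a constant
#' background).
#'
#' Defaults emulate a 60x imaging-flow-cytometer objective: 0.33 um/px and
#' 90x90 px tiles, large enough to contain a 15 um vesicle.
#'
#' @param pixel_size Physical size of one pixel (um/px). Must be > 0.
#' @param tile_shape Integer vector `c(rows, cols)` of the event tile, in px.
#'   The tile must be able to contain a 15 um object at `pixel_size`.
#' @param psf_sigma_infocus Gaussian PSF sigma when in focus (um).
#' @param background_level Constant expected background intensity (a.u.).
#' @param read_noise_sigma Standard deviation of additive Gaussian read noise
#'   (a.u.).
#' @param photon_scale Intensity units per expected photon; shot noise is
#'   Poisson on `expected/photon_scale`, rescaled back to intensity units.
#' @return An object of class `optics_model`.
#' @examples
#' op <- optics_model()
#' op$pixel_size
#' @export
optics_model <- function(pixel_size = 0.33,
                         tile_shape = c(90L, 90L),
                         psf_sigma_infocus = 0.3,
                         background_level = 10,
                         read_noise_sigma = 2,
                         photon_scale = 1) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  tile_shape <- as.integer(tile_shape)
  stopifnot(length(tile_shape) == 2L, all(tile_shape >= 8L))
  if (min(tile_shape) * pixel_size < 15)
    stop("tile_shape too small to contain a 15 um object at this pixel_size",
         call. = FALSE)
  stopifnot(psf_sigma_infocus >= 0, background_level >= 0,
            read_noise_sigma >= 0, photon_scale > 0)
  structure(
    list(pixel_size = pixel_size,
         tile_shape = tile_shape,
         psf_sigma_infocus = psf_sigma_infocus,
         background_level = background_level,
         read_noise_sigma = read_noise_sigma,
         photon_scale = photon_scale),
    class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat("<optics_model>\n")
  cat(sprintf("  pixel size      : %.3g um/px\n", x$pixel_size))
  cat(sprintf("  tile            : %d x %d px (%.1f x %.1f um)\n",
              x$tile_shape[1], x$tile_shape[2],
              x$tile_shape[1] * x$pixel_size, x$tile_shape[2] * x$pixel_size))
  cat(sprintf("  PSF sigma       : %.3g um (in focus)\n", x$psf_sigma_infocus))
  cat(sprintf("  background      : %.3g a.u.\n", x$background_level))
  cat(sprintf("  read noise      : %.3g a.u.\n", x$read_noise_sigma))
  cat(sprintf("  photon scale    : %.3g a.u./photon\n", x$photon_scale))
  invisible(x)
}
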