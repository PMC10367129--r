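# Rendering of synthetic ImageStream-like event tiles.
#
# Geometry is computed analytically on the pixel grid: membranes are
# line-of-sight integrals through thin spherical (or capsule) shells, which
# gives the limb-brightened ring a real vesicle projects to; lumens are
# chord-length integrals through the interior. Patterns are normalized so
# their pre-blur peak equals the requested brightness, blurred with a
# Gaussian PSF, and then corrupted with Poisson shot noise plus Gaussian
# read noise over a constant background.

MEMBRANE_THICKNESS_UM <- 0.15  # sub-resolution shell thickness

# run expr with a private RNG stream; global .Random.seed is restored
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian blur, zero boundary; sigma in pixels
gauss_blur <- function(mat, sigma_px) {
  if (sigma_px < 1e-8) return(mat)
  rad <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma_px)
  k <- k / sum(k)
  n1 <- nrow(mat); n2 <- ncol(mat)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in seq(-rad, rad)) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + rad + 1L]
    }
    K
  }
  band(n1) %*% mat %*% t(band(n2))
}

# projected path length through a thin shell at squared radial distance r2
shell_proj <- function(r2, R, t = MEMBRANE_THICKNESS_UM) {
  Ri <- max(R - t, 0)
  2 * (sqrt(pmax(R^2 - r2, 0)) - sqrt(pmax(Ri^2 - r2, 0)))
}

# projected chord length through a solid ball
ball_proj <- function(r2, R) 2 * sqrt(pmax(R^2 - r2, 0))

# squared distance from grid points to a segment of half-length h through
# the origin at angle theta
seg_dist2 <- function(x, y, h, theta) {
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  du <- pmax(abs(u) - h, 0)
  du^2 + v^2
}

norm_peak <- function(pat, brightness) {
  m <- max(pat)
  if (m <= 0) return(pat)
  pat * (brightness / m)
}

# membrane-channel pattern + interior info used by the reporter painter.
# Vesicle shapes are normalized so the peak of the *outer* shell equals
# membrane_brightness: the dye density per membrane area is a property of
# the bilayer, so internal membranes add signal on top of the same ring
# brightness instead of dimming it through a global peak normalization.
render_membrane <- function(spec, x, y) {
  r2 <- x^2 + y^2
  R <- spec$diameter / 2
  lumen <- NULL  # projected interior pattern, un-normalized
  ref <- NULL    # pattern component whose peak defines the brightness scale
  switch(spec$shape_class,
    sphere = {
      pat <- shell_proj(r2, R)
      lumen <- ball_proj(r2, max(R - MEMBRANE_THICKNESS_UM, 0.1))
    },
    multilamellar = {
      outer <- shell_proj(r2, R)
      pat <- outer
      for (i in seq_len(spec$n_inner_vesicles)) {
        ri <- R * stats::runif(1, 0.25, 0.5)
        rc <- stats::runif(1, 0, max(R - ri - 0.3, 0))
        a <- stats::runif(1, 0, 2 * pi)
        r2i <- (x - rc * cos(a))^2 + (y - rc * sin(a))^2
        pat <- pat + shell_proj(r2i, ri)
      }
      ref <- outer
      lumen <- ball_proj(r2, max(R - MEMBRANE_THICKNESS_UM, 0.1))
    },
    rod = {
      # diameter is the equivalent-circle diameter: the capsule covers the
      # same projected area as a sphere of this diameter
      W <- spec$diameter * sqrt((pi / 4) /
                                (spec$elongation - 1 + pi / 4))
      Rw <- W / 2
      h <- spec$elongation * W / 2 - Rw        # centerline half-length
      theta <- stats::runif(1, 0, pi)
      d2 <- seg_dist2(x, y, h, theta)
      pat <- shell_proj(d2, Rw)
      lumen <- ball_proj(d2, max(Rw - MEMBRANE_THICKNESS_UM, 0.1))
    },
    doublet = {
      d2nd <- spec$diameter * stats::runif(1, 0.6, 0.95)
      R1 <- R; R2 <- d2nd / 2
      theta <- stats::runif(1, 0, pi)
      sep <- R1 + R2  # tangent spheres
      # place so the pair is centered on the tile
      c1 <- -sep * R2 / (R1 + R2); c2 <- c1 + sep
      xa <- x - c1 * cos(theta); ya <- y - c1 * sin(theta)
      xb <- x - c2 * cos(theta); yb <- y - c2 * sin(theta)
      r2a <- xa^2 + ya^2; r2b <- xb^2 + yb^2
      pat <- shell_proj(r2a, R1) + shell_proj(r2b, R2)
      lumen <- ball_proj(r2a, max(R1 - MEMBRANE_THICKNESS_UM, 0.1)) +
        ball_proj(r2b, max(R2 - MEMBRANE_THICKNESS_UM, 0.1))
    },
    aggregate = {
      nb <- sample(3:8, 1)
      pat <- 0
      for (i in seq_len(nb)) {
        rb <- stats::runif(1, 0.5, 1.5)
        rc <- stats::runif(1, 0, 1.5)
        a <- stats::runif(1, 0, 2 * pi)
        r2i <- (x - rc * cos(a))^2 + (y - rc * sin(a))^2
        pat <- pat + stats::runif(1, 0.8, 1.6) * ball_proj(r2i, rb)
      }
      # dense lipid clumps are internally heterogeneous: mottle the profile
      g <- matrix(stats::rnorm(length(x)), nrow(x))
      g <- gauss_blur(g, 1.2)
      g <- g / max(stats::sd(g), 1e-9)
      pat <- pat * pmax(1 + 0.55 * g, 0.15)
      lumen <- pat
    },
    debris = {
      pat <- ball_proj(r2, R)
      lumen <- pat
    })
  if (is.null(ref)) ref <- pat
  scale <- spec$membrane_brightness / max(max(ref), 1e-9)
  list(pattern = pat * scale, lumen_raw = lumen,
       membrane_raw = if (spec$shape_class %in%
                          c("sphere", "multilamellar", "rod", "doublet"))
         pat else NULL)
}

render_reporter <- function(spec, x, y, geom) {
  if (spec$reporter_pattern == "none" || spec$reporter_brightness <= 0)
    return(matrix(0, nrow(x), ncol(x)))
  R <- spec$diameter / 2
  Rin <- max(R - MEMBRANE_THICKNESS_UM, 0.1)
  pat <- switch(spec$reporter_pattern,
    lumen = geom$lumen_raw,
    blob = {
      # condensed lumen content: same total flux as the homogeneous lumen
      # pattern at this brightness, concentrated into one punctum
      rb <- Rin / 4
      rc <- stats::runif(1, 0, 0.5 * Rin)
      a <- stats::runif(1, 0, 2 * pi)
      r2i <- (x - rc * cos(a))^2 + (y - rc * sin(a))^2
      pat_b <- ball_proj(r2i, rb)
      lum <- geom$lumen_raw
      tot_l <- sum(lum / max(max(lum), 1e-9))
      pat_b <- pat_b / max(max(pat_b), 1e-9)
      return(pat_b * spec$reporter_brightness * tot_l / max(sum(pat_b), 1e-9))
    },
    filaments = {
      k <- sample(1:4, 1)
      acc <- 0
      w <- 0.18  # um, ~1 px pre-blur width
      for (i in seq_len(k)) {
        a1 <- stats::runif(1, 0, 2 * pi)
        a2 <- a1 + stats::runif(1, pi / 3, pi)
        rr <- 0.85 * Rin
        p1 <- rr * c(cos(a1), sin(a1)); p2 <- rr * c(cos(a2), sin(a2))
        mid <- (p1 + p2) / 2
        dvec <- p2 - p1
        len <- sqrt(sum(dvec^2))
        th <- atan2(dvec[2], dvec[1])
        d2 <- seg_dist2(x - mid[1], y - mid[2], len / 2, th)
        acc <- acc + exp(-d2 / (2 * w^2))
      }
      acc
    },
    membrane = if (!is.null(geom$membrane_raw)) geom$membrane_raw
               else shell_proj(x^2 + y^2, R),
    lumen_plus_membrane = {
      mem <- if (!is.null(geom$membrane_raw)) geom$membrane_raw
             else shell_proj(x^2 + y^2, R)
      lum <- geom$lumen_raw
      lum / max(max(lum), 1e-9) * 0.5 + mem / max(max(mem), 1e-9)
    })
  norm_peak(pat, spec$reporter_brightness)
}

#' Render one synthetic event image
#'
#' Draws the membrane-dye and reporter channels for one object described by
#' a [phenotype_spec()], under the imaging model of an [optics_model()].
#' Both channels are convolved with a Gaussian PSF of width
#' `sqrt(psf_sigma_infocus^2 + defocus_sigma^2)`; with `noise = TRUE`
#' (default) Poisson shot noise and Gaussian read noise are added over the
#' background and intensities are quantized to integer detector units.
#'
#' The object position is jittered by up to one pixel and rod/doublet
#' orientations are drawn at random, so renders with different seeds differ;
#' a fixed `rng_seed` gives bit-identical pixels. The caller's RNG state is
#' left untouched.
#'
#' @param spec A [phenotype_spec()].
#' @param optics An [optics_model()].
#' @param rng_seed Integer seed for this event's randomness.
#' @param noise Add shot/read noise? `FALSE` returns the expected (pre-noise)
#'   image including background, useful for photometry checks.
#' @param event_id Identifier for the returned event.
#' @return An [image_event()] with channels `membrane` and `reporter`.
#' @examples
#' ev <- render_event(phenotype_spec("sphere", diameter = 8),
#'                    optics_model(), rng_seed = 1)
#' range(ev$channels$membrane)
#' @export
render_event <- function(spec, optics, rng_seed, noise = TRUE,
                         event_id = "event") {
  stopifnot(inherits(spec, "phenotype_spec"), inherits(optics, "optics_model"))
  extent <- switch(spec$shape_class,
    doublet = spec$diameter * 1.95,
    rod = spec$elongation * spec$diameter *
      sqrt((pi / 4) / (spec$elongation - 1 + pi / 4)),
    spec$diameter)
  if (extent > (min(optics$tile_shape) - 6) * optics$pixel_size)
    stop("object (", signif(extent, 3), " um) does not fit in the ",
         min(optics$tile_shape), "-px tile", call. = FALSE)
  with_local_seed(rng_seed, {
    nr <- optics$tile_shape[1]; nc <- optics$tile_shape[2]
    ps <- optics$pixel_size
    jit <- stats::runif(2, -1, 1) * ps
    yv <- (seq_len(nr) - (nr + 1) / 2) * ps - jit[1]
    xv <- (seq_len(nc) - (nc + 1) / 2) * ps - jit[2]
    y <- matrix(yv, nr, nc)
    x <- matrix(xv, nr, nc, byrow = TRUE)

    geom <- render_membrane(spec, x, y)
    mem <- geom$pattern
    rep_ <- render_reporter(spec, x, y, geom)

    sigma_um <- sqrt(optics$psf_sigma_infocus^2 + spec$defocus_sigma^2)
    mem <- gauss_blur(mem, sigma_um / ps)
    rep_ <- gauss_blur(rep_, sigma_um / ps)

    bg <- optics$background_level
    mem_e <- pmax(mem, 0) + bg
    rep_e <- pmax(rep_, 0) + bg
    if (noise) {
      shot <- function(e) {
        lam <- e / optics$photon_scale
        v <- stats::rpois(length(lam), lam) * optics$photon_scale +
          stats::rnorm(length(lam), 0, optics$read_noise_sigma)
        matrix(pmax(round(v), 0), nrow(e))
      }
      mem_e <- shot(mem_e)
      rep_e <- shot(rep_e)
    }
    image_event(event_id, list(membrane = mem_e, reporter = rep_e), ps)
  })
}

#' Draw a labeled synthetic event population
#'
#' Samples `n_events` phenotype classes i.i.d. from the composition's
#' class weights, draws per-event diameters from the (possibly
#' class-specific) size distribution, renders every event with
#' [render_event()], and returns the events together with a ground-truth
#' table. Deterministic for a fixed composition seed.
#'
#' @param comp A [population_composition()].
#' @param optics An [optics_model()].
#' @param noise Passed to [render_event()].
#' @return A list with `events` (list of [image_event()]) and `truth`
#'   (data.frame: event_id, label, shape_class, reporter_pattern,
#'   true_diameter, defocus_sigma).
#' @export
sample_population <- function(comp, optics = optics_model(), noise = TRUE) {
  stopifnot(inherits(comp, "population_composition"),
            inherits(optics, "optics_model"))
  n <- comp$n_events
  max_d <- (min(optics$tile_shape) - 8) * optics$pixel_size
  with_local_seed(comp$seed, {
    labels <- sample(names(comp$class_weights), n, replace = TRUE,
                     prob = comp$class_weights)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    events <- vector("list", n)
    truth <- data.frame(event_id = sprintf("ev%05d", seq_len(n)),
                        label = labels,
                        shape_class = NA_character_,
                        reporter_pattern = NA_character_,
                        true_diameter = NA_real_,
                        defocus_sigma = NA_real_,
                        elongation = NA_real_,
                        n_inner_vesicles = NA_integer_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      cls <- comp$classes[[labels[i]]]
      mu <- if (is.na(cls$size_mean)) comp$size_mean else cls$size_mean
      sdv <- if (is.na(cls$size_sd)) comp$size_sd else cls$size_sd
      d <- switch(cls$shape_class,
        debris = stats::runif(1, 0.8, 2.6),
        aggregate = stats::runif(1, 2.5, 5),
        min(max(stats::rnorm(1, mu, sdv), 3), min(13, max_d)))
      if (cls$shape_class == "doublet") d <- min(d, max_d / 1.95)
      if (cls$shape_class == "rod") d <- min(d, max_d / 1.6)
      sp <- phenotype_spec(
        shape_class = cls$shape_class,
        diameter = d,
        elongation = if (cls$shape_class == "rod")
          stats::runif(1, 2.2, 2.7) else 1,
        n_inner_vesicles = if (cls$shape_class == "multilamellar")
          sample(2:4, 1) else 0L,
        defocus_sigma = cls$defocus_sigma,
        membrane_brightness = cls$membrane_brightness,
        reporter_pattern = cls$reporter_pattern,
        reporter_brightness = cls$reporter_brightness)
      events[[i]] <- render_event(sp, optics, rng_seed = seeds[i],
                                  noise = noise,
                                  event_id = truth$event_id[i])
      truth$shape_class[i] <- sp$shape_class
      truth$reporter_pattern[i] <- sp$reporter_pattern
      truth$true_diameter[i] <- sp$diameter
      truth$defocus_sigma[i] <- sp$defocus_sigma
      truth$elongation[i] <- sp$elongation
      truth$n_inner_vesicles[i] <- sp$n_inner_vesicles
    }
    list(events = events, truth = truth)
  })
}
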