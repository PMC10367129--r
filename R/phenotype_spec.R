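#' Generative description of one synthetic event
#'
#' A `phenotype_spec` tells [render_event()] what kind of object to draw:
#' the shape class of the vesicle (or junk object), its size, the reporter
#' localization pattern in the second channel, brightness levels, and the
#' amount of defocus.
#'
#' Shape classes:
#' \describe{
#'   \item{sphere}{a unilamellar giant vesicle: a thin spherical membrane
#'     shell, which projects to a limb-brightened ring.}
#'   \item{rod}{an elongated (capsule-shaped) vesicle; `elongation` is the
#'     length-to-width ratio, drawn in 2-4 for typical rods.}
#'   \item{doublet}{two adhered vesicles of independently drawn diameters,
#'     imaged as one event (two tangent rings).}
#'   \item{multilamellar}{a vesicle containing `n_inner_vesicles` nested
#'     internal vesicles (nested rings).}
#'   \item{aggregate}{a dense lipid clump: several overlapping bright blobs
#'     with mottled internal intensity and an irregular outline.}
#'   \item{debris}{a single small dim blob (below the ~8 um2 resolution
#'     limit).}
#' }
#'
#' Reporter patterns: `none`, `lumen` (homogeneously filled lumen), `blob`
#' (one bright condensate punctum), `filaments` (1-4 thin chords through the
#' lumen), `membrane` (signal on the membrane shell), `lumen_plus_membrane`.
#'
#' @param shape_class One of the shape classes above.
#' @param diameter Object diameter (um); for rods, the major-axis length.
#' @param elongation Length/width ratio for rods (>= 1).
#' @param n_inner_vesicles Number of internal vesicles for multilamellar
#'   shapes (>= 1).
#' @param defocus_sigma Additional Gaussian blur from defocus (um).
#' @param membrane_brightness Peak pre-noise membrane-channel intensity
#'   (a.u.).
#' @param reporter_pattern Reporter localization pattern (see above).
#' @param reporter_brightness Peak pre-noise reporter-channel intensity
#'   (a.u.); >= 0.
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(shape_class = c("sphere", "rod", "doublet",
                                           "multilamellar", "aggregate",
                                           "debris"),
                           diameter = 8,
                           elongation = 1,
                           n_inner_vesicles = 0L,
                           defocus_sigma = 0,
                           membrane_brightness = 200,
                           reporter_pattern = c("none", "lumen", "blob",
                                                "filaments", "membrane",
                                                "lumen_plus_membrane"),
                           reporter_brightness = 150) {
  shape_class <- match.arg(shape_class)
  reporter_pattern <- match.arg(reporter_pattern)
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("diameter must be a single positive number (um)", call. = FALSE)
  if (!is.numeric(elongation) || elongation < 1)
    stop("elongation must be >= 1", call. = FALSE)
  if (shape_class == "multilamellar" && n_inner_vesicles < 1L)
    stop("multilamellar shapes need n_inner_vesicles >= 1", call. = FALSE)
  if (defocus_sigma < 0)
    stop("defocus_sigma must be >= 0", call. = FALSE)
  if (membrane_brightness < 0 || reporter_brightness < 0)
    stop("brightness values must be >= 0", call. = FALSE)
  structure(
    list(shape_class = shape_class, diameter = diameter,
         elongation = elongation,
         n_inner_vesicles = as.integer(n_inner_vesicles),
         defocus_sigma = defocus_sigma,
         membrane_brightness = membrane_brightness,
         reporter_pattern = reporter_pattern,
         reporter_brightness = reporter_brightness),
    class = "phenotype_spec")
}

#' Built-in phenotype class vocabulary for population sampling
#'
#' Maps population-composition class labels to generative parameters.
#' Each entry gives the shape class, reporter pattern, brightness levels
#' relative to the generator defaults, defocus, and (optionally) a
#' class-specific diameter distribution. Covers the morphology mixture
#' (sphere, multilamellar, rod, doublet, aggregate, debris, defocused) and
#' the reporter-module mixtures (expression, DNA replication, filaments,
#' membrane relocalization, lipid-probe positivity).
#'
#' Brightness conventions: membrane dye peaks at 200 a.u. for vesicles,
#' dim debris at 50, dense aggregates at 300. Reporter-positive classes peak
#' at 150 a.u.; "weak" classes (failed replication, unspecific probe
#' binding) at ~1/10 of the positive level; the specific lipid probe binds
#' 5x above the unspecific level.
#'
#' @return Named list of class definitions.
#' @export
default_phenotype_classes <- function() {
  cl <- function(shape, pattern = "none", rep_bright = 0, mem_bright = 200,
                 defocus = 0, size_mean = NA_real_, size_sd = NA_real_)
    list(shape_class = shape, reporter_pattern = pattern,
         reporter_brightness = rep_bright, membrane_brightness = mem_bright,
         defocus_sigma = defocus, size_mean = size_mean, size_sd = size_sd)
  list(
    sphere        = cl("sphere"),
    multilamellar = cl("multilamellar"),
    rod           = cl("rod"),
    doublet       = cl("doublet"),
    aggregate     = cl("aggregate", mem_bright = 300),
    debris        = cl("debris", mem_bright = 50),
    defocused     = cl("sphere", defocus = 2),
    nonexpressing = cl("sphere"),
    expressing    = cl("sphere", "lumen", 150),
    replication_negative    = cl("sphere", "lumen", 15),
    replication_homogeneous = cl("sphere", "lumen", 150),
    replication_blob        = cl("sphere", "blob", 150,
                                 size_mean = 5.5, size_sd = 1.2),
    no_filaments  = cl("sphere", "lumen", 150),
    filaments     = cl("sphere", "filaments", 150),
    min_lumen     = cl("sphere", "lumen", 150),
    min_membrane  = cl("sphere", "membrane", 150),
    ps_negative   = cl("sphere", "membrane", 15),
    ps_positive   = cl("sphere", "membrane", 75)
  )
}

#' Population composition for the synthetic generator
#'
#' @param class_weights Named numeric vector of sampling probabilities over
#'   the labels of `classes` (non-negative, positive total; normalized
#'   internally).
#' @param n_events Number of events to draw (>= 1).
#' @param seed Integer RNG seed; a fixed seed gives a bit-identical event
#'   set.
#' @param size_mean,size_sd Mean and sd of the vesicle diameter
#'   distribution (um); the defaults match a typical giant-liposome
#'   preparation (7.2 +/- 1.7 um). Diameters are truncated to [3, 13] um so
#'   objects fit in the default tile and stay above the resolution floor.
#'   Debris sizes are drawn separately below the resolution limit.
#' @param classes Class-definition list; see [default_phenotype_classes()].
#' @return An object of class `population_composition`.
#' @export
population_composition <- function(class_weights, n_events, seed,
                                   size_mean = 7.2, size_sd = 1.7,
                                   classes = default_phenotype_classes()) {
  if (is.null(names(class_weights)) || any(!nzchar(names(class_weights))))
    stop("class_weights must be a named vector", call. = FALSE)
  unknown <- setdiff(names(class_weights), names(classes))
  if (length(unknown))
    stop("unknown phenotype classes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(class_weights < 0) || sum(class_weights) <= 0)
    stop("class_weights must be non-negative with positive total",
         call. = FALSE)
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1)
    stop("n_events must be >= 1", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(
    list(class_weights = class_weights / sum(class_weights),
         n_events = as.integer(n_events), seed = as.integer(seed),
         size_mean = size_mean, size_sd = size_sd, classes = classes),
    class = "population_composition")
}
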