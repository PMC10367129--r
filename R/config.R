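# Human-editable YAML configuration: population compositions, gate/pipeline
# definitions, and calibrated presets (so a calibration can be stored and
# shipped next to the data it was derived for).

#' Read a population composition from a YAML config
#'
#' Expected keys: `class_weights` (map label -> weight), `n_events`,
#' `seed`, optional `size_mean`, `size_sd`.
#'
#' @param path YAML file.
#' @param n_events,seed Optional overrides.
#' @return A [population_composition()].
#' @export
read_composition_config <- function(path, n_events = NULL, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$class_weights))
    stop("composition config needs a class_weights map", call. = FALSE)
  w <- unlist(cfg$class_weights)
  population_composition(
    w,
    n_events = if (!is.null(n_events)) n_events else cfg$n_events,
    seed = if (!is.null(seed)) seed else cfg$seed,
    size_mean = if (!is.null(cfg$size_mean)) cfg$size_mean else 7.2,
    size_sd = if (!is.null(cfg$size_sd)) cfg$size_sd else 1.7)
}

#' Read a gating pipeline from a YAML config
#'
#' The config is a list of stages, each with `name`, `type`
#' (threshold/interval/rect/polygon/expr), the referenced feature(s), the
#' bounds or vertices, and an optional `negate` flag.
#'
#' @param path YAML file.
#' @return An [gating_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stages <- lapply(cfg$stages, function(s) {
    ng <- isTRUE(s$negate)
    switch(s$type,
      threshold = gate_threshold(s$name, s$feature, s$cut,
                                 direction = if (is.null(s$direction)) ">"
                                             else s$direction, negate = ng),
      interval = gate_interval(s$name, s$feature, s$lo, s$hi, negate = ng),
      rect = gate_rect(s$name, s$fx, s$fy, unlist(s$xlim), unlist(s$ylim),
                       negate = ng),
      polygon = gate_polygon(s$name, s$fx, s$fy, unlist(s$vx),
                             unlist(s$vy), negate = ng),
      expr = gate_expr(s$name, stats::as.formula(paste("~", s$expr)),
                       negate = ng),
      stop("unknown gate type: ", s$type, call. = FALSE))
  })
  gating_pipeline(stages,
                  label = if (is.null(cfg$label)) "events" else cfg$label)
}

#' Read a run configuration from YAML
#'
#' A run config bundles the knobs of a batch analysis: the feature-layer
#' parameters (`mask_channel`, `channels`, `glcm_levels`,
#' `glcm_granularity`, `close_radius`, `dilate_radius`, `bds_pair`), the
#' manifest `batch_size`, a `pipeline` name, a `presets` path, and a
#' `seed`. Missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return List with `feature_config` (a [feature_config()]),
#'   `batch_size`, `pipeline`, `presets`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fc_args <- cfg[intersect(names(cfg),
                           names(formals(feature_config)))]
  fc_args <- lapply(fc_args, function(v)
    if (is.list(v)) unlist(v) else v)
  list(feature_config = do.call(feature_config, fc_args),
       batch_size = if (is.null(cfg$batch_size)) 100000L
                    else as.integer(cfg$batch_size),
       pipeline = cfg$pipeline,
       presets = cfg$presets,
       seed = cfg$seed)
}

#' Save / load calibrated presets as YAML
#'
#' Serializes an `lg_presets` object (thresholds and two-feature
#' discriminant rules) to a structured text file and back.
#'
#' @param presets An `lg_presets` from [calibrate_pipelines()].
#' @param path YAML file.
#' @return `save_presets()`: the path, invisibly; `load_presets()`: the
#'   `lg_presets`.
#' @export
save_presets <- function(presets, path) {
  ser <- lapply(presets, function(v) {
    if (inherits(v, "lg_threshold"))
      c(list(.kind = "threshold"), unclass(v))
    else if (inherits(v, "lg_gate2d"))
      list(.kind = "gate2d", fx = v$fx, fy = v$fy, classes = v$classes,
           quadratic = v$quadratic, offset = v$offset,
           means = lapply(v$means, as.numeric),
           inv = lapply(v$inv, as.numeric),
           logdet = as.list(v$logdet))
    else v
  })
  atomic_write(path, function(tmp) yaml::write_yaml(ser, tmp))
}

#' @rdname save_presets
#' @export
load_presets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(v) {
    if (is.list(v) && identical(v$.kind, "threshold")) {
      v$.kind <- NULL
      structure(v, class = "lg_threshold")
    } else if (is.list(v) && identical(v$.kind, "gate2d")) {
      structure(list(
        fx = v$fx, fy = v$fy, classes = unlist(v$classes),
        quadratic = isTRUE(v$quadratic),
        offset = if (is.null(v$offset)) 0 else v$offset,
        means = lapply(v$means, as.numeric),
        inv = lapply(v$inv, function(m) matrix(as.numeric(m), 2, 2)),
        logdet = unlist(v$logdet)), class = "lg_gate2d")
    } else if (is.list(v)) unlist(v) else v
  })
  structure(out, class = "lg_presets")
}
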