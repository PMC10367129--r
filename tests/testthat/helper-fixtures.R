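# Shared fixtures, memoized so expensive renders and calibrations happen
# once per test run.

.fx <- new.env(parent = emptyenv())

fx_optics <- function() {
  if (is.null(.fx$optics)) .fx$optics <- optics_model()
  .fx$optics
}

# presets for unit tests (moderate calibration size; the acceptance suite
# calibrates its own, larger, presets)
fx_presets <- function() {
  if (is.null(.fx$presets))
    .fx$presets <- calibrate_pipelines(fx_optics(), n_per_class = 60,
                                       seed = 4242)
  .fx$presets
}

# memoized single-event renders keyed by description
fx_event <- function(key, spec, seed, noise = TRUE) {
  id <- paste0(key, "#", seed, "#", noise)
  if (is.null(.fx$events)) .fx$events <- list()
  if (is.null(.fx$events[[id]]))
    .fx$events[[id]] <- render_event(spec, fx_optics(), rng_seed = seed,
                                     noise = noise, event_id = key)
  .fx$events[[id]]
}

fx_population <- function(key, weights, n, seed) {
  if (is.null(.fx$pops)) .fx$pops <- list()
  if (is.null(.fx$pops[[key]])) {
    pop <- sample_population(
      population_composition(weights, n, seed = seed), fx_optics())
    tab <- extract_features(pop$events)
    .fx$pops[[key]] <- list(pop = pop, tab = tab)
  }
  .fx$pops[[key]]
}

# logical disk mask in an n x n matrix
disk_mask <- function(n, r, cr = (n + 1) / 2, cc = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# capsule (stadium) mask with given half-length h and radius r
capsule_mask <- function(n, r, h) {
  rows <- matrix(seq_len(n), n, n) - (n + 1) / 2
  cols <- t(matrix(seq_len(n), n, n)) - (n + 1) / 2
  du <- pmax(abs(cols) - h, 0)
  du^2 + rows^2 <= r^2
}

precision_recall <- function(truth, pred, class) {
  c(recall = mean(pred[truth == class] == class),
    precision = if (any(pred == class, na.rm = TRUE))
      mean(truth[pred == class] == class, na.rm = TRUE) else 0)
}
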