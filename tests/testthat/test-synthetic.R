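# Synthetic event generator: determinism, photometry, pattern geometry,
# population sampling.

test_that("renders are bit-identical for a fixed seed", {
  sp <- phenotype_spec("sphere", diameter = 8)
  a <- render_event(sp, fx_optics(), rng_seed = 11)
  b <- render_event(sp, fx_optics(), rng_seed = 11)
  expect_identical(a$channels, b$channels)
  c_ <- render_event(sp, fx_optics(), rng_seed = 12)
  expect_false(identical(a$channels$membrane, c_$channels$membrane))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- .Random.seed
  render_event(phenotype_spec("sphere"), fx_optics(), rng_seed = 5)
  expect_identical(.Random.seed, before)
})

test_that("total above-background intensity is linear in brightness", {
  op <- fx_optics()
  for (cls in c("sphere", "rod", "multilamellar")) {
    sp1 <- phenotype_spec(cls, diameter = 8, membrane_brightness = 100,
                          elongation = if (cls == "rod") 2.5 else 1,
                          n_inner_vesicles = if (cls == "multilamellar")
                            2L else 0L)
    sp3 <- sp1; sp3$membrane_brightness <- 300
    e1 <- render_event(sp1, op, rng_seed = 3, noise = FALSE)
    e3 <- render_event(sp3, op, rng_seed = 3, noise = FALSE)
    t1 <- sum(e1$channels$membrane - op$background_level)
    t3 <- sum(e3$channels$membrane - op$background_level)
    expect_equal(t3 / t1, 3, tolerance = 0.01)
  }
})

test_that("a plain sphere shows a membrane ring and a quiet reporter", {
  op <- fx_optics()
  ev <- render_event(phenotype_spec("sphere", diameter = 8), op,
                     rng_seed = 21, noise = FALSE)
  mem <- ev$channels$membrane - op$background_level
  # ring: bright at the rim radius, dark at the center
  ctr <- dim(mem) / 2
  expect_lt(mem[ctr[1], ctr[2]], 0.5 * max(mem))
  expect_gt(max(mem), 50)
  expect_equal(max(abs(ev$channels$reporter - op$background_level)), 0)
})

test_that("blob reporter concentrates its flux in a small disk", {
  op <- fx_optics()
  for (seed in c(5, 6, 7)) {
    ev <- render_event(phenotype_spec("sphere", diameter = 8,
                                      reporter_pattern = "blob"),
                       op, rng_seed = seed, noise = FALSE)
    rep_ <- ev$channels$reporter - op$background_level
    tot <- sum(rep_)
    expect_gt(tot, 0)
    peak <- which(rep_ == max(rep_), arr.ind = TRUE)[1, ]
    lumen_d_px <- (8 - 0.3) / op$pixel_size
    rows <- matrix(seq_len(nrow(rep_)), nrow(rep_), ncol(rep_))
    cols <- t(matrix(seq_len(ncol(rep_)), ncol(rep_), nrow(rep_)))
    disk <- (rows - peak[1])^2 + (cols - peak[2])^2 <= (lumen_d_px / 6)^2
    expect_gt(sum(rep_[disk]) / tot, 0.9)
  }
})

test_that("defocus lowers the gradient RMS focus metric", {
  op <- fx_optics()
  sharp <- render_event(phenotype_spec("sphere", diameter = 8), op, 31)
  blurry <- render_event(phenotype_spec("sphere", diameter = 8,
                                        defocus_sigma = 2), op, 31)
  gs <- intensity_features(sharp, object_mask(sharp), "membrane")
  gb <- intensity_features(blurry, object_mask(blurry), "membrane")
  expect_lt(gb$gradient_rms, gs$gradient_rms)
})

test_that("oversized objects and invalid specs are rejected", {
  small <- optics_model(pixel_size = 0.33, tile_shape = c(50, 50))
  expect_error(render_event(phenotype_spec("sphere", diameter = 16.2),
                            small, 1), "fit")
  expect_error(phenotype_spec("sphere", diameter = -1), "diameter")
  expect_error(phenotype_spec("sphere", reporter_brightness = -5),
               "brightness")
  expect_error(phenotype_spec("multilamellar", n_inner_vesicles = 0),
               "n_inner_vesicles")
  expect_error(phenotype_spec("rod", elongation = 0.5), "elongation")
})

test_that("population sampling is deterministic and honors weights", {
  comp <- population_composition(c(sphere = 1), 10, seed = 1)
  a <- sample_population(comp, fx_optics())
  b <- sample_population(comp, fx_optics())
  expect_identical(lapply(a$events, `[[`, "channels"),
                   lapply(b$events, `[[`, "channels"))
  expect_equal(nrow(a$truth), 10)
  expect_true(all(a$truth$shape_class == "sphere"))
  expect_false(anyDuplicated(a$truth$event_id) > 0)

  comp2 <- population_composition(c(sphere = 0.5, doublet = 0.5), 2000,
                                  seed = 7)
  coarse <- optics_model(pixel_size = 0.5, tile_shape = c(32, 32))
  tr <- sample_population(comp2, coarse, noise = FALSE)$truth
  n_sphere <- sum(tr$label == "sphere")
  expect_lt(abs(n_sphere - 1000), 3 * sqrt(2000 * 0.25))
})

test_that("invalid compositions are rejected", {
  expect_error(population_composition(c(sphere = 0), 10, 1), "positive")
  expect_error(population_composition(c(sphere = 1), 0, 1), "n_events")
  expect_error(population_composition(c(nonsense = 1), 10, 1), "unknown")
  expect_error(population_composition(c(1, 1), 10, 1), "named")
})
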