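# Classification cascades on generator-truth examples and small mixtures.

test_that("identification routes junk classes to their labels", {
  pr <- fx_presets()
  pop <- fx_population("ident",
                       c(sphere = 0.4, debris = 0.2, aggregate = 0.2,
                         defocused = 0.2), 80, 303)
  lab <- identify_liposomes(pop$tab, pr)
  tr <- pop$pop$truth$label
  expect_gt(mean(lab$identification[tr == "sphere"] == "good_liposome"),
            0.85)
  expect_gt(mean(lab$identification[tr == "debris"] == "debris"), 0.85)
  expect_gt(mean(lab$identification[tr == "aggregate"] == "aggregate"),
            0.85)
  expect_gt(mean(lab$identification[tr == "defocused"] == "out_of_focus"),
            0.85)
})

test_that("morphology splits lamellarity and nonspherical shapes", {
  pr <- fx_presets()
  pop <- fx_population("morph",
                       c(sphere = 0.3, multilamellar = 0.3, rod = 0.2,
                         doublet = 0.2), 100, 304)
  lab <- classify_morphology(pop$tab, identify_liposomes(pop$tab, pr), pr)
  tr <- pop$pop$truth$label
  expect_gt(mean(lab$morphology[tr == "multilamellar"] ==
                 "spherical_multilamellar"), 0.8)
  expect_gt(mean(lab$morphology[tr == "sphere"] ==
                 "spherical_unilamellar"), 0.8)
  expect_gt(mean(lab$morphology[tr == "doublet"] == "doublet"), 0.8)
  expect_gt(mean(lab$morphology[tr == "rod"] == "rod"), 0.8)
  expect_true(all(lab$morphology[lab$identification != "good_liposome"]
                  == "unclassified"))
})

test_that("expression, replication and filament cascades follow the truth", {
  pr <- fx_presets()
  pop <- fx_population("reporter",
                       c(expressing = 0.25, nonexpressing = 0.15,
                         replication_blob = 0.2, filaments = 0.2,
                         replication_negative = 0.2), 100, 305)
  tab <- pop$tab; tr <- pop$pop$truth$label
  lab <- identify_liposomes(tab, pr)
  lab <- classify_expression(tab, lab,
                             pr$expression_intensity$threshold)
  lab <- classify_replication(tab, lab, pr)
  lab <- classify_filaments(tab, lab, pr)
  good <- lab$identification == "good_liposome"
  expect_gt(mean(lab$expression[good & tr == "expressing"] ==
                 "expressing", na.rm = TRUE), 0.85)
  expect_gt(mean(lab$expression[good & tr == "nonexpressing"] ==
                 "nonexpressing", na.rm = TRUE), 0.85)
  expect_gt(mean(lab$replication[good & tr == "replication_blob"] ==
                 "blob", na.rm = TRUE), 0.8)
  expect_gt(mean(lab$replication[good & tr == "replication_negative"] ==
                 "negative", na.rm = TRUE), 0.8)
  expect_gt(mean(lab$filament[good & tr == "filaments"] == "filament",
                 na.rm = TRUE), 0.8)
  # homogeneous reporters are not called filamentous
  expect_gt(mean(lab$filament[good & tr == "expressing"] == "no_filament",
                 na.rm = TRUE), 0.8)
})

test_that("relocalization separates membrane- from lumen-localized", {
  pr <- fx_presets()
  pop <- fx_population("minsys",
                       c(min_lumen = 0.5, min_membrane = 0.5), 80, 306)
  tab <- pop$tab; tr <- pop$pop$truth$label
  lab <- classify_relocalization(tab, identify_liposomes(tab, pr), pr)
  expect_gt(mean(lab$relocalization[tr == "min_membrane"] ==
                 "membrane_localized", na.rm = TRUE), 0.85)
  expect_gt(mean(lab$relocalization[tr == "min_lumen"] ==
                 "lumen_localized", na.rm = TRUE), 0.85)
})

test_that("negative-control thresholding bounds PS false positives", {
  pr <- fx_presets()
  neg <- fx_population("psneg", c(ps_negative = 1), 120, 307)
  neg_lab <- identify_liposomes(neg$tab, pr)
  res <- classify_ps(neg$tab, neg$tab, neg_lab, max_fpr = 0.05,
                     negative_labels = neg_lab)
  # negative table against itself: at most 5% positive by construction
  expect_lte(mean(res$labels$ps == "ps_positive", na.rm = TRUE), 0.05)
  expect_lte(res$negative_fpr, 0.05)
  expect_error(classify_ps(neg$tab, neg$tab[0, ],
                           identify_liposomes(neg$tab, pr)), "empty")
})

test_that("raising an intensity threshold never adds positives", {
  pr <- fx_presets()
  pop <- fx_population("reporter",
                       c(expressing = 0.25, nonexpressing = 0.15,
                         replication_blob = 0.2, filaments = 0.2,
                         replication_negative = 0.2), 100, 305)
  lab0 <- identify_liposomes(pop$tab, pr)
  counts <- sapply(c(500, 2000, 8000, 32000), function(thr)
    sum(classify_expression(pop$tab, lab0, thr)$expression == "expressing",
        na.rm = TRUE))
  expect_true(all(diff(counts) <= 0))
})

test_that("reclassification of the same table is bit-identical", {
  pr <- fx_presets()
  pop <- fx_population("ident",
                       c(sphere = 0.4, debris = 0.2, aggregate = 0.2,
                         defocused = 0.2), 80, 303)
  l1 <- classify_morphology(pop$tab, identify_liposomes(pop$tab, pr), pr)
  l2 <- classify_morphology(pop$tab, identify_liposomes(pop$tab, pr), pr)
  expect_identical(l1, l2)
})

test_that("population summaries conserve fractions and sizes", {
  pr <- fx_presets()
  pop <- fx_population("morph",
                       c(sphere = 0.3, multilamellar = 0.3, rod = 0.2,
                         doublet = 0.2), 100, 304)
  lab <- classify_morphology(pop$tab, identify_liposomes(pop$tab, pr), pr)
  s <- population_summary(lab, pop$tab, size_cut = 10)
  expect_equal(sum(s$identification$fraction), 1)
  expect_equal(sum(s$morphology$fraction), 1)
  expect_equal(sum(s$identification$n), 100)
  expect_true(all(s$morphology$frac_below_cut >= 0 &
                  s$morphology$frac_below_cut <= 1))
})

test_that("diameter estimates recover the generating distribution", {
  coarse <- optics_model()
  pop <- fx_population("sizes", c(sphere = 1), 150, 308)
  good <- !pop$tab$mask_empty
  est <- pop$tab$diameter[good]
  tru <- pop$pop$truth$true_diameter[good]
  # the half-level mask contour sits ~1 px outside the geometric edge, so
  # mask-based sizing carries a small positive halo bias
  expect_lt(mean(abs(est - tru)), 0.6)
  expect_lt(abs(mean(est) - mean(tru)), 0.45)
  expect_gt(stats::cor(est, tru), 0.98)
})

test_that("blob subpopulations inherit their smaller size distribution", {
  pr <- fx_presets()
  pop <- fx_population("repl_sizes",
                       c(replication_homogeneous = 0.5,
                         replication_blob = 0.5), 120, 309)
  tab <- pop$tab
  lab <- classify_replication(tab, identify_liposomes(tab, pr), pr)
  mb <- mean(tab$area[lab$replication == "blob"], na.rm = TRUE)
  mh <- mean(tab$area[lab$replication == "homogeneous"], na.rm = TRUE)
  expect_lt(mb, mh)
})
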