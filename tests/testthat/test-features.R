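# Geometry, intensity, focus and colocalization features.

test_that("area matches the pixel-count oracle for a perfect disk", {
  n <- 64
  mask <- disk_mask(n, 15)
  g <- geometry_features(mask, pixel_size = 0.5)
  expect_equal(g$area, sum(mask) * 0.25)          # exact, by definition
  expect_equal(g$area, pi * 7.5^2, tolerance = 0.02)  # discretization
  expect_equal(g$diameter, 2 * sqrt(g$area / pi))
  expect_gt(g$aspect_ratio, 0.98)
})

test_that("aspect ratio of a 2:1 ellipse is 0.5", {
  n <- 64
  rows <- matrix(seq_len(n), n, n) - 32.5
  cols <- t(matrix(seq_len(n), n, n)) - 32.5
  ellipse <- (cols / 20)^2 + (rows / 10)^2 <= 1
  g <- geometry_features(ellipse, pixel_size = 0.33)
  expect_equal(g$aspect_ratio, 0.5, tolerance = 0.02)
})

test_that("circularity orders disk > capsule > doublet", {
  n <- 80
  disk <- disk_mask(n, 15)
  # 3:1 capsule with approximately the same area
  caps <- capsule_mask(n, 8.2, 16.4)
  two <- disk_mask(n, 12, 40.5, 28) | disk_mask(n, 9, 40.5, 49)
  cd <- geometry_features(disk, 0.33)$circularity
  cc <- geometry_features(caps, 0.33)$circularity
  c2 <- geometry_features(two, 0.33)$circularity
  expect_gt(cd, cc)
  expect_gt(cc, c2)
  expect_gt(c2, 0)
})

test_that("degenerate and empty masks are handled", {
  g <- geometry_features(matrix(FALSE, 10, 10), 0.33)
  expect_true(all(is.na(unlist(g))))
})

test_that("a constant image has zero intensity, texture and gradients", {
  img <- matrix(7, 60, 60)
  ev <- image_event("const", list(membrane = img), 0.33)
  mask <- structure(list(region = disk_mask(60, 15), source_channel =
                         "membrane", empty = FALSE), class = "event_mask")
  f <- intensity_features(ev, mask, "membrane")
  expect_equal(f$intensity, 0)
  expect_equal(f$std_dev, 0)
  expect_equal(f$gradient_rms, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$max_pixel, 0)
})

test_that("gradient RMS decreases strictly with defocus", {
  op <- fx_optics()
  g <- sapply(c(0, 0.5, 1, 2), function(s) {
    ev <- render_event(phenotype_spec("sphere", diameter = 8,
                                      defocus_sigma = s),
                       op, rng_seed = 17, noise = FALSE)
    m <- object_mask(ev)
    intensity_features(ev, m, "membrane")$gradient_rms
  })
  expect_true(all(diff(g) < 0))
})

test_that("compactness ranks a point-like blob above a uniform lumen", {
  n <- 60
  mask <- structure(list(region = disk_mask(n, 20), source_channel =
                         "membrane", empty = FALSE), class = "event_mask")
  rows <- matrix(seq_len(n), n, n) - 30.5
  cols <- t(matrix(seq_len(n), n, n)) - 30.5
  blob <- 100 * exp(-(rows^2 + cols^2) / (2 * 2^2))
  uniform <- matrix(0, n, n); uniform[mask$region] <- 10
  e_blob <- image_event("b", list(membrane = blob), 0.33)
  e_uni <- image_event("u", list(membrane = uniform), 0.33)
  cb <- intensity_features(e_blob, mask, "membrane")$compactness
  cu <- intensity_features(e_uni, mask, "membrane")$compactness
  # oracle: radius of gyration of a uniform disk is r/sqrt(2)
  r_eq <- sqrt(sum(mask$region) / pi)
  expect_equal(cu, r_eq / (r_eq / sqrt(2)), tolerance = 0.05)
  expect_gt(cb, cu)
})

test_that("all features are translation invariant", {
  ev <- fx_event("sphere8", phenotype_spec("sphere", diameter = 8), 1)
  roll <- function(m, dr, dc) {
    m <- m[c((nrow(m) - dr + 1):nrow(m), 1:(nrow(m) - dr)), ]
    m[, c((ncol(m) - dc + 1):ncol(m), 1:(ncol(m) - dc))]
  }
  shifted <- image_event(ev$event_id,
                         lapply(ev$channels, roll, dr = 5, dc = 3),
                         ev$pixel_size)
  f0 <- extract_features(ev)
  f1 <- extract_features(shifted)
  num <- vapply(f0, is.numeric, logical(1))
  expect_equal(unlist(f1[num]), unlist(f0[num]), tolerance = 1e-9)
})

test_that("intensity scales linearly; shape and texture are scale-free", {
  ev <- fx_event("sphere8", phenotype_spec("sphere", diameter = 8), 1)
  k <- 3.7
  scaled <- image_event(ev$event_id, lapply(ev$channels, function(m) m * k),
                        ev$pixel_size)
  f0 <- extract_features(ev)
  f1 <- extract_features(scaled)
  expect_equal(f1$intensity, k * f0$intensity, tolerance = 1e-9)
  expect_equal(f1$max_pixel, k * f0$max_pixel, tolerance = 1e-9)
  for (col in c("aspect_ratio", "circularity", "gradient_rms", "contrast",
                "h_homogeneity_mean", "h_correlation_mean",
                "h_entropy_mean", "h_contrast_mean", "h_homogeneity_std",
                "h_correlation_std", "h_entropy_std", "h_contrast_std"))
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-9,
                 info = col)
})

test_that("aspect ratio separates rods from spheres on noiseless renders", {
  op <- fx_optics()
  rod <- render_event(phenotype_spec("rod", diameter = 8, elongation = 3),
                      op, 23, noise = FALSE)
  sph <- render_event(phenotype_spec("sphere", diameter = 8), op, 23,
                      noise = FALSE)
  ar_rod <- geometry_features(object_mask(rod), op$pixel_size)$aspect_ratio
  ar_sph <- geometry_features(object_mask(sph), op$pixel_size)$aspect_ratio
  expect_lt(ar_rod, 0.4)
  expect_gt(ar_sph, 0.4)
})
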