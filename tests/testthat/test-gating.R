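# Declarative gates, pipelines, accounting, and threshold utilities.

test_that("threshold gates flag the expected rows", {
  tab <- data.frame(area = c(4, 9, 12))
  g <- gate_threshold("big", "area", 8, ">")
  expect_equal(as.logical(evaluate_gate(tab, g)), c(FALSE, TRUE, TRUE))
  expect_equal(as.logical(evaluate_gate(tab, gate_threshold("small",
    "area", 8, ">", negate = TRUE))), c(TRUE, FALSE, FALSE))
})

test_that("rows with undefined features fail gates and are counted", {
  tab <- data.frame(area = c(4, NA, 12))
  flags <- evaluate_gate(tab, gate_threshold("big", "area", 8, ">"))
  expect_equal(as.logical(flags), c(FALSE, FALSE, TRUE))
  expect_equal(attr(flags, "n_undefined"), 1L)
  # negation still fails undefined rows
  flags2 <- evaluate_gate(tab, gate_threshold("x", "area", 8, ">",
                                              negate = TRUE))
  expect_equal(as.logical(flags2), c(TRUE, FALSE, FALSE))
})

test_that("rectangle and polygon gates match a brute-force row scan", {
  set.seed(12)
  tab <- data.frame(a = stats::runif(400, 0, 10),
                    b = stats::runif(400, 0, 10))
  r <- gate_rect("r", "a", "b", c(2, 6), c(3, 9))
  manual <- tab$a >= 2 & tab$a <= 6 & tab$b >= 3 & tab$b <= 9
  expect_equal(as.logical(evaluate_gate(tab, r)), manual)
  # triangle polygon vs half-plane arithmetic
  p <- gate_polygon("t", "a", "b", vx = c(0, 10, 0), vy = c(0, 0, 10))
  inside <- tab$a + tab$b < 10
  got <- as.logical(evaluate_gate(tab, p))
  expect_gt(mean(got == inside), 0.995)  # boundary pixels aside
  expect_error(evaluate_gate(tab, gate_threshold("x", "zz", 1)), "unknown")
})

test_that("empty tables give empty flags", {
  tab <- data.frame(area = numeric(0))
  flags <- evaluate_gate(tab, gate_threshold("big", "area", 8))
  expect_length(flags, 0)
})

test_that("pipelines account exactly and conserve events", {
  set.seed(3)
  tab <- data.frame(event_id = 1:1000, u = stats::runif(1000),
                    v = stats::runif(1000))
  pl <- gating_pipeline(list(gate_threshold("u", "u", 0.5, "<"),
                             gate_threshold("v", "v", 0.5, "<")))
  res <- run_pipeline(tab, pl)
  expect_equal(res$stages$n_in[2], res$stages$n_pass[1])
  expect_true(all(res$stages$n_pass + res$stages$n_fail +
                  res$stages$n_undefined == res$stages$n_in))
  expect_equal(sum(res$final), res$stages$n_pass[2])
  expect_gt(sum(res$final), 250 - 3 * sqrt(1000 * 0.25 * 0.75))
  expect_lt(sum(res$final), 250 + 3 * sqrt(1000 * 0.25 * 0.75))
  expect_equal(prod(res$stages$fraction), sum(res$final) / 1000,
               tolerance = 1e-12)
})

test_that("an always-true gate is the identity", {
  tab <- data.frame(a = 1:5)
  res <- run_pipeline(tab, gating_pipeline(gate_threshold("all", "a", 0)))
  expect_true(all(res$final))
})

test_that("stage order never changes the final selected set", {
  set.seed(4)
  tab <- data.frame(a = stats::rnorm(300), b = stats::rnorm(300),
                    c = stats::rnorm(300))
  gates <- list(gate_threshold("ga", "a", 0, ">"),
                gate_interval("gb", "b", -1, 1),
                gate_rect("gc", "a", "c", c(-2, 2), c(-2, 2)))
  final1 <- run_pipeline(tab, gating_pipeline(gates))$final
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    final2 <- run_pipeline(tab, gating_pipeline(gates[perm]))$final
    expect_identical(final2, final1)
  }
})

test_that("cumulative fractions multiply and reproduce the worked example", {
  expect_equal(cumulative_fraction(c(0.06, 0.45, 0.58)), 0.01566)
  expect_equal(cumulative_fraction(numeric(0)), 1)
  expect_equal(cumulative_fraction(c(0.5, 0.5)), 0.25)
  expect_error(cumulative_fraction(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(cumulative_fraction(c(-0.1)), "\\[0, 1\\]")
})

test_that("negative-control thresholds bound the false-positive rate", {
  expect_equal(threshold_from_negative(1:100, 0.05), 95)
  expect_lte(mean(1:100 > threshold_from_negative(1:100, 0.05)), 0.05)
  expect_equal(threshold_from_negative(rep(7, 50), 0.05), 7)
  expect_equal(mean(rep(7, 50) > 7), 0)
  set.seed(8)
  x <- stats::rnorm(1e5)
  expect_equal(threshold_from_negative(x, 0.01), stats::qnorm(0.99),
               tolerance = 0.05 / stats::qnorm(0.99))
  expect_error(threshold_from_negative(numeric(0), 0.05), "empty")
  expect_error(threshold_from_negative(1:10, 1.5), "max_fpr")
})

test_that("threshold calibration finds separating cuts", {
  tab <- data.frame(event_id = 1:40,
                    f = c(rep(10, 20), rep(20, 20)))
  truth <- data.frame(event_id = 1:40,
                      label = rep(c("neg", "pos"), each = 20))
  cal <- calibrate_threshold(tab, truth, "f", "pos")
  expect_gt(cal$threshold, 10)
  expect_lt(cal$threshold, 20)
  expect_equal(cal$balanced_accuracy, 1)
  expect_equal(cal$direction, ">")
  # identical distributions: no signal
  set.seed(13)
  tab2 <- data.frame(event_id = 1:2000, f = stats::rnorm(2000))
  truth2 <- data.frame(event_id = 1:2000,
                       label = rep(c("a", "b"), 1000))
  cal2 <- calibrate_threshold(tab2, truth2, "f", "a")
  expect_lt(cal2$balanced_accuracy, 0.56)
  expect_error(calibrate_threshold(tab2, data.frame(event_id = 1:2000,
    label = "a"), "f", "a"), "both classes")
})

test_that("two-feature discriminant gates recover a linear boundary", {
  set.seed(21)
  n <- 300
  tab <- data.frame(event_id = 1:(2 * n),
                    x = c(stats::rnorm(n, 0), stats::rnorm(n, 3)),
                    y = c(stats::rnorm(n, 0), stats::rnorm(n, 3)))
  truth <- data.frame(event_id = 1:(2 * n),
                      label = rep(c("lo", "hi"), each = n))
  g <- calibrate_gate2d(tab, truth, "x", "y", c("lo", "hi"))
  pred <- predict(g, tab)
  expect_gt(mean(pred == truth$label), 0.95)
  # undefined features propagate as NA
  tab$x[1] <- NA
  expect_true(is.na(predict(g, tab)[1]))
})
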