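# histograms, MPF fitting, binding frequency, mode comparisons

test_that("histogram bins are left-closed, right-open, anchored at 0", {
  h <- build_histogram(55, 10)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$mids[h$counts > 0], 55)    # bin [50, 60)
  h2 <- build_histogram(c(50, 59.999, 60), 10)
  expect_equal(h2$counts[h2$mids == 55], 2L)
  expect_equal(h2$counts[h2$mids == 65], 1L)
  expect_error(build_histogram(numeric(0)), "zero forces")
})

test_that("histogram counts are conserved", {
  set.seed(1)
  for (n in c(1, 36, 500)) {
    f <- rnorm_pos(n, 70, 20)
    expect_equal(sum(build_histogram(f, 10)$counts), n)
    expect_equal(sum(build_histogram(f, 7)$counts), n)
  }
})

test_that("modal bin of a large Gaussian sample contains the mean", {
  set.seed(2)
  h <- build_histogram(rnorm_pos(1e4, 76, 10), 10)
  modal <- which.max(h$counts)
  expect_true(h$bin_edges[modal] <= 76 && 76 < h$bin_edges[modal + 1])
})

test_that("a symmetric three-bin histogram fits its center exactly", {
  h <- build_histogram(c(45, rep(55, 10), 65), 10)
  fit <- fit_mpf(h)
  expect_equal(fit$mode_pN, 55, tolerance = 1e-6)
})

test_that("fit_mpf demands enough occupied bins", {
  expect_error(fit_mpf(build_histogram(rep(55, 20), 10)), "bin width")
})

test_that("MPF recovery at the study's sample sizes (median over seeds)", {
  modes_penta <- vapply(1:20, function(s) {
    set.seed(s)
    fit_mpf(build_histogram(rnorm_pos(36, 76, 10), 10))$mode_pN
  }, 0)
  expect_lt(abs(median(modes_penta) - 76), 4)

  modes_di <- vapply(1:20, function(s) {
    set.seed(s)
    fit_mpf(build_histogram(rnorm_pos(32, 50, 18), 10))$mode_pN
  }, 0)
  expect_lt(abs(median(modes_di) - 50), 6)
})

test_that("the local-fit MPF estimator is approximately unbiased", {
  modes <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    fit_mpf(build_histogram(rnorm_pos(36, 76, 10), 10))$mode_pN
  }, 0)
  expect_lt(abs(mean(modes) - 76), 1)
})

test_that("three-peak decomposition recovers the mixture modes", {
  one_run <- function(s) {
    set.seed(s)
    comp <- sample(1:3, 500, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    f <- rnorm_pos(500, c(70, 110, 140)[comp], 10)
    peaks <- suppressWarnings(fit_multi_mpf(build_histogram(f, 10), 3))
    if (length(peaks) == 3) vapply(peaks, `[[`, 0, "mode_pN") else rep(NA_real_, 3)
  }
  rec <- vapply(1:7, one_run, numeric(3))
  med <- apply(rec, 1, median, na.rm = TRUE)
  expect_true(all(abs(med - c(70, 110, 140)) < 5))
})

test_that("fit_multi_mpf with one peak equals fit_mpf", {
  set.seed(3)
  h <- build_histogram(rnorm_pos(200, 70, 12), 10)
  expect_equal(fit_multi_mpf(h, 1)[[1]]$mode_pN, fit_mpf(h)$mode_pN)
})

test_that("degenerate two-component fit collapses to a single peak", {
  set.seed(6)
  h <- build_histogram(rnorm_pos(300, 70, 10), 10)
  peaks <- suppressWarnings(fit_multi_mpf(h, 2))
  modes <- vapply(peaks, `[[`, 0, "mode_pN")
  # both components sit on the same underlying peak (or were merged)
  expect_true(all(abs(modes - 70) < 15))
})

test_that("binding frequency and its Wilson interval", {
  bf0 <- binding_frequency(rep("no_adhesion", 500))
  expect_equal(bf0$fraction, 0)
  expect_equal(bf0$ci[2], 0.007625, tolerance = 1e-3)  # z^2/(n+z^2)

  bf <- binding_frequency(c(rep("specific", 125), rep("no_adhesion", 875)))
  expect_equal(bf$fraction, 0.125)
  expect_true(bf$fraction >= 0.10 && bf$fraction <= 0.15)

  expect_equal(binding_frequency(rep("specific", 10))$fraction, 1)

  # oracle: stats::prop.test without continuity correction is Wilson
  for (x in c(0, 3, 125, 500)) {
    ours <- wilson_ci(x, 500)
    ref <- prop.test(x, 500, correct = FALSE)$conf.int
    expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("mode differences reproduce the closed-form z half-widths", {
  penta <- mpf_result(76, 10, 36)
  tri <- mpf_result(55, 11, 38)
  di <- mpf_result(50, 18, 32)

  c1 <- compare_modes(penta, tri, 0.95)
  expect_equal(c1$difference_pN, 21)
  expect_equal(c1$half_width_pN, 4.786, tolerance = 1e-3)
  expect_equal(round(c1$half_width_pN), 5)

  c2 <- compare_modes(penta, di, 0.95)
  expect_equal(c2$difference_pN, 26)
  expect_equal(c2$half_width_pN, 7.040, tolerance = 1e-3)
  expect_equal(round(c2$half_width_pN), 7)

  c3 <- compare_modes(tri, di, 0.80)
  expect_equal(c3$difference_pN, 5)
  expect_equal(c3$half_width_pN, 4.675, tolerance = 1e-3)
  expect_equal(round(c3$half_width_pN), 5)

  expect_equal(compare_modes(penta, penta)$difference_pN, 0)
  expect_error(compare_modes(mpf_result(50, 10, 1), penta), "n > 1")
})

test_that("z half-width agrees with a parametric bootstrap", {
  set.seed(11)
  n1 <- 36; s1 <- 10; n2 <- 38; s2 <- 11
  d <- rnorm(1e5, 0, s1 / sqrt(n1)) - rnorm(1e5, 0, s2 / sqrt(n2))
  hw_boot <- as.numeric(diff(quantile(d, c(0.025, 0.975)))) / 2
  hw <- compare_modes(mpf_result(76, s1, n1), mpf_result(55, s2, n2))$half_width_pN
  expect_lt(abs(hw - hw_boot) / hw, 0.05)
})
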