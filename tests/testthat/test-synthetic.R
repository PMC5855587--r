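# ground-truth-labelled curve generator

test_that("noise-free specific curve is an exact WLC forward model", {
  cfg <- exact_specific_config(force_pN = 60, Lc_nm = 35)
  r <- simulate_retract_curve(cfg, "c", seed = 10, force_class = "specific")
  expect_identical(r$label$true_class, "specific")
  expect_equal(r$label$true_rupture_force_pN, 60)

  d <- curve_segment(r$curve)
  a <- -d$force_pN                    # adhesion magnitude, baseline is 0
  z <- d$piezo_position_nm
  # maximum tether force equals the drawn rupture force exactly
  expect_equal(max(a), 60, tolerance = 1e-9)
  # pointwise: in the ramp, force equals wlc_force at x = z - |deflection|
  p <- wlc_params(0.1, 35, 298)
  ramp <- which(z > 0 & a > 1e-6)
  x <- z[ramp] - a[ramp] / (0.02 * 1000)
  expect_equal(a[ramp], wlc_force(x, p), tolerance = 1e-6)
  # after the rupture the force steps to the baseline in one sample
  j <- which.max(a)
  expect_lt(abs(a[j + 1]), 1e-9)
})

test_that("class probabilities zero give only no-adhesion labels", {
  cfg <- simulation_config(n_curves = 20, p_specific = 0, p_nonspecific = 0,
                           seed = 4, points_per_curve = 200)
  sim <- simulate_ensemble(cfg)
  expect_true(all(sim$labels$true_class == "no_adhesion"))
})

test_that("specific-label count falls in the central 99% binomial band", {
  sim <- simulate_ensemble(simulation_config(n_curves = 1000, p_specific = 0.125,
                                             seed = 6, points_per_curve = 150))
  n_spec <- sum(sim$labels$true_class == "specific")
  # qbinom(c(.005,.995), 1000, .125) = [95, 156]
  expect_gte(n_spec, 95)
  expect_lte(n_spec, 156)
})

test_that("the master seed makes the ensemble byte-identical", {
  cfg <- simulation_config(n_curves = 6, seed = 99, points_per_curve = 250)
  a <- simulate_ensemble(cfg)
  b <- simulate_ensemble(cfg)
  expect_identical(a$labels, b$labels)
  for (i in seq_along(a$curves)) {
    expect_identical(a$curves[[i]]$data, b$curves[[i]]$data)
  }
  # per-curve sub-seeds: any single curve is reproducible in isolation
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_curves)
  solo <- simulate_retract_curve(cfg, "curve_00004", seed = seeds[4])
  expect_identical(solo$curve$data, a$curves[[4]]$data)
})

test_that("a mixture rupture model reproduces its component weights", {
  cfg <- simulation_config(
    n_curves = 600, p_specific = 1, p_nonspecific = 0,
    rupture_force_model = list(mean_pN = c(70, 110, 140), sd_pN = 10,
                               weight = c(0.6, 0.25, 0.15)),
    seed = 12, points_per_curve = 150
  )
  sim <- simulate_ensemble(cfg)
  f <- sim$labels$true_rupture_force_pN
  comp <- apply(abs(outer(f, c(70, 110, 140), "-")), 1, which.min)
  obs <- tabulate(comp, 3) / length(f)
  exp_w <- c(0.6, 0.25, 0.15)
  se <- sqrt(exp_w * (1 - exp_w) / length(f))
  expect_true(all(abs(obs - exp_w) < 4 * se))
})

test_that("plateau curves need a plateau model that fits in the curve", {
  expect_error(simulation_config(p_plateau = 0.5), "plateau_model")
  expect_error(
    simulation_config(
      p_plateau = 0.5, curve_length_um = 0.1,
      plateau_model = list(force_mean_pN = 55, force_sd_pN = 5,
                           detach_length_mean_nm = 500, detach_length_sd_nm = 10)
    ),
    "exceeds the curve length"
  )
})

test_that("labels are consistent with their class", {
  cfg <- simulation_config(
    n_curves = 60, p_specific = 0.3, p_nonspecific = 0.3, p_plateau = 0.2,
    plateau_model = list(force_mean_pN = 55, force_sd_pN = 5,
                         detach_length_mean_nm = 100, detach_length_sd_nm = 20),
    seed = 31, points_per_curve = 200
  )
  lb <- simulate_ensemble(cfg)$labels
  expect_true(all(is.na(lb$true_rupture_force_pN[lb$true_class == "no_adhesion"])))
  expect_true(all(!is.na(lb$true_rupture_force_pN[lb$true_class == "specific"])))
  expect_true(all(!is.na(lb$true_plateau_force_pN[lb$true_class == "plateau"])))
  expect_true(all(is.na(lb$true_plateau_force_pN[lb$true_class != "plateau"])))
})
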