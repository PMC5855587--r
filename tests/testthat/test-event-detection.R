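# baseline, contact point, rupture detection and curve classification

test_that("contact point is recovered near the true origin", {
  cfg <- simulation_config(n_curves = 1, include_approach = TRUE, seed = 1)
  cv <- simulate_retract_curve(cfg, "c", seed = 17, force_class = "specific")$curve
  b <- estimate_baseline_and_contact(cv)
  expect_lt(abs(b$contact_nm - 0), 2)   # generator places contact at z = 0
  expect_lt(abs(b$offset_pN), 2)
})

test_that("pure-noise trace has no contact and classifies no_adhesion", {
  set.seed(20)
  z <- seq(0, 750, length.out = 1500)
  cv <- force_curve("noise", rep("retract", length(z)), z,
                    rnorm(length(z), 0, 5 / 20), 0.02)
  b <- estimate_baseline_and_contact(cv)
  expect_true(is.na(b$contact_nm))
  expect_lt(abs(b$offset_pN), 1)
  expect_identical(classify_curve(cv)$class, "no_adhesion")
})

test_that("linear baseline drift is recovered", {
  cfg <- simulation_config(n_curves = 1, baseline_drift_pN_per_um = 5,
                           p_specific = 0, p_nonspecific = 0, seed = 1)
  cv <- simulate_retract_curve(cfg, "d", seed = 23, force_class = "no_adhesion")$curve
  b <- estimate_baseline_and_contact(cv)
  expect_lt(abs(b$slope_pN_per_nm - 5e-3) / 5e-3, 0.2)
})

test_that("a specific rupture is located in force and extension", {
  # Lc = 65 nm puts a 60 pN rupture at ~35 nm extension
  cfg <- exact_specific_config(force_pN = 60, Lc_nm = 65, noise_sd_pN = 5)
  true_ext <- wlc_extension(60, wlc_params(0.1, 65, 298))
  expect_equal(true_ext, 35, tolerance = 0.02)
  r <- simulate_retract_curve(cfg, "s", seed = 42, force_class = "specific")
  res <- detect_ruptures(r$curve)
  expect_identical(res$class, "specific")
  expect_equal(nrow(res$events), 1L)
  expect_lt(abs(res$events$rupture_force_pN - 60), 2 * 5)
  expect_lt(abs(res$events$rupture_extension_nm - true_ext), 3)
})

test_that("adhesion below the window marks the curve non-specific", {
  # Lc = 9 nm: a 60 pN rupture at ~4.9 nm extension
  cfg <- exact_specific_config(force_pN = 60, Lc_nm = 9, noise_sd_pN = 5)
  r <- simulate_retract_curve(cfg, "ns", seed = 7, force_class = "specific")
  res <- detect_ruptures(r$curve)
  expect_identical(res$class, "nonspecific")
  expect_equal(nrow(res$events), 0L)
  expect_gt(nrow(res$rejected), 0L)
  expect_true(all(res$rejected$rupture_extension_nm < 15))
})

test_that("ruptures below the 10 pN floor are not detected", {
  cfg <- exact_specific_config(force_pN = 8, Lc_nm = 100, noise_sd_pN = 1)
  r <- simulate_retract_curve(cfg, "w", seed = 9, force_class = "specific")
  res <- detect_ruptures(r$curve)
  expect_equal(nrow(res$events), 0L)
})

test_that("generator-made nonspecific curves classify nonspecific", {
  cfg <- simulation_config(n_curves = 1, seed = 1)
  for (s in 1:5) {
    r <- simulate_retract_curve(cfg, "n", seed = 100 + s,
                                force_class = "nonspecific")
    expect_identical(classify_curve(r$curve)$class, "nonspecific")
  }
})

test_that("plateaus are detected with the right mean force", {
  cfg <- exact_plateau_config(force_pN = 55, detach_nm = 100, noise_sd_pN = 5)
  r <- simulate_retract_curve(cfg, "p", seed = 13, force_class = "plateau")
  pl <- detect_plateau(r$curve)
  expect_false(is.null(pl))
  expect_lt(abs(pl$mean_force_pN - 55), 2)
  expect_gte(pl$length_nm, 20)
  expect_identical(classify_curve(r$curve)$class, "plateau")
})

test_that("WLC ramps and silent curves yield no plateau", {
  cfg <- exact_specific_config(force_pN = 76, Lc_nm = 35, noise_sd_pN = 5)
  r <- simulate_retract_curve(cfg, "r", seed = 3, force_class = "specific")
  expect_null(detect_plateau(r$curve))
  cfg0 <- simulation_config(n_curves = 1, p_specific = 0, p_nonspecific = 0)
  r0 <- simulate_retract_curve(cfg0, "z", seed = 3, force_class = "no_adhesion")
  expect_null(detect_plateau(r0$curve))
})

test_that("multiple candidates resolve to the largest-extension rupture", {
  # two-step staircase: ruptures at ~25 nm (80 pN) and ~45 nm (50 pN)
  z <- seq(-20, 730, length.out = 2000)
  sig <- numeric(length(z))
  sig[z < 0] <- -z[z < 0] * 0.8 * 20
  sig[z >= 0 & z <= 25] <- -80 * (z[z >= 0 & z <= 25] / 25)
  sig[z > 25 & z <= 45] <- -50 * ((z[z > 25 & z <= 45] - 25) / 20)
  set.seed(77)
  cv <- force_curve("stairs", rep("retract", length(z)), z,
                    (sig + rnorm(length(z), 0, 3)) / 20, 0.02)
  res <- detect_ruptures(cv)
  expect_identical(res$class, "specific")
  expect_gte(nrow(res$events), 2L)
  o <- order(res$events$rupture_extension_nm)
  expect_lt(abs(res$headline_force_pN -
                  res$events$rupture_force_pN[o[length(o)]]), 1e-12)
  expect_lt(abs(res$headline_force_pN - 50), 10)
})

test_that("accepted events always fall inside the extension window", {
  sim <- simulate_ensemble(simulation_config(n_curves = 150, seed = 55))
  res <- classify_ensemble(sim)
  if (nrow(res$events)) {
    expect_true(all(res$events$rupture_extension_nm >= 15))
    expect_true(all(res$events$rupture_extension_nm <= 60))
  }
  narrow <- classify_ensemble(sim, window_nm = c(20, 40))
  if (nrow(narrow$events)) {
    expect_true(all(narrow$events$rupture_extension_nm >= 20))
    expect_true(all(narrow$events$rupture_extension_nm <= 40))
  }
})

test_that("tether fits annotate accepted events with a plausible Lc", {
  cfg <- exact_specific_config(force_pN = 76, Lc_nm = 35, noise_sd_pN = 5)
  r <- simulate_retract_curve(cfg, "f", seed = 29, force_class = "specific")
  res <- detect_ruptures(r$curve, fit_tether = TRUE)
  expect_equal(nrow(res$events), 1L)
  expect_false(is.na(res$events$wlc_Lc_nm))
  expect_lt(abs(res$events$wlc_Lc_nm - 35) / 35, 0.15)
})
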