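# peeling work integration and energy conversions

test_that("constant 55 pN over 60 nm gives the canonical energies", {
  x <- seq(0, 100, by = 0.5)
  r <- peeling_result(x, rep(55, length(x)), c(20, 80))
  expect_equal(r$mean_force_pN, 55, tolerance = 1e-12)
  expect_equal(r$work_J, 3300e-21, tolerance = 1e-12)
  expect_equal(r$work_per_nm_J, 55e-21, tolerance = 1e-12)
  expect_equal(r$molar_work_per_nm_J, 55e-21 * 6.02214076e23, tolerance = 1e-12)
  expect_equal(r$molar_work_per_nm_J, 33.12e3, tolerance = 1e-3)
  expect_equal(r$per_residue_energy_kJ_per_mol, 11.04, tolerance = 1e-3)
})

test_that("per-residue energy conversions are linear and unit-consistent", {
  x <- seq(0, 100, by = 0.5)
  r <- peeling_result(x, rep(55, length(x)), c(20, 80))
  expect_equal(per_residue_energy(r, 1), r$molar_work_per_nm_J / 1000)
  expect_equal(per_residue_energy(r, 3), r$per_residue_energy_kJ_per_mol)
  r2 <- peeling_result(x, rep(110, length(x)), c(20, 80))
  expect_equal(r2$per_residue_energy_kJ_per_mol,
               2 * r$per_residue_energy_kJ_per_mol)
  r0 <- peeling_result(x, rep(0, length(x)), c(20, 80))
  expect_equal(r0$work_J, 0)
  expect_equal(r0$per_residue_energy_kJ_per_mol, 0)
})

test_that("work is invariant to axis shift and grid refinement", {
  set.seed(4)
  x <- seq(0, 100, by = 1)
  f <- approx(c(0, 30, 55, 100), c(20, 60, 40, 50), xout = x)$y  # piecewise linear
  w <- peeling_result(x, f, c(20, 80))$work_J
  # translation of the extension axis (and the segment with it)
  w_shift <- peeling_result(x + 13.7, f, c(20, 80) + 13.7)$work_J
  expect_equal(w_shift, w, tolerance = 1e-12)
  # 10x grid refinement of the same piecewise-linear force
  x_fine <- seq(0, 100, by = 0.1)
  f_fine <- approx(x, f, xout = x_fine)$y
  w_fine <- peeling_result(x_fine, f_fine, c(20, 80))$work_J
  expect_lt(abs(w_fine - w) / w, 1e-6)
})

test_that("invalid segments and negative forces are rejected", {
  x <- seq(0, 50, by = 0.5)
  expect_error(peeling_result(x, rep(10, length(x)), c(20, 80)), "outside")
  expect_error(peeling_result(x, rep(-10, length(x)), c(10, 40)),
               "negative mean force")
})

test_that("peeling_work integrates a generated plateau curve exactly", {
  cfg <- exact_plateau_config(force_pN = 55, detach_nm = 100)
  cv <- simulate_retract_curve(cfg, "p", seed = 5, force_class = "plateau")$curve
  r <- peeling_work(cv)
  expect_equal(r$mean_force_pN, 55, tolerance = 1e-6)
  expect_equal(r$work_J, 3300e-21, tolerance = 1e-6)
  expect_equal(r$per_residue_energy_kJ_per_mol, 11.04, tolerance = 1e-3)
})

test_that("peeling_work refuses curves without an overlapping plateau", {
  cfg <- exact_specific_config(force_pN = 76, Lc_nm = 35, noise_sd_pN = 5)
  cv <- simulate_retract_curve(cfg, "s", seed = 2, force_class = "specific")$curve
  expect_error(peeling_work(cv), "plateau")
})
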