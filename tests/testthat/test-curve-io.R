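# force-curve container, TSV round trips, manifest handling

test_that("force is spring constant times deflection, in pN", {
  z <- seq(0, 99.9, by = 0.1)
  defl <- rep(0, length(z)); defl[500] <- 2.5
  cv <- force_curve("c1", rep("retract", length(z)), z, defl,
                    spring_constant_nN_per_nm = 0.02)
  d <- curve_segment(cv)
  expect_equal(d$force_pN[500], 50)  # 0.02 nN/nm x 2.5 nm = 50 pN
  # linearity: scaling deflection scales force
  cv2 <- force_curve("c2", rep("retract", length(z)), z, 3 * defl,
                     spring_constant_nN_per_nm = 0.02)
  expect_equal(curve_segment(cv2)$force_pN, 3 * d$force_pN)
})

test_that("write_curve / read_curve round-trips bit-identically", {
  set.seed(2)
  for (k in c(0.02, 0.09)) {
    cfg <- simulation_config(n_curves = 1, spring_constant_nN_per_nm = k,
                             include_approach = TRUE, points_per_curve = 300)
    cv <- simulate_retract_curve(cfg, "rt", seed = sample.int(1e6, 1))$curve
    path <- withr::local_tempfile(fileext = ".tsv")
    write_curve(cv, path)
    back <- read_curve(path)
    expect_identical(back$data$piezo_position_nm, cv$data$piezo_position_nm)
    expect_identical(back$data$deflection_nm, cv$data$deflection_nm)
    expect_identical(back$data$segment, cv$data$segment)
    expect_identical(back$spring_constant_nN_per_nm, cv$spring_constant_nN_per_nm)
    expect_identical(back$temperature_K, cv$temperature_K)
    expect_identical(back$curve_id, cv$curve_id)
    expect_identical(back$sample_label, cv$sample_label)
  }
})

test_that("malformed curve files are rejected with format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# curve_id\tx", "# spring_constant_nN_per_nm\t0.02",
               "# pulling_speed_um_per_s\t5", "# temperature_K\t298",
               "# sample_label\ts",
               "segment\tpiezo_position_nm", "retract\t1"), path)
  expect_error(read_curve(path), "columns|deflection")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("segment\tpiezo_position_nm\tdeflection_nm", "retract\t1\t0"),
             path2)
  expect_error(read_curve(path2), "metadata")
  expect_error(read_curve(file.path(tempdir(), "nope.tsv")), "no such file")
})

test_that("validation rejects non-monotone piezo and empty retract", {
  expect_error(
    force_curve("bad", rep("retract", 3), c(0, 2, 1), c(0, 0, 0), 0.02),
    "bad.*monotone"
  )
  cv <- force_curve("appr_only", rep("approach", 100), seq(100, 1), rep(0, 100), 0.02)
  expect_error(write_curve(cv, tempfile()), "empty retract")
  expect_error(
    force_curve("bad2", rep("retract", 10), 1:10, rep(0, 10), -0.02),
    "spring constant"
  )
})

test_that("a 1e5-point curve survives a file round trip", {
  cfg <- simulation_config(n_curves = 1, points_per_curve = 1e5)
  cv <- simulate_retract_curve(cfg, "big", seed = 1)$curve
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cv, path)
  back <- read_curve(path)
  expect_identical(back$data$deflection_nm, cv$data$deflection_nm)
})

test_that("manifest round-trips an ensemble and flags missing files", {
  sim <- simulate_ensemble(simulation_config(n_curves = 4, seed = 3,
                                             points_per_curve = 200))
  dir <- withr::local_tempdir()
  write_ensemble(sim, dir)
  curves <- read_manifest(file.path(dir, "manifest.json"))
  expect_length(curves, 4)
  expect_identical(curves[[2]]$data$deflection_nm,
                   sim$curves[[2]]$data$deflection_nm)
  file.remove(file.path(dir, "curve_00003.tsv"))
  expect_error(read_manifest(file.path(dir, "manifest.json")), "missing")
})
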