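test_that("generate_curve honours the config and is seed-reproducible", {
  cf <- coefficient_set("NEO_HOOKEAN", 0.0615)
  cfg0 <- generator_config(cf, lambda_max = 2, n_points = 200L, noise_sd = 0)
  cv0 <- generate_curve(cfg0)
  expect_length(cv0$stretch, 200L)
  expect_equal(cv0$stress, uniaxial_stress(cf, cv0$stretch)) # noiseless = exact
  cfg1 <- generator_config(cf, lambda_max = 2, n_points = 80L,
                           noise_sd = 0.01, seed = 7L)
  expect_identical(generate_curve(cfg1)$stress, generate_curve(cfg1)$stress)
  cfg2 <- generator_config(cf, lambda_max = 2, n_points = 80L,
                           noise_sd = 0.01, seed = 8L)
  expect_false(identical(generate_curve(cfg1)$stress, generate_curve(cfg2)$stress))
  # plateau tail is continuous at the knee and follows its slope
  cfgp <- generator_config(cf, lambda_max = 2.2, n_points = 121L,
                           plateau_at = 1.8, plateau_slope = 0.05)
  cvp <- generate_curve(cfgp)
  after <- cvp$stretch > 1.8
  expect_equal(cvp$stress[after],
               uniaxial_stress(cf, 1.8) + 0.05 * (cvp$stretch[after] - 1.8))
  # invalid configs list the offending fields
  expect_error(generator_config(cf, lambda_max = 0.9, n_points = 1L),
               "lambda_max.*n_points", class = "aneumech_validation_error")
})

test_that("specimen series round-trips through the io pipeline", {
  cf <- coefficient_set("YEOH", c(0.3, 0.08))
  cfg <- generator_config(cf, lambda_max = 2.0, n_points = 120L, noise_sd = 0,
                          stages = 4L, preconditioning_cycles = 2L, seed = 12L)
  raw <- generate_specimen_series(cfg)
  stages <- segment_stages(raw)
  expect_length(stages, 4L)                       # programmed stage count
  kept <- drop_preconditioning(stages, 2L)
  expect_length(kept, 4L)
  curves <- lapply(kept, to_curve)
  # kept cycles are the generator's designated true (softening-free) cycles:
  # the fit on the final stage recovers the generating coefficients
  ft <- fit_model(curves[[4]], "YEOH")
  expect_equal(ft$coefficients$coefficients, cf$coefficients, tolerance = 1e-3)
  expect_lt(ft$nrmse, 1e-8)
  # without dropping preconditioning the softened cycles bias the curve up
  biased <- to_curve(stages[[4]])
  expect_gt(max(biased$stress), max(curves[[4]]$stress))
  # softening factor 0 makes all cycles of a step identical (noise-free)
  cfg0 <- generator_config(cf, lambda_max = 1.6, n_points = 40L,
                           stages = 1L, preconditioning_cycles = 2L,
                           softening = 0, seed = 1L)
  raw0 <- generate_specimen_series(cfg0)
  cyc <- aneumech:::split_cycles(segment_stages(raw0)[[1]])
  expect_length(cyc, 3L)
  expect_equal(cyc[[1]]$force, cyc[[3]]$force)
})

test_that("stage segmentation recovers the programmed count across configs", {
  cf <- coefficient_set("NEO_HOOKEAN", 0.1)
  for (stages in c(1L, 2L, 5L)) {
    for (pre in c(0L, 2L)) {
      cfg <- generator_config(cf, lambda_max = 2.1, n_points = 90L,
                              stages = stages, preconditioning_cycles = pre,
                              seed = stages * 10L + pre)
      raw <- generate_specimen_series(cfg)
      expect_length(segment_stages(raw), stages)
      # the stage column is redundant with return-to-origin splitting at the
      # cycle level: without it every cycle is its own segment
      raw_nostage <- raw_test(raw$force, raw$displacement, NULL, raw$meta)
      expect_length(segment_stages(raw_nostage), stages * (pre + 1L))
    }
  }
})

test_that("generate_cohort structure, determinism and rupture round-trip", {
  coh <- generate_cohort(5, 3, stress_ratio = 3, seed = 2024L)
  expect_length(coh, 8L)
  status <- vapply(coh, function(sp) sp$meta$status, "")
  expect_identical(sum(status == "ruptured"), 5L)
  coh2 <- generate_cohort(5, 3, stress_ratio = 3, seed = 2024L)
  expect_identical(vapply(coh, function(sp) sp$meta$ultimate_stress, 0),
                   vapply(coh2, function(sp) sp$meta$ultimate_stress, 0))
  # programmed rupture point is recovered by extract_ultimates (noise-free)
  for (sp in coh[c(1, 6)]) {
    cv <- to_curve(sp$raw)
    u <- extract_ultimates(cv)
    expect_equal(u$ultimate_stress, sp$meta$ultimate_stress, tolerance = 1e-10)
    expect_equal(u$ultimate_strain, sp$meta$ultimate_strain, tolerance = 1e-10)
  }
  expect_error(generate_cohort(0, 3), class = "aneumech_validation_error")
})

test_that("a 3x median stress ratio gives > 80% exact-test power at n = (5, 3)", {
  set.seed(77)
  rejects <- replicate(200, {
    coh <- generate_cohort(5, 3, stress_ratio = 3)
    stress <- vapply(coh, function(sp) sp$meta$ultimate_stress, 0)
    status <- vapply(coh, function(sp) sp$meta$status, "")
    mann_whitney_exact(stress[status == "ruptured"],
                       stress[status == "unruptured"])$p_value <= 0.05
  })
  expect_gt(mean(rejects), 0.8)
})
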