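test_that("max_valid_stretch returns the full range on exactly-model curves", {
  cf <- coefficient_set("YEOH", c(1.12581, 0.172556))
  cv <- model_curve(cf, 2.0, n = 50L)
  res <- max_valid_stretch(cv, "YEOH")
  expect_equal(res$lambda_limit, 2.0)
  expect_false(res$failed)
  expect_lte(res$nrmse_at_limit, res$threshold)
  # threshold = +Inf degenerates to the last point (never fails)
  res_inf <- max_valid_stretch(cv, "NEO_HOOKEAN", threshold = Inf)
  expect_equal(res_inf$lambda_limit, 2.0)
})

test_that("limit search matches an exhaustive prefix-refit oracle on noiseless input", {
  cf <- coefficient_set("NEO_HOOKEAN", 0.0615)
  pc <- plateau_curve(cf, 1.8, 2.3, 40)
  thr <- 0.05
  res <- max_valid_stretch(pc, "NEO_HOOKEAN", threshold = thr)
  # oracle: literal loop over every admissible prefix, largest end in budget
  ends <- 3:length(pc$stretch)
  ok <- vapply(ends, function(e) {
    pre <- tensile_curve(pc$stretch[1:e], pc$stress[1:e], "o")
    fit_model(pre, "NEO_HOOKEAN")$nrmse <= thr
  }, TRUE)
  expect_equal(res$lambda_limit, pc$stretch[max(ends[ok])])
})

test_that("lambda_limit is monotone non-decreasing in the threshold", {
  cf <- coefficient_set("NEO_HOOKEAN", 0.1)
  set.seed(17)
  pc <- plateau_curve(cf, 1.6, 2.2, 45, noise_sd = 0.002)
  thresholds <- c(0.01, 0.03, 0.05, 0.1, 0.3)
  lims <- vapply(thresholds, function(t) {
    max_valid_stretch(pc, "NEO_HOOKEAN", threshold = t)$lambda_limit
  }, 0)
  expect_true(all(diff(lims) >= 0))
})

test_that("the failure flag reports an unreachable threshold honestly", {
  set.seed(3)
  lam <- seq(1, 2, length.out = 20)
  cv <- tensile_curve(lam, abs(rnorm(20, 0.5, 0.4)), "junk")
  res <- max_valid_stretch(cv, "NEO_HOOKEAN", threshold = 1e-6)
  expect_true(res$failed)
  expect_equal(res$lambda_limit, lam[model_spec("NEO_HOOKEAN")$n_coeffs + 2L])
})

test_that("cohort_summary computes quantiles, mean and clamped Tukey fences", {
  mk <- function(id, lim) {
    structure(list(specimen_id = id, model = model_spec("NEO_HOOKEAN"),
                   lambda_limit = lim, nrmse_at_limit = 0, threshold = 0.05,
                   fit = NULL, failed = FALSE), class = "applicability_result")
  }
  res <- lapply(1:4, function(i) mk(paste0("s", i), i))
  groups <- setNames(rep("ruptured", 4), paste0("s", 1:4))
  s <- cohort_summary(res, groups)
  expect_equal(s$q25, 1.75)      # linear-interpolation quantiles of 1:4
  expect_equal(s$q75, 3.25)
  expect_equal(s$mean, 2.5)
  # fences Q1 - 1.5 IQR = -0.5, Q3 + 1.5 IQR = 5.5, clamped to data range
  expect_equal(s$lower_fence, 1)
  expect_equal(s$upper_fence, 4)
  expect_true(s$lower_fence <= s$q25 && s$q25 <= s$q75 &&
                s$q75 <= s$upper_fence)
  # single specimen per group: all five numbers collapse to its limit
  s1 <- cohort_summary(res[1], groups[1])
  expect_equal(unlist(s1[c("lower_fence", "q25", "mean", "q75", "upper_fence")]),
               c(lower_fence = 1, q25 = 1, mean = 1, q75 = 1, upper_fence = 1))
  # permutation invariance
  s_perm <- cohort_summary(res[c(3, 1, 4, 2)], groups)
  expect_equal(s_perm, s)
  # unknown specimen -> error naming it
  expect_error(cohort_summary(res, groups[1:3]), "s4",
               class = "aneumech_validation_error")
})

test_that("recommend_model reproduces the status/deformation lookup with its boundaries", {
  la <- 1.76; lb <- 2.31; eps <- 1e-9
  pick <- function(st, lam) recommend_model(st, lam, la, lb)$name
  # the six cells
  expect_identical(pick("ruptured", 1.3), "NEO_HOOKEAN")
  expect_identical(pick("ruptured", 2.0), "YEOH")
  expect_identical(pick("ruptured", 2.5), "MR5")
  expect_identical(pick("unruptured", 1.3), "NEO_HOOKEAN")
  expect_identical(pick("unruptured", 2.0), "NEO_HOOKEAN")
  expect_identical(pick("unruptured", 2.5), "MR5")
  # boundary convention: lambda on a boundary belongs to the smaller regime
  expect_identical(pick("ruptured", la - eps), "NEO_HOOKEAN")
  expect_identical(pick("ruptured", la), "NEO_HOOKEAN")
  expect_identical(pick("ruptured", la + eps), "YEOH")
  expect_identical(pick("ruptured", lb), "YEOH")
  expect_identical(pick("ruptured", lb + eps), "MR5")
  expect_identical(pick("unruptured", la + eps), "NEO_HOOKEAN")
  expect_identical(pick("unruptured", lb), "NEO_HOOKEAN")
  expect_identical(pick("unruptured", lb + eps), "MR5")
  # no row for the healthy-artery status
  expect_error(recommend_model("not_applicable", 1.5),
               class = "aneumech_validation_error")
})
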