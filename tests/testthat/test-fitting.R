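test_that("design matrix reproduces the stress forms", {
  # hand value: NH at lambda = (1, 2) -> column (0, 2 (2 - 1/4)) = (0, 3.5)
  X <- design_matrix("NEO_HOOKEAN", c(1, 2))
  expect_equal(unname(X), matrix(c(0, 3.5), ncol = 1))
  lam <- seq(1, 2.5, length.out = 40)
  set.seed(7)
  for (name in c("NEO_HOOKEAN", "YEOH", "MR3", "MR5")) {
    ms <- model_spec(name)
    X <- design_matrix(ms, lam)
    expect_identical(ncol(X), as.integer(ms$n_coeffs))
    cf <- coefficient_set(ms, rnorm(ms$n_coeffs))
    expect_equal(drop(X %*% cf$coefficients), uniaxial_stress(cf, lam))
  }
  # Yeoh's first column is the Neo-Hookean column
  expect_equal(design_matrix("YEOH", lam)[, 1], design_matrix("NEO_HOOKEAN", lam)[, 1])
  expect_error(design_matrix("MR3", c(1, -0.5)), class = "aneumech_domain_error")
})

test_that("nrmse matches its definition and error contract", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3) / 2)
  expect_error(nrmse(c(1, -1), c(0, 0)), class = "aneumech_validation_error")
  expect_error(nrmse(1:3, 1:2), class = "aneumech_validation_error")
})

test_that("noiseless parameter recovery for every feasible printed row", {
  tab <- aneurysm_coefficients()
  checked <- 0L
  for (i in seq_len(nrow(tab))) {
    cf <- reference_coefficients(tab$id[i], tab$model[i])
    if (!stability_check(cf)$overall || linear_part(cf) < 0) next # K1/MR5, Ul/MR3
    cv <- model_curve(cf, reference_stretch_limit(tab$id[i], tab$model[i]))
    ft <- fit_model(cv, cf$model)
    tol <- if (cf$model$name == "NEO_HOOKEAN") 1e-6 else 1e-3
    expect_equal(ft$coefficients$coefficients, cf$coefficients,
                 tolerance = tol,
                 label = sprintf("recovered %s / %s", tab$id[i], tab$model[i]))
    checked <- checked + 1L
  }
  expect_identical(checked, 30L) # 32 printed rows minus K1/MR5 and Ul/MR3
})

test_that("enforcing the linear part on the infeasible MR5 row K1 activates it", {
  cf <- reference_coefficients("K1", "MR5") # linear_part < 0 as printed
  cv <- model_curve(cf, reference_stretch_limit("K1", "MR5"))
  ft <- fit_model(cv, "MR5")
  expect_true("linear_part>=0" %in% ft$active_constraints)
  expect_gte(linear_part(ft$coefficients), -1e-8)
  expect_gt(ft$nrmse, 0)
  # dropping the constraint recovers the printed row and a smaller residual
  ft_free <- fit_model(cv, "MR5", fit_options(enforce_linear_part = FALSE))
  expect_equal(ft_free$coefficients$coefficients, cf$coefficients, tolerance = 1e-3)
  expect_lt(ft_free$rss, ft$rss)
})

test_that("constrained optimum beats every feasible point of a brute-force grid", {
  # NH (1 coeff), Yeoh (2), MR3 (3) on short curves, incl. data pushing the
  # fit against the constraints (negative late curvature).
  set.seed(23)
  lam <- seq(1, 1.9, length.out = 25)
  cases <- list(
    list(model = "NEO_HOOKEAN",
         y = uniaxial_stress(coefficient_set("NEO_HOOKEAN", 0.1), lam) + rnorm(25, 0, 0.005)),
    list(model = "YEOH",
         y = 0.25 * (lam - 1) - 0.2 * (lam - 1)^3 + rnorm(25, 0, 0.002)),
    list(model = "MR3",
         y = 0.3 * (lam - 1) - 0.25 * (lam - 1)^2 + rnorm(25, 0, 0.002)))
  for (case in cases) {
    cv <- tensile_curve(lam, case$y, "grid")
    ms <- model_spec(case$model)
    ft <- fit_model(cv, ms)
    X <- design_matrix(ms, lam)
    cons <- aneumech:::fit_constraints(ms, fit_options())
    # grid of half-width 0.2 around the constrained optimum, pitch 0.4/30
    center <- ft$coefficients$coefficients
    axes <- lapply(center, function(c0) seq(c0 - 0.2, c0 + 0.2, length.out = 31))
    grid <- as.matrix(expand.grid(axes))
    feas <- grid[apply(grid %*% t(cons$A) >= -1e-12, 1, all), , drop = FALSE]
    rss_grid <- colSums((case$y - tcrossprod(X, feas))^2)
    expect_lte(ft$rss, min(rss_grid) + 1e-10, label = case$model)
  }
})

test_that("enlarging the feasible set never increases the optimal residual", {
  set.seed(31)
  lam <- seq(1, 2.1, length.out = 30)
  for (name in c("MR3", "MR5")) {
    for (rep in 1:5) {
      y <- 0.2 * (lam - 1) + rnorm(30, 0, 0.01)
      cv <- tensile_curve(lam, y, "mono")
      rss_full <- fit_model(cv, name)$rss
      rss_stab <- fit_model(cv, name, fit_options(enforce_linear_part = FALSE))$rss
      rss_free <- fit_model(cv, name, fit_options(FALSE, FALSE))$rss
      expect_lte(rss_stab, rss_full + 1e-12)
      expect_lte(rss_free, rss_stab + 1e-12)
    }
  }
})

test_that("Neo-Hookean recovery is robust to 1% noise", {
  c1_true <- 0.0615
  cf <- coefficient_set("NEO_HOOKEAN", c1_true)
  lam <- seq(1, 1.8, length.out = 100)
  sig0 <- uniaxial_stress(cf, lam)
  set.seed(99)
  rel_err <- replicate(200, {
    cv <- tensile_curve(lam, sig0 + rnorm(100, 0, 0.01 * max(sig0)), "noise")
    abs(fit_model(cv, "NEO_HOOKEAN")$coefficients$coefficients - c1_true) / c1_true
  })
  expect_lt(median(rel_err), 0.05)
})

test_that("fit_model enforces its preconditions and determinism", {
  cv <- model_curve(coefficient_set("NEO_HOOKEAN", 0.1), 1.5, n = 4L)
  expect_error(fit_model(cv, "MR5"), class = "aneumech_validation_error")
  cv2 <- model_curve(coefficient_set("YEOH", c(0.2, 0.05)), 2, n = 60L)
  f1 <- fit_model(cv2, "MR5")
  f2 <- fit_model(cv2, "MR5")
  expect_identical(f1$coefficients$coefficients, f2$coefficients$coefficients)
})
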