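#' Maximum valid stretch of a model on a curve
#'
#' Determines the applicability limit of a hyperelastic model: the largest
#' stretch up to which the model still fits the measured curve within a
#' stated NRMSE tolerance. Every data point is a candidate endpoint: over
#' expanding prefixes of the curve (anchored at lambda = 1, stepping
#' `stride` points) the model is refit and its NRMSE recorded; the result is
#' the largest endpoint lambda whose prefix fit has NRMSE <= `threshold`.
#' If even the smallest admissible prefix (n_coeffs + 2 points) exceeds the
#' threshold, the limit is reported at that smallest prefix with
#' `failed = TRUE`.
#'
#' @param curve a [tensile_curve()] with at least `n_coeffs + 2` points.
#' @param model a [model_spec()] or model name.
#' @param threshold NRMSE tolerance (> 0, default 0.05).
#' @param options a [fit_options()] passed to every refit.
#' @param stride prefix step in points (default 1).
#' @return an object of class `applicability_result`: `specimen_id`,
#'   `model`, `lambda_limit`, `nrmse_at_limit`, `threshold`, `fit` (the
#'   [fit_model()] result at the limit), `failed`.
#' @export
max_valid_stretch <- function(curve, model, threshold = 0.05,
                              options = fit_options(), stride = 1L) {
  stopifnot(inherits(curve, "tensile_curve"))
  model <- as_model_spec(model)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0) { # +Inf is a valid "accept all"
    abort_validation("`threshold` must be a single value > 0")
  }
  stride <- as.integer(stride)
  if (stride < 1L) abort_validation("`stride` must be >= 1")
  n <- length(curve$stretch)
  n_min <- model$n_coeffs + 2L
  if (n < n_min) {
    abort_validation(sprintf(
      "curve has %d points; the limit search for %s needs at least %d",
      n, model$name, n_min))
  }
  ends <- unique(c(seq(n_min, n, by = stride), n))
  best <- NULL
  first <- NULL
  for (e in ends) {
    pre <- tensile_curve(curve$stretch[1:e], curve$stress[1:e],
                         curve$specimen_id, curve$stage)
    ft <- fit_model(pre, model, options)
    if (is.null(first)) first <- list(end = e, fit = ft)
    if (ft$nrmse <= threshold) best <- list(end = e, fit = ft)
  }
  failed <- is.null(best)
  if (failed) best <- first
  structure(list(specimen_id = curve$specimen_id,
                 model = model,
                 lambda_limit = curve$stretch[best$end],
                 nrmse_at_limit = best$fit$nrmse,
                 threshold = threshold,
                 fit = best$fit,
                 failed = failed),
            class = "applicability_result")
}

#' @export
print.applicability_result <- function(x, ...) {
  cat(sprintf("<applicability_result> %s / %s: lambda_limit = %.5f (NRMSE %.4g, threshold %.3g)%s\n",
              x$specimen_id, x$model$name, x$lambda_limit, x$nrmse_at_limit,
              x$threshold, if (x$failed) " [FAILED: no prefix within threshold]" else ""))
  invisible(x)
}

#' Cohort summary of applicability limits
#'
#' Summarises `lambda_limit` per (group, model) with the five numbers shown
#' on box-style applicability plots: lower fence, 25% quantile, mean, 75%
#' quantile, upper fence. Quantiles use linear interpolation
#' (`stats::quantile` type 7); fences are Tukey's `Q1 - 1.5 IQR` /
#' `Q3 + 1.5 IQR`, clamped to the observed minimum / maximum.
#'
#' @param results list of [max_valid_stretch()] results (or a data frame
#'   with columns `specimen_id`, `model`, `lambda_limit`).
#' @param groups named character vector mapping specimen id to group label
#'   (e.g. rupture status); every specimen in `results` must be present.
#' @return a data frame with columns `group`, `model`, `n`, `lower_fence`,
#'   `q25`, `mean`, `q75`, `upper_fence`.
#' @export
cohort_summary <- function(results, groups) {
  df <- if (is.data.frame(results)) {
    results
  } else {
    do.call(rbind, lapply(results, function(r) {
      data.frame(specimen_id = r$specimen_id, model = r$model$name,
                 lambda_limit = r$lambda_limit, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(df) || nrow(df) == 0L) abort_validation("no applicability results given")
  missing_grp <- setdiff(unique(df$specimen_id), names(groups))
  if (length(missing_grp)) {
    abort_validation(sprintf("no group for specimen(s): %s",
                             paste(missing_grp, collapse = ", ")))
  }
  df$group <- unname(groups[df$specimen_id])
  combos <- unique(df[c("group", "model")])
  combos <- combos[order(combos$group, combos$model), , drop = FALSE]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    v <- df$lambda_limit[df$group == combos$group[i] & df$model == combos$model[i]]
    if (length(v) == 0L) {
      abort_validation(sprintf("empty group '%s'", combos$group[i]))
    }
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    data.frame(group = combos$group[i], model = combos$model[i],
               n = length(v),
               lower_fence = max(q[1] - 1.5 * iqr, min(v)),
               q25 = q[1], mean = mean(v), q75 = q[2],
               upper_fence = min(q[2] + 1.5 * iqr, max(v)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recommended hyperelastic model by aneurysm status and deformation level
#'
#' Looks up the optimal model for an FSI simulation given the aneurysm's
#' rupture status and the stretch level of interest. Deformation regimes
#' are bounded by `lambda_a` (small/medium) and `lambda_b` (medium/large);
#' a stretch exactly on a boundary belongs to the smaller-deformation
#' regime. Ruptured: Neo-Hookean (small), Yeoh (medium), MR5 (large).
#' Unruptured: Neo-Hookean (small and medium), MR5 (large).
#'
#' @param status `"ruptured"` or `"unruptured"` (`"not_applicable"` has no
#'   recommendation and errors).
#' @param stretch stretch ratio lambda >= 1 of the regime of interest.
#' @param lambda_a,lambda_b regime boundaries (defaults 1.76 and 2.31).
#' @return a [model_spec()].
#' @examples
#' recommend_model("ruptured", 2.0)$name # "YEOH"
#' @export
recommend_model <- function(status, stretch, lambda_a = 1.76, lambda_b = 2.31) {
  if (identical(status, "not_applicable")) {
    abort_validation("no recommendation is defined for status 'not_applicable'")
  }
  status <- match.arg(status, c("ruptured", "unruptured"))
  check_number(stretch, "stretch", lower = 1)
  check_number(lambda_a, "lambda_a", lower = 1, strict = TRUE)
  check_number(lambda_b, "lambda_b", lower = lambda_a, strict = TRUE)
  name <- if (status == "ruptured") {
    if (stretch <= lambda_a) "NEO_HOOKEAN"
    else if (stretch <= lambda_b) "YEOH"
    else "MR5"
  } else {
    if (stretch <= lambda_b) "NEO_HOOKEAN" else "MR5"
  }
  model_spec(name)
}
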