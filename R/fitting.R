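#' Fitting options
#'
#' Controls which physical constraints the coefficient identification
#' enforces.
#'
#' @param enforce_stability enforce the Drucker-type sign conditions of
#'   [stability_check()] (default `TRUE`). MR5's strict `C5 < 0` is relaxed
#'   to `C5 <= 0` so the feasible set is closed; a fit landing on `C5 = 0`
#'   is flagged as a boundary solution.
#' @param enforce_linear_part enforce `linear_part(coeffs) >= 0`
#'   (default `TRUE`).
#' @param tolerance solver convergence / rank-truncation tolerance (> 0).
#' @param active_tol a constraint with margin below this value (MPa) at the
#'   optimum is reported active.
#' @return an object of class `fit_options`.
#' @export
fit_options <- function(enforce_stability = TRUE,
                        enforce_linear_part = TRUE,
                        tolerance = 1e-10,
                        active_tol = 1e-8) {
  stopifnot(is.logical(enforce_stability), length(enforce_stability) == 1L,
            is.logical(enforce_linear_part), length(enforce_linear_part) == 1L)
  check_number(tolerance, "tolerance", lower = 0, strict = TRUE)
  check_number(active_tol, "active_tol", lower = 0)
  structure(list(enforce_stability = enforce_stability,
                 enforce_linear_part = enforce_linear_part,
                 tolerance = tolerance,
                 active_tol = active_tol),
            class = "fit_options")
}

#' Design matrix of a hyperelastic model
#'
#' All four supported stress forms are linear in their coefficients, so the
#' least-squares problem is linear: column j of the design matrix is
#' `d sigma / d C_j` evaluated at each stretch, and
#' `uniaxial_stress(coeffs, lam)` equals `design_matrix(model, lam) %*% C`
#' for every coefficient vector.
#'
#' @param model a [model_spec()] or model name.
#' @param stretches stretch ratios (> 0).
#' @return numeric matrix, `length(stretches)` rows by `n_coeffs` columns.
#' @export
design_matrix <- function(model, stretches) {
  model <- as_model_spec(model)
  lam <- check_stretch(stretches)
  model_basis(model, lam)
}

#' Normalised root-mean-square error
#'
#' `NRMSE = sqrt(mean((y_e - y_m)^2)) / abs(mean(y_e))` where `y_e` are the
#' observed (experimental) and `y_m` the model values.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 1).
#' @return a single non-negative number.
#' @examples
#' nrmse(c(1, 2, 3), c(1, 2, 4)) # sqrt(1/3)/2
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    abort_validation("`observed` and `predicted` must have equal length >= 1")
  }
  m <- mean(observed)
  if (!is.finite(m) || m == 0) {
    abort_validation("NRMSE is undefined: mean of observed values is 0")
  }
  sqrt(mean((observed - predicted)^2)) / abs(m)
}

# --- constrained linear least squares -------------------------------------
#
# min ||X c - y||^2  s.t.  A c >= 0   (all constraints homogeneous).
#
# Convex QP in <= 5 variables with <= 5 constraints. Solved by enumerating
# every subset S of constraints as the candidate active set: minimise on the
# subspace {A_S c = 0} via an SVD nullspace basis, keep the feasible
# candidate with the smallest residual. The true optimum's active set is one
# of the subsets, so the minimum over feasible candidates is the global
# optimum. Deterministic, no initialisation.
solve_constrained_ls <- function(X, y, A, feas_tol = 1e-9, rank_tol = 1e-12) {
  p <- ncol(X)
  if (is.null(A) || nrow(A) == 0L) {
    cf <- svd_lstsq(X, y, rank_tol)
    return(list(coefficients = cf, rss = sum((y - X %*% cf)^2)))
  }
  m <- nrow(A)
  scale_ok <- function(cf) all(A %*% cf >= -feas_tol * pmax(1, rowSums(abs(A))))
  best <- NULL
  for (mask in 0:(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    if (length(S) == 0L) {
      cf <- svd_lstsq(X, y, rank_tol)
    } else {
      N <- null_space(A[S, , drop = FALSE], rank_tol)
      if (ncol(N) == 0L) {
        cf <- rep(0, p)
      } else {
        theta <- svd_lstsq(X %*% N, y, rank_tol)
        cf <- drop(N %*% theta)
      }
    }
    if (!scale_ok(cf)) next
    rss <- sum((y - X %*% cf)^2)
    if (is.null(best) || rss < best$rss - 0) best <- list(coefficients = cf, rss = rss)
  }
  if (is.null(best)) {
    abort_aneumech("constraint set infeasible (should not occur: c = 0 is always feasible)",
                   "aneumech_infeasibility_error")
  }
  best
}

svd_lstsq <- function(X, y, rank_tol = 1e-12) {
  s <- svd(X)
  keep <- s$d > rank_tol * max(s$d, .Machine$double.eps)
  if (!any(keep)) return(rep(0, ncol(X)))
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep]))
}

null_space <- function(A, rank_tol = 1e-12) {
  p <- ncol(A)
  s <- svd(A, nu = 0, nv = p)
  rank <- sum(s$d > rank_tol * max(s$d, .Machine$double.eps))
  if (rank >= p) return(matrix(numeric(0), nrow = p, ncol = 0))
  s$v[, (rank + 1L):p, drop = FALSE]
}

# Assemble the enforced constraint rows for a model under the given options.
fit_constraints <- function(model, options) {
  model <- as_model_spec(model)
  A <- matrix(numeric(0), nrow = 0, ncol = model$n_coeffs)
  labels <- character(0)
  if (isTRUE(options$enforce_stability)) {
    sc <- stability_constraints(model)
    A <- rbind(A, sc$A)
    labels <- c(labels, sc$labels)
  }
  if (isTRUE(options$enforce_linear_part)) {
    A <- rbind(A, linear_part_weights(model))
    labels <- c(labels, "linear_part>=0")
  }
  list(A = A, labels = labels)
}

#' Fit a hyperelastic model to a stress-stretch curve
#'
#' Identifies the model coefficients by least squares, optionally subject to
#' the Drucker-type stability conditions and the non-negativity of the
#' linear energy coefficient. Because every supported stress form is linear
#' in its coefficients, the problem is a convex inequality-constrained
#' linear least-squares problem and the solution is deterministic (no random
#' initialisation).
#'
#' @param curve a [tensile_curve()].
#' @param model a [model_spec()] or model name.
#' @param options a [fit_options()].
#' @return an object of class `fit_result`: `coefficients` (a
#'   [coefficient_set()]), `nrmse`, `active_constraints` (labels of enforced
#'   constraints with margin at zero, e.g. a boundary `C5 = 0`), `window`
#'   `(lambda_min, lambda_max)`, `n_points` and `rss`.
#' @export
fit_model <- function(curve, model, options = fit_options()) {
  stopifnot(inherits(curve, "tensile_curve"))
  model <- as_model_spec(model)
  if (!inherits(options, "fit_options")) abort_validation("`options` must be fit_options()")
  n <- length(curve$stretch)
  if (n < model$n_coeffs + 1L) {
    abort_validation(sprintf(
      "curve has %d points; fitting %s needs at least %d",
      n, model$name, model$n_coeffs + 1L))
  }
  X <- design_matrix(model, curve$stretch)
  cons <- fit_constraints(model, options)
  sol <- solve_constrained_ls(X, curve$stress, cons$A)
  cf <- coefficient_set(model, sol$coefficients)
  active <- character(0)
  if (nrow(cons$A)) {
    margins <- drop(cons$A %*% sol$coefficients)
    active <- cons$labels[margins <= options$active_tol]
  }
  structure(list(coefficients = cf,
                 nrmse = nrmse(curve$stress, drop(X %*% sol$coefficients)),
                 active_constraints = active,
                 window = c(lambda_min = min(curve$stretch),
                            lambda_max = max(curve$stretch)),
                 n_points = n,
                 rss = sol$rss,
                 options = options),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s over lambda [%.4f, %.4f], n = %d\n",
              x$coefficients$model$name, x$window[1], x$window[2], x$n_points))
  cat(sprintf("  C = (%s) MPa\n", paste(signif(x$coefficients$coefficients, 6),
                                        collapse = ", ")))
  cat(sprintf("  NRMSE = %.4g", x$nrmse))
  if (length(x$active_constraints)) {
    cat(sprintf("  active: %s", paste(x$active_constraints, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
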