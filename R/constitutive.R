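#' Hyperelastic model specification
#'
#' The four incompressible hyperelastic models supported by the package and
#' the number of material coefficients each carries. All coefficients are in
#' MPa; the volumetric part of the generalised Rivlin expansion is dropped
#' under incompressibility (J = 1).
#'
#' @param name one of `"NEO_HOOKEAN"` (1 coefficient), `"YEOH"` (2),
#'   `"MR3"` (Mooney-Rivlin 3-parameter, 3) or `"MR5"` (Mooney-Rivlin
#'   5-parameter, 5).
#' @return an object of class `model_spec` with fields `name` and `n_coeffs`.
#' @examples
#' model_spec("YEOH")$n_coeffs # 2
#' @export
model_spec <- function(name = c("NEO_HOOKEAN", "YEOH", "MR3", "MR5")) {
  name <- match.arg(name)
  n <- c(NEO_HOOKEAN = 1L, YEOH = 2L, MR3 = 3L, MR5 = 5L)[[name]]
  structure(list(name = name, n_coeffs = n), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d coefficient%s)\n", x$name, x$n_coeffs,
              if (x$n_coeffs > 1L) "s" else ""))
  invisible(x)
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) return(model)
  if (is.character(model) && length(model) == 1L) return(model_spec(model))
  abort_validation("`model` must be a model_spec or a model name")
}

#' Coefficient set for a hyperelastic model
#'
#' Couples a [model_spec()] with its material coefficients C1..Cn (MPa).
#'
#' @param model a [model_spec()] or model name.
#' @param coefficients numeric vector of length `model$n_coeffs`, all finite.
#' @return an object of class `coefficient_set`.
#' @examples
#' coefficient_set("NEO_HOOKEAN", 0.0615)
#' @export
coefficient_set <- function(model, coefficients) {
  model <- as_model_spec(model)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != model$n_coeffs) {
    abort_validation(sprintf(
      "%s requires %d coefficients, got %d",
      model$name, model$n_coeffs, length(coefficients)))
  }
  if (!all(is.finite(coefficients))) {
    abort_validation("all coefficients must be finite")
  }
  structure(list(model = model, coefficients = coefficients),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s: %s MPa\n", x$model$name,
              paste(signif(x$coefficients, 6), collapse = ", ")))
  invisible(x)
}

check_stretch <- function(stretch) {
  if (!is.numeric(stretch) || length(stretch) == 0L) {
    abort_domain("`stretch` must be a non-empty numeric vector")
  }
  if (any(!is.finite(stretch)) || any(stretch <= 0)) {
    abort_domain("stretch ratios must be finite and > 0")
  }
  as.numeric(stretch)
}

#' Uniaxial nominal stress of a hyperelastic model
#'
#' Evaluates the uniaxial stress sigma(lambda) = F/S0 (MPa) of an
#' incompressible hyperelastic model, exactly as the closed forms are
#' conventionally printed for tensile-test identification:
#' \describe{
#'   \item{Neo-Hookean}{`2 C1 (lambda - lambda^-2)`}
#'   \item{Yeoh}{`2 (lambda - lambda^-2) (C1 + 2 C2 (lambda^2 + 2/lambda - 3))`}
#'   \item{MR3}{`2 C1 (lambda - 1/lambda) + 2 C2 (1 - lambda^-3) +
#'     6 C3 (lambda^2 - lambda - 1 + lambda^-2 + lambda^-3 - lambda^-4)`}
#'   \item{MR5}{MR3 plus
#'     `4 C4 lambda (1 - lambda^-3)(lambda^2 + 2/lambda - 3) +
#'      4 C5 (2 lambda + lambda^-2 - 3)(1 - lambda^-3)`}
#' }
#' Note that the Mooney-Rivlin forms are implemented verbatim: their first
#' term `2 C1 (lambda - 1/lambda)` does not reduce to the Neo-Hookean form at
#' C2 = C3 = 0, and no "correction" is applied (see the methods vignette).
#'
#' @param coeffs a [coefficient_set()].
#' @param stretch stretch ratio lambda = l/l0 (> 0), scalar or vector.
#' @return stress in MPa, same length as `stretch`; exactly 0 at lambda = 1.
#' @examples
#' uniaxial_stress(coefficient_set("NEO_HOOKEAN", 0.0615), 1.5)
#' @export
uniaxial_stress <- function(coeffs, stretch) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  lam <- check_stretch(stretch)
  drop(model_basis(coeffs$model, lam) %*% coeffs$coefficients)
}

# The stress of every supported model is linear in its coefficients; column j
# is d sigma / d C_j. Shared by uniaxial_stress() and design_matrix().
model_basis <- function(model, lam) {
  model <- as_model_spec(model)
  nh <- 2 * (lam - lam^-2)
  switch(model$name,
    NEO_HOOKEAN = cbind(C1 = nh),
    YEOH = cbind(C1 = nh, C2 = 2 * nh * (lam^2 + 2 / lam - 3)),
    MR3 = mr3_basis(lam),
    MR5 = {
      b <- mr3_basis(lam)
      cbind(b,
            C4 = 4 * lam * (1 - lam^-3) * (lam^2 + 2 / lam - 3),
            C5 = 4 * (2 * lam + lam^-2 - 3) * (1 - lam^-3))
    })
}

mr3_basis <- function(lam) {
  cbind(C1 = 2 * (lam - 1 / lam),
        C2 = 2 * (1 - lam^-3),
        C3 = 6 * (lam^2 - lam - 1 + lam^-2 + lam^-3 - lam^-4))
}

#' Strain energy density under uniaxial incompressible kinematics
#'
#' Evaluates the strain energy density W (MPa) with the standard
#' incompressible uniaxial substitutions I1 = lambda^2 + 2/lambda,
#' I2 = 2 lambda + 1/lambda^2, J = 1 (volumetric terms dropped):
#' Neo-Hookean `W = C1 (I1 - 3)`; Yeoh `W = C1 (I1 - 3) + C2 (I1 - 3)^2`
#' (the cubic Yeoh term is fixed at zero since the stress form uses only
#' C1, C2); MR3 `W = C1 (I1 - 3) + C2 (I2 - 3) + C3 (I1 - 3)(I2 - 3)`;
#' MR5 adds `C4 (I1 - 3)^2 + C5 (I2 - 3)^2`.
#'
#' @inheritParams uniaxial_stress
#' @return energy density in MPa; exactly 0 at lambda = 1.
#' @export
strain_energy <- function(coeffs, stretch) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  lam <- check_stretch(stretch)
  i1 <- lam^2 + 2 / lam - 3
  i2 <- 2 * lam + lam^-2 - 3
  cf <- coeffs$coefficients
  switch(coeffs$model$name,
    NEO_HOOKEAN = cf[1] * i1,
    YEOH = cf[1] * i1 + cf[2] * i1^2,
    MR3 = cf[1] * i1 + cf[2] * i2 + cf[3] * i1 * i2,
    MR5 = cf[1] * i1 + cf[2] * i2 + cf[3] * i1 * i2 +
      cf[4] * i1^2 + cf[5] * i2^2)
}

#' Linear part of the elastic energy
#'
#' The coefficient in front of the linear energy term, interpreted as the
#' small-strain stiffness of the model: `C1` for Neo-Hookean and Yeoh,
#' `C1 - 3 C3` for MR3 and `C1 - 3 C3 - 6 C4 + 4 C5` for MR5. Physical
#' identification requires it to be non-negative; [fit_model()] can enforce
#' this.
#'
#' @param coeffs a [coefficient_set()].
#' @return a single number in MPa.
#' @export
linear_part <- function(coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  drop(linear_part_weights(coeffs$model) %*% coeffs$coefficients)
}

linear_part_weights <- function(model) {
  model <- as_model_spec(model)
  switch(model$name,
    NEO_HOOKEAN = 1,
    YEOH = c(1, 0),
    MR3 = c(1, 0, -3),
    MR5 = c(1, 0, -3, -6, 4))
}

# Linear forms a . C with the convention "a . C >= 0 is required";
# `strict_upper` marks conditions of the form a . C > 0 (only MR5's C5 < 0,
# written as -C5 > 0). Returns a list(matrix A, labels, strict).
stability_constraints <- function(model) {
  model <- as_model_spec(model)
  switch(model$name,
    NEO_HOOKEAN = ,
    YEOH = list(A = matrix(numeric(0), nrow = 0, ncol = model$n_coeffs),
                labels = character(0), strict = logical(0)),
    MR3 = list(
      A = rbind(c(1, 1, 0), c(0, 0, 1)),
      labels = c("C1+C2>=0", "C3>=0"),
      strict = c(FALSE, FALSE)),
    MR5 = list(
      A = rbind(c(1, 1, 0, 0, 0),
                c(0, 0, 0, 1, 0),
                c(0, 0, 0, 0, -1),
                c(0, 0, 1, 1, 1)),
      labels = c("C1+C2>=0", "C4>=0", "C5<0", "C3+C4+C5>=0"),
      strict = c(FALSE, FALSE, TRUE, FALSE)))
}

#' Drucker-type stability check for Mooney-Rivlin coefficients
#'
#' Checks the coefficient sign conditions implied by material stability
#' (non-negative work of stress increments): for MR3, `C1 + C2 >= 0` and
#' `C3 >= 0`; for MR5, `C1 + C2 >= 0`, `C4 >= 0`, `C5 < 0` and
#' `C3 + C4 + C5 >= 0`. Neo-Hookean and Yeoh carry no stated conditions and
#' pass vacuously (the report notes this). Because printed coefficient
#' tables are rounded, each condition is evaluated with a small absolute
#' tolerance.
#'
#' @param coeffs a [coefficient_set()].
#' @param tolerance non-negative slack in MPa applied to every condition
#'   (default `1e-5`): `a . C >= 0` passes when `a . C >= -tolerance`, and
#'   the strict `C5 < 0` passes when `C5 < +tolerance`.
#' @return an object of class `stability_report`: a list with `model`,
#'   a data frame `conditions` (label, margin, pass) and logical `overall`
#'   (the conjunction; `TRUE` with a note when no conditions apply).
#' @examples
#' stability_check(coefficient_set("MR3", c(0.479274, -0.43089, 0.159734)))
#' @export
stability_check <- function(coeffs, tolerance = 1e-5) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  check_number(tolerance, "tolerance", lower = 0)
  cons <- stability_constraints(coeffs$model)
  if (length(cons$labels) == 0L) {
    rep <- list(model = coeffs$model,
                conditions = data.frame(label = character(0),
                                        margin = numeric(0),
                                        pass = logical(0)),
                overall = TRUE,
                note = "no stability conditions stated for this model")
    return(structure(rep, class = "stability_report"))
  }
  margin <- drop(cons$A %*% coeffs$coefficients)
  pass <- margin >= -tolerance
  structure(list(model = coeffs$model,
                 conditions = data.frame(label = cons$labels,
                                         margin = margin,
                                         pass = pass),
                 overall = all(pass),
                 note = NULL),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s: overall %s\n", x$model$name,
              if (x$overall) "PASS" else "FAIL"))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  if (nrow(x$conditions)) {
    for (i in seq_len(nrow(x$conditions))) {
      cat(sprintf("  %-12s margin %+.3e  %s\n", x$conditions$label[i],
                  x$conditions$margin[i],
                  if (x$conditions$pass[i]) "pass" else "FAIL"))
    }
  }
  invisible(x)
}
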