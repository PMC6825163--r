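# Published reference values shipped with the package as plain CSV under
# inst/extdata. Specimen ids follow the study cohort: 8 aneurysm specimens
# (5 ruptured: V, Z, U, M, Ul; 3 unruptured: R, K2, K1) and 2 healthy
# temporal-artery records (A1, A2) that carry no rupture status.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "aneumech")
  if (!nzchar(p)) abort_io(sprintf("packaged reference file missing: %s", file))
  p
}

#' Published specimen characteristics
#'
#' Geometry, rupture status and ultimate stress/strain for the study
#' cohort. The strain limit is stored verbatim as a dimensionless value;
#' whether it is engineering strain or stretch is left to the caller (most
#' printed values exceed 1).
#'
#' @return a data frame with columns `id`, `status`, `thickness_mm`,
#'   `width_mm`, `area_mm2`, `ultimate_strain`, `ultimate_stress_MPa`.
#' @export
aneurysm_specimens <- function() {
  utils::read.csv(ref_path("specimens.csv"), stringsAsFactors = FALSE)
}

#' Published hyperelastic coefficients
#'
#' Fitted coefficients (MPa) of all four models for each aneurysm specimen,
#' at the moment of maximum relative elongation.
#'
#' @return a data frame with columns `id`, `model`, `C1`..`C5` (`NA` where
#'   the model has fewer coefficients).
#' @export
aneurysm_coefficients <- function() {
  utils::read.csv(ref_path("coefficients.csv"), stringsAsFactors = FALSE)
}

#' Published applicability limits
#'
#' Maximum stretch ratio per specimen at which each model still
#' approximates the measured curve sufficiently well.
#'
#' @return a data frame with columns `id`, `MR3`, `MR5`, `YEOH`,
#'   `NEO_HOOKEAN`.
#' @export
aneurysm_stretch_limits <- function() {
  utils::read.csv(ref_path("stretch_limits.csv"), stringsAsFactors = FALSE)
}

#' Look up a published coefficient set
#'
#' @param id specimen id (e.g. `"K2"`).
#' @param model model name or [model_spec()].
#' @return a [coefficient_set()] built from the published table.
#' @examples
#' reference_coefficients("K2", "NEO_HOOKEAN")
#' @export
reference_coefficients <- function(id, model) {
  model <- as_model_spec(model)
  tab <- aneurysm_coefficients()
  row <- tab[tab$id == id & tab$model == model$name, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort_validation(sprintf("no published coefficients for %s / %s",
                             id, model$name))
  }
  coefficient_set(model, as.numeric(row[1, 2L + seq_len(model$n_coeffs)]))
}

#' Look up a published applicability limit
#'
#' @inheritParams reference_coefficients
#' @return the published maximum stretch ratio (a single number).
#' @export
reference_stretch_limit <- function(id, model) {
  model <- as_model_spec(model)
  tab <- aneurysm_stretch_limits()
  row <- tab[tab$id == id, , drop = FALSE]
  if (nrow(row) != 1L) abort_validation(sprintf("no published limits for %s", id))
  row[[model$name]][1]
}

#' Serialise a coefficient set to JSON
#'
#' @param coeffs a [coefficient_set()].
#' @return a JSON string `{"model": ..., "coefficients_MPa": [...]}`.
#' @export
coefficients_to_json <- function(coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  jsonlite::toJSON(list(model = coeffs$model$name,
                        coefficients_MPa = coeffs$coefficients),
                   auto_unbox = TRUE, digits = NA)
}
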