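Package: aneumech
Title: Hyperelastic Model Fitting and Applicability Limits for Cerebral
    Aneurysm Wall Tissue
Version: 0.1.0
Authors@R:
    person("Aneumech", "Maintainers", email = "maintainers@aneumech.org",
           role = c("aut", "cre"))
Description: Tools for the mechanical characterisation of cerebral aneurysm
    wall tissue from uniaxial tensile tests. Reads raw tensile-machine
    records (force, crosshead displacement, stage), segments loading stages,
    removes preconditioning cycles, converts to stress-stretch curves and
    truncates at the plasticity plateau. Fits four incompressible
    hyperelastic models (Neo-Hookean, Yeoh, Mooney-Rivlin 3- and
    5-parameter) by inequality-constrained linear least squares with
    Drucker-type stability conditions and a non-negative linear-energy
    coefficient, scores fits by normalised root-mean-square error (NRMSE),
    and determines each model's maximum valid stretch by an expanding-prefix
    refit search. Cohorts of ruptured and unruptured specimens are compared
    with an exact small-sample Mann-Whitney test, and a deformation-regime
    lookup recommends the optimal model per aneurysm status. A seeded
    synthetic-data generator emulates the full experimental protocol so the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
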