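# aneumech

Mechanical characterisation of cerebral aneurysm wall tissue from uniaxial
tensile tests.

Preoperative fluid–structure interaction (FSI) modelling of cerebral
aneurysms needs a constitutive model for the vessel and aneurysm wall, and
the right choice depends on the aneurysm's rupture status and on the
deformation range the simulation will explore. `aneumech` implements the
complete desk-side analysis that turns raw tensile-machine records of
aneurysm wall specimens into that choice:

1. **Preprocessing** — read force/displacement/stage records, segment the
   programmed loading stages, discard preconditioning cycles (biological
   tissue softens over the first loadings), convert to stress–stretch
   curves with σ = F/S₀ (MPa) and λ = l/l₀ = ε + 1, and truncate each curve
   at the plasticity plateau beyond which a hyperelastic description is
   meaningless.
2. **Constitutive fitting** — identify the coefficients of four
   incompressible hyperelastic models (Neo-Hookean, Yeoh, 3- and
   5-parameter Mooney-Rivlin). All four uniaxial stress forms are linear in
   their coefficients, e.g. Neo-Hookean σ = 2C₁(λ − λ⁻²) and Yeoh
   σ = 2(λ − λ⁻²)(C₁ + 2C₂(λ² + 2/λ − 3)), so the problem is solved as an
   inequality-constrained **linear** least squares — deterministic, no
   initial guesses. The constraints are the Drucker-type stability
   conditions (MR3: C₁+C₂ ≥ 0, C₃ ≥ 0; MR5: C₁+C₂ ≥ 0, C₄ ≥ 0, C₅ < 0,
   C₃+C₄+C₅ ≥ 0) and non-negativity of the linear energy coefficient
   (C₁ for Neo-Hookean/Yeoh, C₁ − 3C₃ for MR3, C₁ − 3C₃ − 6C₄ + 4C₅ for
   MR5).
3. **Applicability limits** — fit quality is scored by the normalised RMS
   error, NRMSE = √(n⁻¹Σ(yₑ − yₘ)²) / |n⁻¹Σyₑ|; the *applicability limit*
   of a model on a curve is the largest stretch λ such that refitting on
   the prefix [1, λ] stays within an NRMSE tolerance (default 0.05). Limits
   are summarised per cohort (lower fence, Q1, mean, Q3, upper fence).
4. **Cohort statistics** — ultimate stress and strain per specimen,
   compared between ruptured and unruptured cohorts with an **exact**
   small-sample Mann-Whitney U test (complete enumeration of all group
   assignments; mid-ranks for ties; no normal approximation).
5. **Recommendation** — the status × deformation-regime lookup for FSI
   work, with regime boundaries λₐ = 1.76 and λᵦ = 2.31: ruptured →
   Neo-Hookean / Yeoh / MR5 for small / medium / large deformations;
   unruptured → Neo-Hookean up to λᵦ, MR5 beyond.

The published specimen characteristics, fitted coefficients and
applicability limits of the 8-specimen aneurysm cohort (5 ruptured, 3
unruptured, plus 2 healthy temporal-artery records) ship as plain-CSV
reference tables (`aneurysm_specimens()`, `aneurysm_coefficients()`,
`aneurysm_stretch_limits()`). Because the raw machine records are not
deposited anywhere, a seeded synthetic generator
(`generate_curve()`, `generate_specimen_series()`, `generate_cohort()`)
emulates the full protocol — multi-stage loading, preconditioning
softening, plateau, rupture, measurement noise — so every pipeline stage is
testable end to end.

## Worked example

Recover the published Yeoh coefficients of specimen Z from a noisy
synthetic curve over its published window, find an applicability limit on a
curve with a plateau, and run the cohort test on the published ultimates:

```r
library(aneumech)

cf <- reference_coefficients("Z", "YEOH")       # C = (1.12581, 0.172556) MPa
curve <- generate_curve(generator_config(cf, lambda_max = 2.00094,
                                         n_points = 120L, noise_sd = 0.01,
                                         seed = 42L), specimen_id = "Z")
fit_model(curve, "YEOH")
#> <fit_result> YEOH over lambda [1.0000, 2.0009], n = 120
#>   C = (1.12589, 0.172543) MPa
#>   NRMSE = 0.003503

lim <- max_valid_stretch(
  generate_curve(generator_config(cf, lambda_max = 2.3, n_points = 60L,
                                  plateau_at = 1.95, noise_sd = 0.005,
                                  seed = 42L), specimen_id = "Z"),
  "YEOH", threshold = 0.05)
lim
#> <applicability_result> Z / YEOH: lambda_limit = 2.05763 (NRMSE 0.04357, threshold 0.05)

sp <- aneurysm_specimens()
mann_whitney_exact(sp$ultimate_stress_MPa[sp$status == "ruptured"],
                   sp$ultimate_stress_MPa[sp$status == "unruptured"])
#> <mw_test_result> exact Mann-Whitney: U = 0 (n1 = 5, n2 = 3), two_sided p = 0.0357143

recommend_model("ruptured", 2.0)
#> <model_spec> YEOH (2 coefficients)
```

The fit recovers the generating coefficients to 0.01% despite 1% noise; the
applicability search places the Yeoh limit just past the plateau knee at
λ ≈ 1.95; U = 0 is complete separation of the cohorts (every unruptured
ultimate stress exceeds every ruptured one), and p = 2/56 ≈ 0.036 is the
smallest two-sided p an exact test can produce at n = 5 vs 3 — significant
at 0.05; and at medium deformation a ruptured aneurysm is best served by
the Yeoh model.

## End-to-end runs

`cmd_simulate()`, `cmd_fit()`, `cmd_limits()` and `cmd_compare()` run whole
cohorts from a JSON config (`run_config()`), writing tidy CSV/JSON reports;
`aneumech_cli()` (installed wrapper in `inst/cli/aneumech`) exposes them as
`fit` / `limits` / `compare` / `simulate` subcommands with exit codes
0 (success) / 2 (validation) / 3 (I/O).

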