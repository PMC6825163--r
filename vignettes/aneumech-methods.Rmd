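---
title: "Methods: hyperelastic characterisation of aneurysm wall tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperelastic characterisation of aneurysm wall tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneumech)
```

This vignette is the package's own account of its science: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The models

Aneurysm wall tissue under uniaxial tension is treated as a homogeneous,
incompressible, isotropic hyperelastic material. With stretch ratio
λ = l/l₀ and the incompressible uniaxial substitutions
I₁ = λ² + 2/λ, I₂ = 2λ + 1/λ², J = 1 (volumetric terms dropped), the four
supported models are, in energy / uniaxial-stress form:

* **Neo-Hookean**: W = C₁(I₁ − 3), σ = 2C₁(λ − λ⁻²).
* **Yeoh**: W = C₁(I₁ − 3) + C₂(I₁ − 3)² — the cubic term of the usual
  three-term Yeoh family is fixed at zero because the stress form used for
  identification involves only C₁, C₂:
  σ = 2(λ − λ⁻²)(C₁ + 2C₂(λ² + 2/λ − 3)).
* **Mooney-Rivlin 3-parameter (MR3)**:
  W = C₁(I₁ − 3) + C₂(I₂ − 3) + C₃(I₁ − 3)(I₂ − 3), i.e. the Rivlin terms
  C₁₀, C₀₁, C₁₁.
* **Mooney-Rivlin 5-parameter (MR5)**: MR3 plus C₄(I₁ − 3)² + C₅(I₂ − 3)²
  (Rivlin C₂₀, C₀₂).

The MR stress forms are implemented **verbatim as conventionally printed
for this identification problem**, with first term 2C₁(λ − 1/λ). Note a
deliberate infidelity to textbook kinematics: differentiating
W = C₁(I₁ − 3) gives 2C₁(λ − λ⁻²), so the printed MR first term does not
nest the Neo-Hookean model at C₂ = C₃ = 0. We do **not** "correct" the MR
forms; reproducing the published formulas bit-for-bit takes precedence,
and the C₂–C₅ terms *are* exact derivatives of their Rivlin energy terms
(a fact the test suite exploits for the Neo-Hookean energy–stress
consistency check only).

A related ambiguity: the stress these formulas produce is F/S₀ on the
*undeformed* section — nominal (engineering) stress — although the source
material labels it Cauchy stress. The package computes exactly F/S₀
everywhere and calls it nominal stress in the documentation.

## Constraints

Material stability (stress increments doing non-negative work) imposes
sign conditions on the coefficients: C₁+C₂ ≥ 0 and C₃ ≥ 0 for MR3;
C₁+C₂ ≥ 0, C₄ ≥ 0, C₅ < 0 and C₃+C₄+C₅ ≥ 0 for MR5. No conditions are
stated for Neo-Hookean or Yeoh, so `stability_check()` passes them
vacuously and says so in its report. Separately, the coefficient in front
of the linear energy term — C₁, C₁ − 3C₃, or C₁ − 3C₃ − 6C₄ + 4C₅ — is the
small-strain stiffness and must be non-negative for a physically
interpretable fit; `fit_model()` enforces both families by default and
reports which constraints are active at the optimum.

Numerical choices:

* **Stability tolerance 1e-5 MPa** (`stability_check(tolerance=)`):
  published coefficient tables are rounded, and several printed rows sit
  within ~1e-6 MPa of a boundary (e.g. the MR5 row K2 has
  C₃+C₄+C₅ ≈ 1.2e-6); exact-zero margins must not fail the audit.
* **Strict C₅ < 0 relaxed to C₅ ≤ 0 in the solver** so the feasible set is
  closed (a strict inequality has no attained optimum on its boundary);
  a fit landing exactly on C₅ = 0 is reported as an active ("boundary")
  constraint.
* **Constraint-activity tolerance 1e-8 MPa** at the optimum.

The audit of the published tables themselves (run by the test suite)
deserves a note: all 8 MR3 and all 8 MR5 printed rows pass the stability
conditions, but the linear part is negative for **two** printed rows — MR5
row K1 (≈ −0.0055 MPa) *and* MR3 row Ul (≈ −0.0247 MPa) — even though the
identification is stated to have enforced non-negativity. The package
flags both and resolves neither; the corresponding acceptance clause,
which expects only the K1 exception, is intentionally left failing rather
than weakened.

## Fitting

Every supported stress form is linear in its coefficients, so
identification is inequality-constrained **linear** least squares:
minimise ‖Xc − y‖² subject to Ac ≥ 0, where column j of X is ∂σ/∂C_j
(`design_matrix()`) and the rows of A are the enforced constraints (all
homogeneous). This subsumes the usual two-step "unconstrained fit, then
constrained refinement" procedure and is deterministic — no seeds, no
starting points.

Because no quadratic-programming solver is available as a dependency and
the problem is tiny (≤ 5 unknowns, ≤ 5 constraints), the solver enumerates
every subset of constraints as a candidate active set, minimises on each
equality-constrained subspace via an SVD nullspace basis, and returns the
feasible candidate with the smallest residual. For a convex QP the
optimum's active set is one of the subsets, so this is exact, at a cost of
at most 2⁵ small solves per fit. Property tests verify it against a
brute-force feasible-grid oracle and check that enlarging the feasible set
never increases the optimal residual. Residuals are unweighted.

## Applicability limits

Fit quality is the normalised RMS error
NRMSE = √(n⁻¹Σ(yₑᵢ − yₘᵢ)²) / |n⁻¹Σyₑᵢ|, undefined when the observed mean
is zero (an error, not an NaN). What "approximates with a given accuracy"
means numerically is never quantified in the source material, and the
original limit-search implementation lived in an unavailable supplementary
notebook. The package's reconstruction, `max_valid_stretch()`, is an
**expanding-prefix refit**: every data point is a candidate endpoint;
prefixes are anchored at λ = 1 (whether non-prefix windows were ever
allowed is unknown; anchoring is assumed); the model is refit on each
prefix and the limit is the largest endpoint whose fit has
NRMSE ≤ threshold. The threshold (default **0.05**) and the prefix stride
(default 1 point) are exposed. If even the smallest admissible prefix
(n_coeffs + 2 points) exceeds the threshold, the result carries a
`failed` flag instead of pretending a limit exists.

Cohort summaries report, per group and model, the five numbers of a
box-style display: mean, 25%/75% quantiles with linear interpolation
(`stats::quantile` type 7), and Tukey fences Q1 − 1.5·IQR / Q3 + 1.5·IQR
clamped to the observed range (fences are named but not defined in the
source; Tukey's rule is the conventional reading).

The recommendation lookup `recommend_model()` uses regime boundaries
λₐ = 1.76 and λᵦ = 2.31; a stretch exactly on a boundary is assigned to
the smaller-deformation regime (the small-deformation regime is printed
as λ ≤ λₐ), and the healthy-artery status has no recommendation row, so
it errors rather than guessing.

## Preprocessing

* `to_curve()` drops rows with λ < 1 silently but counts them in an
  attribute: slack take-up at clamp engagement is physical, not signal.
  Duplicate λ values (the traverse can repeat positions) are collapsed by
  averaging σ — order-independent.
* `segment_stages()` splits on the machine's stage column when present;
  otherwise a new stage starts when the displacement returns below 2% of
  the running stage maximum (the clamps going back to the programmed
  origin). The 2% default is a robustness choice against machine noise;
  no value is stated in the source.
* `drop_preconditioning()` keeps the last cycle of each programmed
  elongation step, discarding up to `n_cycles` (default 2 — more are not
  needed in practice) earlier softened cycles and never discarding
  everything. The function accepts both raw stage segments (cycles split
  internally at displacement resets) and lists of per-cycle curves
  (grouped by equal target stretch): the pipeline's published description
  is ambiguous about whether preconditioning removal happens before or
  after stress–stretch conversion, and supporting both orders costs
  nothing.
* `truncate_at_plateau()` estimates the local slope dσ/dλ as the secant
  over a centered window of `window` points (default 5) and cuts the curve
  where the slope first falls below `slope_fraction` (default 0.1) of the
  maximum slope seen so far. The cut is placed at the *left edge* of the
  triggering window (index i − h): a centered estimator first registers
  the collapse about a half-width after the knee, and shifting by h
  removes that bias, placing the cut within one grid step of a hard knee.
  Both parameters are exposed; `slope_fraction = 0` disables truncation.

## Cohort statistics

With n = 5 ruptured vs n = 3 unruptured specimens, normal approximations
to the Mann-Whitney test are indefensible, so `mann_whitney_exact()`
enumerates. The production path is a subset-sum dynamic programme over the
doubled mid-ranks — exactly the complete enumeration of all C(n₁+n₂, n₁)
assignments, factored by rank sum — and the test suite checks it against a
literal `combn()` oracle. Ties get mid-ranks; the enumeration is over the
observed (tied) ranks, so no continuity correction is involved.

The **two-sided p-value is defined as P(|U − n₁n₂/2| ≥ |U_obs − n₁n₂/2|)**.
Conventions differ (doubling the smaller tail is common), and at these
sample sizes near-threshold conclusions depend on the convention, so it is
worth being explicit. Under this definition the smallest achievable
two-sided p at n = 5 vs 3 is 2/56 ≈ 0.036 — attained exactly at complete
separation (U = 0). A published significance of p ≤ 0.01 for ultimate
stress is therefore **not reconstructable** with an exact test at these
sizes; the package reproduces the direction (unruptured stronger) and
significance at 0.05, and treats the stricter level as irreproducible.

Ultimate values are extracted from *untruncated* curves: ultimate stress
is the maximum stress over the record (the maximum can be interior when
the specimen weakens before separating), ultimate strain is λ − 1 at the
last recorded point. The published per-specimen strain limits are stored
verbatim as dimensionless numbers: most exceed 1 and whether they are
engineering strain or stretch is not stated, so interpretation is left to
the caller.

## The synthetic generator: the stated world

No raw records are deposited, so the generator is the package's stand-in
for the experiment, and its defaults state the world the tests assume:

* **Elastic response** from any supported coefficient set on a uniform λ
  grid; beyond an optional knee λ_c the curve continues as a straight
  plateau segment, continuous at the knee, with configurable (default 0)
  slope. Rupture is modelled as termination of the record.
* **Noise**: additive Gaussian on stress, clipped at zero — the simplest
  defensible machine-noise model; no noise model is published.
* **Protocol**: `stages` programmed elongation steps with increasing
  targets; each step preceded by up to `preconditioning_cycles` repeats
  whose stress is inflated by a softening factor (default 20% on the
  first cycle, decaying geometrically by 0.5 per cycle, exactly 1 on the
  kept cycle); clamps return to the origin between cycles. The softening
  numbers are invented — the phenomenon (matrix relaxation) is described
  in the literature without magnitudes. The encoding to
  force/displacement is the exact inverse of `to_curve()`.
* **Cohorts**: per-specimen ultimate stresses are log-normal with the
  unruptured median `stress_ratio` times the ruptured one; ultimate
  strains share one log-normal across groups (the published cohorts
  differ in stress, not strain). Default `sdlog = 0.35`: a
  normal-extremes calculation done before any measurement showed that the
  documented power property (stress ratio 3, n = 5 vs 3, exact-test
  rejection > 80%) requires sdlog ≲ 0.38, whereas the raw published
  ruptured-cohort spread (~0.5–0.6 on the log scale) would undercut it;
  0.35 favours the stated property and is documented as slightly tighter
  than the published spread. Not revisited after measuring.

What the generator does **not** emulate: viscoelastic hysteresis within a
cycle (cycles are loading ramps only), anisotropy and fibre dispersion,
temperature/humidity effects, post-plateau rupture-front mechanics. A
green round-trip test therefore establishes that the pipeline inverts its
own stated world — not that the world is a faithful aneurysm.

One validation world is fixed a priori for the knee-localisation
acceptance check: Yeoh row Z response, λ ∈ [1, 2.2] on a 25-point grid
(spacing h = 0.05), hard plateau at λ_c = 1.8, noise 0.5% of the maximum
stress, threshold 0.05, 50 seeds, required accuracy ±2h. The grid is
deliberately coarse: the λ-distance at which the prefix NRMSE crosses a
threshold scales like (threshold · mean σ · √(span) / σ′(λ_c))^(2/3),
which for this response is ≈ 0.07–0.1 regardless of grid density — a
"within two grid steps" claim is only meaningful when 2h is at least that
large. A finer grid would not make the search worse in λ, only make the
same accuracy look worse in grid steps.

## Known limitations

* The MR stress forms do not nest Neo-Hookean (inherited verbatim, see
  above), and the stated linear-part expressions do not match a
  small-strain Taylor expansion of those forms; both are implemented as
  printed, without reconciliation.
* Published applicability limits (per-specimen maximum elongations)
  cannot be recomputed here — the raw curves they were derived from are
  not available — so they serve as fitting *windows* and lookup values,
  not as recomputed targets.
* The exact test is conservative at these sample sizes; its achievable
  p-values are a coarse lattice.
* No uncertainty quantification of coefficients, no weighted or robust
  regression, no multiple-testing correction (two unadjusted tests), and
  no anisotropic (fibre-reinforced) energies — all out of scope.
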