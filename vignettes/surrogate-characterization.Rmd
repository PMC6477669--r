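---
title: "Characterizing heel-pad surrogates: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing heel-pad surrogates: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padmech)
```

`padmech` characterizes cylindrical elastomeric surrogates of the calcaneal
fat pad from uniaxial compression tests. This vignette is the package's own
account of the science it implements: the constitutive model and its
assumptions, the conventions and tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken where
the design was genuinely open.

## Coordinates, units and sign convention

All quantities live in a fixed unit system: mm, N, s, MPa. This is not
cosmetic — with forces in N and areas in mm², stress in N/mm² *is* MPa, so
the identified coefficients carry no hidden conversion factors.

A test machine reports compression-positive displacement `d` and resisting
force `F`. `to_stress_stretch()` maps these to *engineering* (undeformed
reference) material coordinates:

- strain `ε = −d/h0`, stretch `λ = 1 + ε`, stress `σ = −F/A0`,

with `h0` the undeformed height and `A0 = πd²/4` the undeformed
cross-section. Internally the package is signed and tension-positive:
compression means `λ < 1` and `σ < 0`. This makes the constitutive stress
equation hold with its natural signs and keeps the fitter free of ad-hoc
absolute values; `magnitude_view()` provides the familiar
positive-magnitude curves for reporting. True-stress (deformed-area)
correction, barreling and friction effects are deliberately out of scope:
the characterization is engineering-stress throughout, and the identified
coefficients must be interpreted in that frame.

`to_stress_stretch()` is exactly invertible given the geometry
(`to_machine_coordinates()`), which the tests exploit as a round-trip
invariant.

## The Yeoh model

The surrogates are nearly incompressible elastomers with a markedly
nonlinear compressive response, which suits a reduced-polynomial
hyperelastic description. The Yeoh strain energy is a cubic in the first
Cauchy–Green invariant:

ψ = c1 (I1 − 3) + c2 (I1 − 3)² + c3 (I1 − 3)³,

and under incompressible uniaxial deformation (λ, λ^(−1/2), λ^(−1/2)), so
that I3 = 1 and I1 = λ² + 2/λ, the stress–stretch relation in closed form is

σ(λ) = 2 (λ² − 1/λ) (c1 + 2 c2 (I1 − 3) + 3 c3 (I1 − 3)²).

Three points about this pair deserve explicitness:

- **I1-only form.** Source material for this family of models sometimes
  prints the quadratic and cubic terms against (I2 − 3) and (I3 − 3); that
  cannot be the model actually fitted, because the companion stress equation
  above depends on I1 alone (and any I3 term is vacuous under
  incompressibility). The package implements the standard I1-only Yeoh
  form, which reproduces the stress equation exactly by differentiation.
- **Which stress the closed form is.** The printed relation is the
  Cauchy-stress identity σ = λ·dψ/dλ of the incompressible uniaxial state,
  and the test suite asserts exactly that consistency (central differences,
  h = 1e−6, to 1e−6 relative over λ ∈ [0.5, 1.5] for every packaged
  parameter row). In practice the relation is applied to engineering
  stress–stretch data, as is common in this characterization workflow; since
  the same forward model generates and refits the synthetic data, the
  identified coefficients are self-consistent under either reading, but
  users transplanting coefficients into FE solvers should check which
  stress measure their solver's uniaxial test data option expects.
- **I2 convention.** `cg_invariants()` follows the ordered-pair definition
  I2 = Σ_{i≠j} λi²λj² (six terms, so the reference state gives I2 = 6, not
  the classical 3). I2 is exposed for completeness only; nothing downstream
  consumes it.

The neo-Hookean model is the exact degenerate case c2 = c3 = 0. Other
hyperelastic families (Mooney–Rivlin, Ogden) and any rate-dependent
(viscoelastic) law are out of scope: rate dependence is represented by
identifying a *separate* coefficient set per displacement rate, which is
why the packaged parameter table is rate-stratified.

## Parameter identification

`fit_yeoh()` minimizes the sum of squared stress residuals over (c1, c2,
c3). Numerical choices:

- **Optimizer.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
  analytic Jacobian. The uniaxial Yeoh stress is *linear* in the
  coefficients, so the Jacobian is constant and the optimizer converges
  essentially in one step from any start; the machinery still matters for
  the bounded variant, and the implementation is deliberately the general
  NLS path so the model form can evolve without touching the fitter.
- **Multi-start.** The originating workflow (spreadsheet solver from
  "arbitrary" initial coefficients) specifies no initialization, so the
  fitter restarts from a neutral family: an origin-adjacent point plus
  log-spaced magnitudes 1e−4…1 MPa (5 starts by default, plus any
  user-supplied start). Best SSR wins; exact ties break toward the smallest
  ‖c‖₂.
- **Constraints.** Unconstrained by default, matching the identification
  procedure being emulated; `nonneg = TRUE` (or explicit box bounds)
  restricts the coefficients when a user needs guaranteed monotone,
  energy-stable parameters.
- **Tolerances.** Relative SSR change 1e−12, gradient norm 1e−10, at most
  10,000 residual evaluations per start. Fits report `converged` honestly
  rather than failing.
- **Degenerate inputs.** Fewer than 4 points, or fewer than 4 distinct
  stretches, are errors — three coefficients against three or fewer
  effective abscissae would be an interpolation, not an identification.

R² between observed and predicted stresses is 1 − SS_res/SS_tot with
SS_tot about the observed mean; constant observed series are an error
(undefined variance), and negative values are possible and meaningful.
`classify_fit()` applies the conventional strict R² > 0.95 accuracy flag;
the threshold is configurable.

The test suite pins the fitter to a brute-force 21³ lattice oracle (±50%
around the generating coefficients): the fitter's SSR must never exceed
the lattice minimum on noise-free plants.

## Cyclic analysis: segmentation, EDR, repeatability

`segment_cycles()` cuts a record at displacement peaks. Peaks are plateau
runs of equal displacement that are strict local maxima with a minimum
prominence of 1% of the maximum displacement — the prominence floor exists
purely so encoder jitter cannot spawn spurious cycles; no segmentation rule
is inherited from the emulated protocol, so this one is the package's own.
Loading runs from the preceding trough to the peak, unloading from the peak
to the following trough; a monotone ramp yields a single flagged
loading-only loop.

The energy dissipation ratio of a loop is

EDR = (A_load − A_unload) / A_load,

with both areas computed by trapezoidal integration of force over
displacement (N·mm), matching force–displacement hysteresis reporting.
Whether the ratio is computed in force–displacement or stress–strain space
is immaterial: both unit maps are linear, so the ratio is identical — the
package chooses machine coordinates. EDR values outside [0, 1] by more than
1e−9 are errors; within that band they are clipped (integration noise on
nearly coincident branches).

Repeatability of a cyclic test is judged on peak forces. The criterion
"maximum variation within ±10% of the maximum load" is implemented as the
peak-to-peak spread: (max − min) ≤ tolerance × max peak. Because
"variation" could also be read as deviation about the mean, the result
object reports per-cycle deviations from the mean peak under both
normalizations (by the maximum and by the mean peak) alongside the binary
verdict, so either convention can be audited. Initial idle conditioning
cycles can be excluded with `skip_cycles` (default 0 — synthetic records
have no conditioning transient).

## Surrogate selection

Candidates and references are force–strain curves (compressive strain
magnitude, N). `correlate_curves()` resamples both onto an evenly spaced
grid over the *shared* strain span — [max of the minima, min of the maxima],
21 points by default — by linear interpolation (never extrapolation), then
computes R² with the reference playing the observed series. The
reference-as-observed choice is a documented convention; with the roles
swapped only SS_tot changes, and the self-correlation and admission
properties tested are unaffected. `select_surrogates()` admits candidates
with R² ≥ 0.8 (inclusive, configurable), names the per-group argmax, and
breaks exact ties lexicographically with an explicit tie flag so selection
is invariant to input order.

Reference tissue curves are *inputs*: the in vivo literature curves that
motivated this workflow exist only as published figures and are not
packaged or digitized. The synthetic cohort supplies references for
testing; consequently the package's tests demonstrate the selection
*machinery*, not agreement with any particular tissue dataset.

## The synthetic-data generator

The generator exists so that every analysis stage is exercised end-to-end
with data whose ground truth is known exactly.

- `generate_compression_record()`: displacement ramps linearly at the
  nominal rate to the peak (default 9 mm on the 40 mm × 18 mm cylinder —
  half the specimen height, i.e. λ down to 0.5); force is the forward-model
  resisting force |σ(λ)|·A0 plus optional Gaussian load-cell noise
  parameterized as a fraction of the noise-free peak force, clipped at
  zero. Noise is applied to force only — the displacement encoder is
  treated as exact. An optional 40 N load cap truncates the record the way
  a machine's load limit would.
- `generate_hysteresis_record()`: triangular displacement cycles; the
  unloading force equals (1 − q) times the loading force at the same
  displacement, so each cycle's EDR is *exactly* the prescribed q under the
  trapezoid rule. The sampled record duplicates the apex sample (loading
  force, then scaled unloading force at the same displacement) so the
  pointwise-scaled construction survives discretization; the segmenter's
  plateau-aware peak detection handles this. The default q in the
  demonstration pipeline is 0.22, the control surrogate's mean dissipation
  level; 0.25 corresponds to the in vivo heel pad at 0.8 mm/s.
- `generate_cohort()`: per-specimen variability as independent lognormal
  multipliers (meanlog 0, sdlog chosen by the user; the demonstration
  pipeline uses 0.05, a realistic single-digit-percent batch variation for
  cast elastomer specimens) on each coefficient, keeping positive
  coefficients positive.

Determinism: every generator takes a seed and restores the caller's RNG
state; the pipeline derives per-stage seeds from one root seed with fixed
offsets, so a config file fully reproduces a run (bundles embed a config
hash).

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: machine compliance and contact
mechanics at the piston interface, the macro/microchamber architecture and
its anisotropy, genuine viscoelastic rate dependence (rate enters only
through per-rate coefficient sets), permanent set and Mullins-type
softening between cycles, and displacement-channel noise. A real cyclic
record's EDR is an empirical outcome; the synthetic one's EDR is
prescribed, which is precisely what makes it a round-trip test of the
analyzer rather than a material prediction.

## Problem sizes and defaults

The packaged defaults mirror the emulated protocol: 40 mm × 18 mm
cylinders, 9 mm peak displacement, 40 N load cap, rates 0.8/1.96/180/1800
mm/s as metadata, five cycles, thresholds 0.95 (fit accuracy), 0.8
(selection), 21-point correlation grid, ±10% repeatability band. Parameter
recovery checks use 50-point noise-free curves on λ ∈ [0.55, 1]; stochastic
recovery checks use 200-point curves at 1% force noise over 100 seeds,
where the mean relative error of c2 stays inside a 5% envelope (per-seed
errors can reach roughly twice that — an identifiability property of the
small-c1 control coefficients under this noise level, established by
Monte-Carlo with a closed-form linear least-squares oracle). Property
suites over random loops run at deliberately coarse sampling (a few Hz) —
the EDR construction is sampling-exact, so dense grids would add cost, not
information.

## Known limitations

- Engineering stress/strain only; no true-stress or friction correction.
- One specimen geometry (right cylinder) and uniaxial compression only; no
  shear, bending, torsion or fatigue loading.
- The Yeoh fit is unweighted; heteroscedastic load-cell noise would call
  for weighted least squares, which is intentionally not implemented.
- Uncertainty on identified coefficients is not quantified beyond the
  Monte-Carlo seed sweeps in the tests.
- Selection quality is bounded by the reference curves supplied; the
  package ships none.
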