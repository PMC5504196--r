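---
title: "Trimodal race-model bounds: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimodal race-model bounds: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trirace)
```

## The models

**Channel latencies.** Each modality x ∈ {A, V, S} is a Poisson counter:
detection occurs at the c-th event of a Poisson process with intensity
λ_x, so the detection time is Erlang, `D_x ~ Gamma(c, λ_x)`, with integer
shape c shared across modalities (only the rates differ between channels).
Times are in milliseconds and rates in events per millisecond throughout;
with λ on the order of 0.01/ms and c = 2, mean unimodal latencies are
around 200 ms, the scale of simple detection RTs. Residual components such
as motor time are deliberately not modelled: the simulated RT *is* the
detection time. Non-integer gamma shapes and ex-Gaussian-style extensions
are out of scope.

**Race architecture.** The redundant-condition latency is the per-trial
minimum of the member channels, `D_AVS = min(D_A, D_V, D_S)`. Crucially,
`simulate_race()` derives *all seven* condition samples from the same joint
draws: unimodal conditions are the marginal columns, redundant conditions
the row-wise minima. This realizes complete context invariance — the
requirement that unimodal and bimodal condition distributions equal the
corresponding marginals of the trivariate joint — *by construction*, which
makes the race output a true-positive control: every bound must hold on it
up to sampling error, and `check_context_invariance()` must report zero
sup-distance on shared trials.

**Superposition architecture.** The coactivation alternative pools the
member Poisson processes into one counter, so the redundant latency is
again Erlang with the summed rate: `D_AVS ~ Gamma(c, λ_A + λ_V + λ_S)`.
At c = 1 the two architectures coincide exactly (the minimum of independent
exponentials is exponential with the summed rate); for c ≥ 2 superposition
is strictly faster than any race, which is what generates bound violations.

## The bound family

On a common time grid the package computes, whenever the needed conditions
are present: the three bimodal bounds `F_xy ≤ F_x + F_y`; the Boole bound
`F_AVS ≤ F_A + F_V + F_S`; the three Bonferroni-type bounds
`F_AVS ≤ F_xy + F_xz − F_x`; their pointwise minimum (the sharp bound); and
the three restricted bounds `F_AVS ≤ F_xy + F_z` for designs where a
bimodal condition stands in for a combined channel and context invariance
is assumed only for that bivariate pairing. Algebraically, wherever the
empirical bimodal bounds hold, each Bonferroni curve lies below the Boole
curve and the sharp curve below all three; the test suite asserts this
pointwise, and verifies every bound by brute-force enumeration on a small
discrete joint distribution where all probabilities are exact.

## Numerical conventions

- **ECDFs are right-continuous** (`P(RT ≤ t)`), matching the probability
  statements the bounds are made of.
- **Grids** default to the union of all observed values plus 0. ECDFs and
  bounds built from them are step functions that change only there, so no
  information is lost and no interpolation artifacts are introduced.
- **Clipping.** All bounds are clipped to [0, 1]; Bonferroni raw values are
  additionally floored at 0 (a negative bound is vacuous). Whether plotted
  reference curves elsewhere are clipped before display is a presentation
  choice; here clipping is always applied, which also caps how far into the
  upper percentiles a violation can extend.
- **Violation tolerance.** `assess_violation()` flags a bound when the
  target CDF exceeds it by more than `tolerance`, with a 1e-12 guard so
  exact floating-point ties never count. `rmi_report()` defaults the
  tolerance per bound to the sum of one-sample
  Dvoretzky–Kiefer–Wolfowitz band half-widths (level α = 0.05) over the
  target and all input conditions — conservative by the triangle
  inequality, so false violations on race data are rare. Set
  `tolerance = 0` to read raw curve exceedance as one would off a figure;
  the reported violation *percentiles* are percentiles of the
  redundant-condition distribution itself (the y-axis value where its CDF
  crosses the bound), a convention that is configurable in the sense that
  `tidy()` also reports the violated time range.
- **Context-invariance tolerance.** The diagnostic compares two ECDFs, so
  the default is the two-sample DKW-style band
  `sqrt(log(2/α)/2)·sqrt(1/n₁ + 1/n₂)` at α = 0.01 rather than a
  one-sample band at the larger n: the one-sample band under-covers
  two-ECDF comparisons (roughly a 14% false-flag rate at n = 2000 versus
  about 1% for the two-sample form). This is a diagnostic, not a
  significance test.
- **Ties in the sharp bound** need no tie-breaking (a pointwise minimum),
  but the `argmin` column names all curves attaining the minimum at each
  grid point for diagnostics.
- **Degenerate inputs.** Empty samples, negative latencies, unsorted grids,
  unknown condition labels, and correlation triples outside the admissible
  set are errors with messages naming the violated constraint; a missing
  condition makes the affected bounds "skipped" (with the reason) and the
  affected invariance identities "not checkable", never silent failures.

## Dependence between channels

Negative dependence between channel latencies speeds up minima — slow trials
in one channel tend to be rescued by fast trials in another — so correlation
is a lever on the attainable RSE under a race. Two structural facts shape
the implementation:

1. **Admissibility.** The three pairwise correlations must form a positive
   semidefinite matrix; given two of them the third is confined to the
   Stanley–Wang interval `r_xy·r_xz ± sqrt((1−r_xy²)(1−r_xz²))`. The
   equicorrelated triple (−0.5, −0.5, −0.5) sits exactly on the boundary
   (smallest eigenvalue 0) and is admitted via a −1e-10 eigenvalue
   tolerance; (−1, −1, −1) is not constructible. `is_admissible()` uses the
   closed-form trigonometric eigenvalues of a symmetric 3×3 matrix
   (vectorized, so a 101³ grid runs in about a second); `base::eigen` is
   the independent oracle in the unit tests, agreeing to ~1e-14.

2. **Copula choice and calibration.** A multivariate distribution with
   Erlang margins and specified Pearson correlations is not unique; the
   package uses a Gaussian copula (trivariate standard normals mapped
   through Φ and the Erlang quantile function), which gives exact margins
   and supports a wide negative-dependence range. The Pearson correlation
   of the gamma margins is an attenuated, strictly increasing function of
   the latent normal correlation depending only on the (shared) shape, so
   it is computed once per shape by two-dimensional Gauss–Hermite
   quadrature (48 nodes) and inverted by monotone interpolation — a
   deterministic calibration accurate to well under the ±0.02 target, in
   place of a simulation-based lookup. Requested and achieved correlations
   are both attached to the simulator output.

   Two hard limits follow. The countermonotone floor for shape-2 margins is
   ≈ −0.80, and — more binding — the *latent* equicorrelated matrix must
   itself be PSD (ρ ≥ −0.5), which maps to achieved Pearson correlations of
   ≈ −0.42. The popular equicorrelated target of −0.5 is therefore not
   exactly attainable with this copula: `simulate_race()` clamps the latent
   matrix to the admissible set, warns, and reports the achieved values.
   The negative-dependence test asserts the directional claim (the
   trimodal minimum is faster than under independence by more than the
   Monte-Carlo error) at that strongest attainable dependence, not any
   specific optimum; which admissible triple maximizes the trimodal RSE is
   left open.

## Seeding

One master seed lives in `trimodal_config()`; per-architecture and
per-condition substreams are derived from it by a fixed integer hash of the
stream label. Mixed compositions (race sub-conditions plus a superposition
trimodal condition) are therefore reproducible stream by stream, and CLI
runs with the same seed are byte-identical.

## What the generator does and does not emulate

The fixture scenarios (`race_independent`, `race_negative`,
`superposition_avs`, `mixed_fig1`, `mixed_fig2`) reproduce idealized
detection-time compositions at the reference setting c = 2,
λ_A = λ_V = λ_S = 0.01/ms, n = 2000 trials per condition — sample sizes and
parameters chosen so a full report runs in well under a second. They do
*not* emulate: motor/residual RT components, anticipations or outliers,
fatigue or sequential effects, inter-subject variability, or non-Poisson
channel dynamics. Consequently, passing tests show the bound machinery and
the simulators are correct and internally consistent — they do not certify
that empirical RT data satisfy the race model's assumptions, and the
package deliberately provides no significance test of violations
(permutation/bootstrap procedures for the trimodal case are future work).

## Problem sizes used in the checks

The shipped tests run the reference setting at n = 2000 (20 seeds for the
violation-percentile summary, 100 seeds for the false-violation-rate
control), n = 10000 for dependence and DKW-convergence checks, a 101³ grid
for the admissibility/PSD equivalence, and exact enumeration on a 4-point
discrete joint for the brute-force bound verification. The whole suite
completes in about a minute on one CPU.
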