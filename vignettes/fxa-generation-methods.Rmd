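---
title: "Methods: factor Xa generation from plasma composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factor Xa generation from plasma composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xagen)
```

This vignette is the package's account of its science: the kinetic model
and its assumptions, the conventions behind every reported number, the
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not establish.

## The kinetic model

The core is the Hockin et al. (2002) mass-action description of
tissue-factor-initiated coagulation: 34 species and 43 reaction arrows
covering TF:VIIa formation and its action on fX and fIX, feedback
activation of fVII by TF:VIIa, fXa and thrombin, thrombin activation of
the cofactors fV and fVIII, the intrinsic tenase (fIXa:fVIIIa) and
prothrombinase (fXa:fVa) complexes with explicit Michaelis intermediates,
meizothrombin as the prothrombinase intermediate, fVIIIa A2-domain
dissociation (the two fragments are tracked as separately conserved
moieties), TFPI inhibition of fXa and of TF:VIIa:Xa, and irreversible
antithrombin inhibition of thrombin, meizothrombin, fXa, fIXa and
TF:VIIa. The protein C pathway, platelets, the contact pathway and the
vasculature are outside the model: simulated curves describe the plasma
procoagulant/anticoagulant protein ensemble only.

Rate constants live in `inst/extdata/rate_constants.yaml`, transcribed
from the source model's table rather than hard-coded, so the transcription
is auditable and individually overridable; the loader enforces
completeness and positivity. The TF:VIIa + AT arrow is part of the source
model and is kept by default; `sim_config(include_tf_viia_at = FALSE)`
removes it for users who prefer the narrower antithrombin target set.

Percent factor levels become molar initial conditions through the mean
concentration table (`inst/extdata/mean_concentrations.yaml`): fII 1.4 µM
and fX 170 nM as printed with the model description, the other six from
the source model family's literature convention (fV 20 nM, fVII 10 nM,
fVIII 0.7 nM, fIX 90 nM, TFPI 2.5 nM, AT 3.4 µM), all overridable. The
fVII percentage scales fVIIa too: `[VIIa](0)` is 1% of the individual's
molar fVII. Tissue factor triggers at 5 pM by default.

## Numerics

Integration is stiff adaptive lsoda with a compiled mass-action
right-hand side, `rtol = 1e-8`, `atol = 1e-14` M, sampled on the closed
1 s grid `t = 0, 1, ..., 3600` (3601 points). Tolerance-level negative
concentrations are clamped to zero in the reported trajectory only, never
fed back into the integrator. Identical inputs give bit-identical
trajectories.

Correctness rests on two independent checks rather than one: the
right-hand side is verified against a naive per-reaction flux enumeration
written directly from the reaction strings, and the adaptive solution is
verified against a fixed-step classical RK4 integration at `dt = 1 ms`
(0.5% relative agreement on fXa at 600, 1800 and 3600 s, for the nominal
composition and for compositions drawn across the published control
ranges). Every trajectory is additionally required to conserve all nine
protein moieties to within ten times the solver tolerance at every grid
point.

## Generation parameters

`MaxL` is the series maximum; `MaxR` is the maximum of the 1 s forward
difference, assigned to the later grid point, so both are reproducible
from the trajectory file alone without solver internals. Times of
attainment take the earliest index, with ties called at one part in 1e9 so
floating-point noise on flat stretches cannot push them later. `AUC` is
the rectangle sum `Σ level · Δt` — a deliberate convention (summing the
concentration at each time point) rather than a trapezoid, matching how
the study totals fXa exposure. Reporting units are fixed: fXa in nM,
pM/s and µM·s; thrombin in nM, nM/s and µM·s.

"Total active fXa" counts free fXa plus prothrombinase-resident fXa; the
substrate-bound ternary complex Xa:Va:II is included by default
(`include_xa_va_ii`), since that fXa is catalytically engaged rather than
inhibited. Meizothrombin enters "total thrombin" with weight 1.2 by
default (the source model's activity convention), switchable to 1.0.

## Risk statistics

The 90th-percentile cutoff is computed once on the pooled cases+controls
distribution — nearest rank, `sorted[ceiling(0.9 n)]`, with "above"
meaning strictly greater — and then applied within subgroups; for
`n = 899` this puts exactly 89 subjects above. Odds ratios use the Woolf
log-normal CI, which reproduces every published interval we checked at
1-decimal rounding (e.g. 2.1 with CI 1.3–3.2 from the whole-population
counts, and 15.7 with CI 1.8–135 in the small OC-negative stratum); a
zero cell makes the OR undefined (`NA`), a value rather than an error.
Fisher's exact p is the standard two-sided hypergeometric sum. Group
comparisons gate on a Kolmogorov–Smirnov normality check (against a
normal with the sample moments, α = 0.05) before choosing the t-test or
the rank-sum test; trend slopes are OLS with a normal-approximation 95%
CI. Subjects missing a stratification field are excluded from that
stratification only.

## Normalization search

The discrepancy between two curves is the worst relative difference of
the three magnitude parameters, `max |Δ{MaxL, MaxR, AUC}| / reference`;
a curve is "normalized" at discrepancy ≤ θ, default θ = 0.05. The search
is exhaustive over all 2^8 = 256 factor subsets by increasing
cardinality (each subset costs one ODE solve, so the whole search runs in
seconds), returning the smallest passing subset with ties broken by
smallest discrepancy — no greedy heuristic, so the reported subset is
provably minimal for the given θ, and the full trace is returned as the
witness. θ is a convention standing in for the study's visual criterion
of curve overlap; at θ = 0.05 the search run by the acceptance suite
returns {fIX, TFPI} for the fXa analyte and {fII, fIX, AT, TFPI} for
thrombin on the published oral-contraceptive mean compositions, and
{fIX, TFPI} is the best of all 28 two-factor subsets for fXa.

## Synthetic cohorts

The generator emulates the published case-control factor distributions:
per group and factor a normal draw with the printed mean and SD,
truncated by rejection at the printed observed range (so no
non-physiological levels), independent across factors by default. Group
sizes default to 473 controls and 426 cases. Demographics (sex, age, BMI,
OC use among premenopausal women) follow marginals chosen to match the
published subgroup counts; subgroup simulations (e.g. OC users) reuse the
whole-group SDs with the subgroup means, since subgroup SDs are not
published. A Gaussian-copula correlation hook exists because real factor
levels correlate, but no published correlation matrix is available, so
the default is independence — consequently synthetic odds ratios share
the direction, not the magnitude, of the published ones, and the test
suite asserts direction and calibration properties (pooled above-cutoff
count, null-cohort CI coverage) rather than published effect sizes.
Truncation at an asymmetric window biases a marginal mean slightly away
from the nominal value; tests compare sampled moments against the
analytic truncated-normal mean. Sampling is Mersenne-Twister under a
single recorded seed; the seed and generator are written into the cohort
attributes and the run manifest.

## Problem sizes

The test suite simulates: the reference compositions (one ODE solve
each), six full-horizon RK4 verifications at 1 ms steps, two exhaustive
normalization searches (2 × 257 solves), one 899-subject cohort and
twenty 899-subject null cohorts — all chosen as the smallest sizes at
which the corresponding claims are meaningful (the null-coverage check,
for instance, needs replicate cohorts at the study's own size for its
CI-coverage statement to refer to the study design).

## Known limitations

* Times-to-maximum at mean-like compositions run a few hundred seconds
  later than the published population means, while the magnitude
  parameters and every directional contrast land inside the published
  ranges; the likely cause is a small difference in the exact upstream
  model variant or mean-concentration table, which are not fully printed.
  Analyses here are therefore directional and property-based on timing
  quantities.
* Absolute synthetic cohort statistics depend on the unpublished
  inter-factor correlation structure (see above).
* The model omits the protein C pathway, platelets, contact activation
  and flow; simulated "risk" is a statement about plasma composition
  only.
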