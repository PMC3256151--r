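# xagen

Plasma-composition-based simulation of factor Xa generation, with the
case-control risk analysis built on top of it.

## The problem

Thrombin generation profiles computed from an individual's measured plasma
factor levels are an established phenotypic readout of procoagulant
potential, but many healthy individuals have nearly indistinguishable
thrombin curves. Factor Xa — the protease of prothrombinase, formed through
both the extrinsic tenase (TF:VIIa) and the intrinsic tenase (fVIIIa:fIXa)
— varies over a wider range across a population and can discriminate
between individuals whose thrombin profiles overlap. `xagen` turns eight
routinely measured plasma levels (fII, fV, fVII, fVIII, fIX, fX,
antithrombin, TFPI; percent of the population mean) into a deterministic
factor Xa (or thrombin) generation time course, reduces it to five
generation parameters, and provides the epidemiological machinery used to
relate those parameters to deep-vein-thrombosis case-control status.

It is written for coagulation researchers running in-silico population
studies: each subject is one stiff ODE solve (~30 ms), so cohorts of
hundreds run in seconds.

## The model

The kinetics are the Hockin et al. (2002) mass-action model of the tissue
factor pathway: 34 species, 43 reaction arrows, including TFPI inhibition
of fXa and of TF:VIIa:Xa, antithrombin inhibition of thrombin, fXa, fIXa
and TF:VIIa, and fVIIIa A2-domain dissociation. For each subject the
zymogen and inhibitor initial conditions are

    [X_i](0) = (level_i / 100) * mean_i,   [VIIa](0) = 0.01 * [VII](0),

with mean concentrations `fII = 1.4 µM`, `fX = 170 nM` (and literature
values for the rest), triggered by `[TF](0) = 5 pM`, integrated over
3600 s (lsoda, rtol 1e-8, atol 1e-14 M) on a 1 s output grid. Total active
fXa is `[Xa] + [Xa:Va] + [Xa:Va:II]`; total thrombin is
`[IIa] + 1.2 [mIIa]`. A curve is summarized by

* `MaxL`, `TMaxL` — maximum level and earliest time attaining it;
* `MaxR`, `TMaxR` — maximum 1 s forward-difference rate and its time;
* `AUC` — the rectangle sum `Σ level · Δt`.

Downstream: pooled nearest-rank 90th-percentile cutoffs, 2×2 case-control
tables with Woolf odds-ratio CIs and Fisher's exact tests, subgroup
stratification, OLS trend slopes, an exhaustive minimal-factor-subset
normalization search between two group mean compositions, and a
truncated-normal synthetic cohort generator matching published
case-control factor distributions (473 controls / 426 cases).

## Worked example

```r
library(xagen)
fx <- fixture_compositions()        # published reference compositions
m_users    <- trajectory_metrics(simulate_subject(fx$oc_users), "fXa")
m_nonusers <- trajectory_metrics(simulate_subject(fx$oc_nonusers), "fXa")
rbind(users = m_users, nonusers = m_nonusers)
#>          analyte  MaxR TMaxR  MaxL TMaxL   AUC
#> users        fXa 13.24   759 10.70  2140 28.07
#> nonusers     fXa  8.60   822  6.85  2209 17.62
```

Simulating the printed mean compositions of oral-contraceptive users
versus non-users: users generate fXa at a 54% higher maximum rate
(13.2 vs 8.6 pM/s), reach a 56% higher maximum level (10.7 vs 6.9 nM),
produce 59% more total fXa (28.1 vs 17.6 µM·s) and peak 63 s earlier —
the largest subgroup contrast in the study population. The exhaustive
normalization search explains it:

```r
res <- normalization_search(fx$oc_users, fx$oc_nonusers, analyte = "fXa")
res$subset
#> [1] "fIX"  "TFPI"
res$discrepancy
#> [1] 0.03656772
```

Adjusting only fIX and TFPI to the non-user means brings the user curve
within 4% of the non-user curve — elevated fIX and depressed TFPI drive
the oral-contraceptive fXa phenotype, whereas normalizing the thrombin
curve needs four factors (`fII, fIX, AT, TFPI`).

The numbered scripts under `analysis/` run the full workflow (reference
profiles, synthetic cohort, risk tables, normalization) and write their
tables under `results/`.

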