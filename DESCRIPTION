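Package: xagen
Title: Plasma-Composition-Based Simulation of Factor Xa Generation and
    Thrombotic Risk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic kinetic modeling of the tissue factor pathway of
    blood coagulation from an individual's measured plasma factor levels
    (fII, fV, fVII, fVIII, fIX, fX, antithrombin and tissue factor pathway
    inhibitor, as percent of the population mean). Integrates the Hockin et
    al. (2002) <doi:10.1074/jbc.M201173200> mass-action reaction network to
    obtain factor Xa and thrombin generation time courses, reduces them to
    generation parameters (maximum rate and level, their times, area under
    the curve), and provides the downstream epidemiological toolkit: pooled
    90th-percentile cutoffs, case-control contingency tables with Woolf
    odds-ratio confidence intervals and Fisher's exact tests, subgroup
    comparisons, covariate trend slopes, a minimal-factor-subset
    normalization search between group mean compositions, and a
    truncated-normal synthetic cohort generator emulating published
    case-control factor-level distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
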