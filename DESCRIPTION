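Package: nfltraj
Title: Comparative CSF and Plasma Neurofilament Light Chain Trajectory
    Analysis for Autosomal Dominant Alzheimer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for staging, quality control and longitudinal modelling of
    neurofilament light chain (NfL) measured in cerebrospinal fluid and plasma
    in autosomal dominant Alzheimer's disease family cohorts. Implements
    estimated-years-to-onset (EYO) staging from mutation-specific onset ages,
    duplicate-assay coefficient-of-variation QC, Bayesian linear mixed models
    with restricted cubic splines of EYO and carrier-status interactions
    (Gibbs sampler authored in the package), divergence-point detection from
    posterior difference distributions, empirical-Bayes extraction of
    within-person annualized rates of change, AIC-based covariate selection,
    plasma/CSF ratio analysis, segmented (breakpoint) regression for
    bifurcation-point estimation, and mixed-model coupling of NfL change to
    imaging change. A truth-parameterized synthetic cohort generator emulates
    the data structure of such studies so the whole pipeline is testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lme4,
    lmerTest,
    emmeans,
    mgcv,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite
Config/testthat/edition: 3
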