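Package: aripopk
Title: Population Pharmacokinetics of Aripiprazole and Dehydroaripiprazole
    in Children with Tic Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint parent-metabolite population-pharmacokinetic modelling of
    oral aripiprazole (ARI) and its active metabolite dehydroaripiprazole
    (DARI) in pediatric patients with tic disorders. Provides a closed-form
    depot/parent/metabolite structural model with allometric body-weight and
    CYP2D6-phenotype covariate effects, FOCE-ELS estimation with stepwise
    covariate selection and nonparametric bootstrap, goodness-of-fit, visual
    predictive check and NPDE diagnostics, Monte-Carlo simulation of
    steady-state exposure with probability-of-target-attainment dose
    optimization, CYP2D6 diplotype phenotyping, metabolic-ratio phenotype
    discrimination, and YGTSS-based exposure-response ROC analysis. A
    synthetic-cohort generator emulating the sparse-sampling study design is
    included for simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
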