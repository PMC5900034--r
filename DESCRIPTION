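Package: nmrage
Title: NMR Metabonomics of Metabolic Ageing: Simulation, Preprocessing and
    Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for 1D 1H NMR metabolite profiling of
    urine and plasma, aimed at biomarker discovery in ageing cohorts of
    wild-type and FMO5-knockout mice. Provides a seeded synthetic-cohort
    generator (Lorentzian multiplets, dilution, chemical-shift jitter,
    multiplicative noise, planted group effects, protein-binding line
    broadening), spectral preprocessing (ppm calibration, region exclusion,
    probabilistic quotient normalization, log transformation), recursive
    segment-wise peak alignment with a custom-interval second pass,
    multivariate pattern recognition (PCA with bi-cross-validated rank
    selection, maximum margin criterion discriminant analysis, leave-mouse-out
    quadratic-classifier cross-validation), FDR-controlled univariate ANOVA
    biomarker tables, line-width analysis of protein-bound metabolites, and
    metabolite identification carbon efficiency (MICE) scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
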