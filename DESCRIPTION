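Package: xdprogress
Title: Quantitative Natural-History Modelling of X-Linked Dystonia-Parkinsonism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative natural-history analysis of X-linked
    dystonia-parkinsonism (XDP) rating-scale and oromotor data: a catalogue of
    107 clinical measures with their value kinds (ordinal, positive real,
    count), a longitudinal cohort data model with delimited-text input/output,
    a synthetic cohort simulator with ground-truth latents, first-versus-last
    change testing (Wilcoxon signed-rank with last-observation-carried-forward
    and next-observation-carried-backward imputation, Benjamini-Hochberg false
    discovery rate control), Bayesian estimation of the measure correlation
    matrix under missingness, principal-variables selection of a minimal
    measure battery, a hierarchical Bayesian symptom-trajectory model with
    latent per-subject age at onset and rate of progression fitted by Markov
    chain Monte Carlo, and a per-category rate-heterogeneity analysis with
    hierarchical clustering of progression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    withr,
    generics,
    ggplot2,
    MASS,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
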