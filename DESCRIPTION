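Package: nsclineage
Title: Lineage Analysis of Adult Neural Stem Cells from Long-Term Intravital Imaging Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the quantitative analysis of adult pallial neural stem
    cell (NSC) lineages reconstructed from long-term intravital imaging of the
    zebrafish telencephalon. Provides a validated long-format track data model
    (apical area, deltaA reporter scores, proliferation-marker flags, division
    and delamination events), annotation of division events from quiescence and
    of division modes based on deltaA expression in daughter pairs, descriptive
    lineage statistics (apical-area conservation at division, slow quiescent
    growth, per-cell-per-day division likelihoods with exact Poisson
    intervals), interval-censored exponential estimation of the
    activation-onset-to-cytokinesis rate with profile-likelihood confidence
    intervals, logistic and multinomial regressions of division propensity and
    division fate with fish fixed effects and type II Wald tests, and a
    stochastic simulator of the underlying lineage-progression model that
    generates synthetic track tables and tissue snapshots with configurable
    activation rates, growth laws, and asymmetric fate rules, so that every
    stage of the analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
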