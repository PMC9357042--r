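Package: linger
Title: Quantifying How Recently Read Material Lingers in Free Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the persistence ("lingering") of recently
    encountered material in spontaneous thought, operationalized as pre- vs.
    post-exposure changes in free-association word chains. Provides a
    synthetic cohort generator with a position-decaying theme-injection
    model; document-term matrix construction with within-participant
    scaling; leave-one-participant-out linear support-vector classification
    with bootstrap repeats and a label-flip permutation null; a word-embedding
    theme-similarity statistic (maximal cosine to a set of theme words) with
    pre/post contrasts and a binned time-course; word-level bias scores and
    odds ratios; nonparametric effect sizes (rank-biserial r, ranked epsilon
    squared); and cross-validated backward stepwise regression predicting
    self-reported lingering. An end-to-end pipeline ties the stages into one
    seeded, reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
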