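Package: fourpath
Title: Rates of Inbreeding and Effective Population Size under Four-Path
    Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic prediction of the per-generation rate of inbreeding
    (deltaF) and effective population size in discrete-generation breeding
    programs that truncation-select parents on genomically enhanced breeding
    values (GEBV) along the four classical paths: sires of sons (SS), sires of
    daughters (SD), dams of sons (DS) and dams of daughters (DD). The
    prediction is built from expected long-term genetic contributions: a
    gene-flow matrix and its unit left eigenvector give the average
    contribution per parent, regressions of offspring selective advantage and
    selected-offspring numbers on the parental selective advantage give the
    selection-induced contribution slopes, and deltaF follows as half a
    weighted sum of squared contributions, with an optional correction for the
    deviation of selected family sizes from Poisson variance. A stochastic
    four-path breeding simulator with exact pedigree (tabular relationship
    matrix) inbreeding serves as an independent Monte-Carlo check of every
    analytic component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
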