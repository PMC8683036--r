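Package: ardi
Title: Acoustic Reappearance Diversity Index for Animal Vocal Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating the acoustic reappearance
    diversity index (ARDI), a univariate measure of musical patterning in
    animal vocalizations scored from spectrograms. Implements multi-rater
    score aggregation with reliability statistics (mean pairwise Spearman
    correlation, Cronbach's alpha, rater-subset agreement curves),
    correlation-matrix principal components analysis with Jolliffe's
    backward variable elimination (method B2) and a battery of component
    retention stopping rules (Kaiser-Guttman, parallel analysis, broken
    stick, Velicer's MAP, Bartlett's test, scree and LEV elbows),
    reappearance-probability and song-complexity indices, corroboration of
    indices against researcher call-name labels, species-level
    socioecological hypothesis tests, and a seeded synthetic score
    generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
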