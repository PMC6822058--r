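Package: mdpr
Title: Molecular Degree of Perturbation Scoring for Transcriptome Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores transcriptome samples by their molecular degree of
    perturbation (MDP): a robust modified z-score distance from a
    user-defined control class, computed per gene from the control
    median and median absolute deviation, thresholded, and averaged over
    a gene universe (all genes, the most perturbed genes, or a supplied
    GMT gene set). Provides class-wise outlier flagging from the scores,
    Student t-test differential expression with Benjamini-Hochberg
    adjustment, before/after outlier-removal comparison against a
    seeded random-removal null distribution, single-cell gene filtering
    and MDP-by-viral-load quadrant contrasts, and seeded synthetic
    bulk and single-cell data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
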