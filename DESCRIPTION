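Package: lipidproc
Title: Processing and Quantitation of High-Resolution Lipidomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for untargeted high-resolution lipidomics feature
    tables: lipid species annotation by accurate mass within a ppm tolerance,
    natural-isotope-abundance correction with joint deconvolution of
    overlapping isotopologue peak groups, internal-standard normalization and
    protein scaling, lipid class summation and fold-change estimation,
    differential statistics (Student's t-test, one-way ANOVA with Bonferroni
    correction, Dunnett's test versus control), PLS-DA with variable importance
    in projection (VIP) ranking, ether-lipid (plasmanyl/plasmenyl)
    classification from acid-hydrolysis experiments, and stable-isotope
    dilution quantitation of CTP:phosphoethanolamine cytidylyltransferase
    activity. Includes a ground-truthed synthetic-study generator emulating
    control versus patient fibroblast and plasma lipidomes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    multcomp,
    pheatmap
Config/testthat/edition: 3
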