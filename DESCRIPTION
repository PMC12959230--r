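Package: sepalcv
Title: Morphological Robustness Screens for Arabidopsis Sepal Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify morphological robustness of Arabidopsis sepals
    and relate it to wild-type gene-expression statistics. Extracts area,
    length, width and aspect ratio from black-background sepal photographs or
    contours; computes squared coefficients of variation (CV2) and
    batch-corrected relative effects per knockout genotype; screens mutant
    phenotype dispersion against mean and variability of the corresponding
    gene's wild-type expression with Pearson correlation tests; and probes the
    resilience of any screen with subsampling replicates and exhaustive
    leave-x-out enumeration. Includes a synthetic-data generator producing
    measurement tables, expression matrices and rasterized sepal outlines with
    known ground truth, so the full pipeline is testable without raw data.
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
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    tiff,
    withr
Config/testthat/edition: 3
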