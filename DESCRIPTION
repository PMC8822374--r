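Package: annoqc
Title: Quality Control for Whole-Slide Image Annotation Projects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A data-dictionary-driven toolkit for quality control of
    pathologist annotations on whole-slide images. Provides an annotation
    data model with JSON and GeoJSON input/output and dictionary-based
    validation; exact polygon geometry (areas, unions, Jaccard similarity)
    for region agreement; tissue masking so exhaustiveness is measured over
    tissue only; the four annotation QC metrics (completeness,
    exhaustiveness, diversity, agreement); pairwise inter-annotator
    agreement for cell point annotations via globally optimal radius-based
    matching, confusion matrices and weighted Cohen's kappa; an automatic
    QC pipeline with an issue log; and a multi-annotator simulator with
    closed-form expectations so every metric is testable without external
    slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    EBImage,
    jsonlite,
    png,
    polyclip,
    stats,
    utils
Suggests:
    optparse,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
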