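Package: agemark
Title: Age-Aware Detection and Validation of Gut-Microbiome Disease Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and validating age-group-specific
    disease signatures in gut-microbiome taxonomic profiles. Provides
    region-matched cohort binning, PERMANOVA with confounders and
    interaction terms, an iterative same-age versus different-age
    random-forest classification framework with paired Wilcoxon and
    permutation-null testing, stability-based marker selection with
    linear-model ageing deconvolution, gain/loss directionality and
    shared multi-disease response grouping, frailty regression from
    taxonomic composition, and species-to-metabolite capability
    inference. Ships a synthetic multi-cohort generator with planted
    region, batch, ageing, disease and disease-by-age effects so that
    every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
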