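Package: cbsmap
Title: Variant Effect Maps and Vitamin B6 Remediability for CBS Complementation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multiplexed yeast-complementation screens of
    human cystathionine beta-synthase (CBS) variants. Converts per-variant
    sequencing count tables into background-corrected allele frequencies,
    anchored fitness scores with regularized errors, and vitamin-B6
    remediability (delta) scores; classifies deleterious and B6-remediable
    variants against empirical synonymous/nonsense nulls with
    Benjamini-Hochberg FDR control; imputes and refines complete variant
    effect maps with gradient-boosted trees over intrinsic map features;
    evaluates maps against pathogenic/benign reference sets
    (precision-recall, Bayes-factor log-likelihood ratios, fitness-activity
    curves); and scores diploid patient genotypes for correlation with
    ordinal clinical phenotypes. A synthetic-data generator emulates the
    mutagenized clone library, pooled selection, and sequencing so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    minpack.lm
Config/testthat/edition: 3
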