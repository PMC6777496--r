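Package: growthnet
Title: Candidate-Gene Discovery for Idiopathic Short Stature from Trio Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a candidate-gene discovery analysis
    for idiopathic short stature cohorts. Detects de novo, compound
    heterozygous, homozygous and X-linked recessive inheritance in trio
    exomes, classifies variants on the five-class (benign to pathogenic)
    scale by population frequency and predicted effect, merges variant- and
    gene-level evidence into a combined 1-4 score with high/medium confidence
    tiering, performs Fisher exact gene-set enrichment with
    Benjamini-Hochberg FDR control, clusters enriched annotation terms by
    Cohen's kappa over shared genes with a fuzzy seed-and-merge heuristic,
    and maps candidate genes onto the resulting clusters with treemap
    reporting. Includes a synthetic-data generator that plants known
    inheritance patterns, enriched terms and correlated annotation blocks so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
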