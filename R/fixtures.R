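fixture_path <- function(file) {
  system.file("extdata", file, package = "growthnet", mustWork = TRUE)
}

#' Reference fixture: high-confidence short-stature candidate genes
#'
#' The 13 high-confidence candidate genes from a 254-family idiopathic
#' short-stature exome screen, transcribed from the published per-gene
#' summary: independent family count, variant tallies per class (V/IV/III),
#' gene-level evidence category count (of 8), and the combined 1-4 score
#' range across families. Where the published rendering leaves the
#' per-class tally assignment ambiguous, `tally_uncertain` is TRUE (family
#' counts, category counts and scores are unambiguous throughout).
#'
#' @return Tibble with one row per gene, directly consumable by
#'   [tier_genes()].
#' @export
iss_candidates <- function() {
  readr::read_tsv(fixture_path("iss_high_confidence_candidates.tsv"),
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    tally_uncertain = readr::col_logical(),
                    .default = readr::col_integer()),
                  progress = FALSE)
}

#' Reference fixture: previously reported candidate genes
#'
#' The 6 candidate genes of the screen that had previously been associated
#' with short stature or syndromes featuring it.
#'
#' @return Tibble: gene, confidence, n_families.
#' @export
iss_reported_candidates <- function() {
  readr::read_tsv(fixture_path("iss_reported_candidates.tsv"),
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    confidence = readr::col_character(),
                    n_families = readr::col_integer()),
                  progress = FALSE)
}

#' Reference fixture: enriched growth-gene clusters
#'
#' The 29 significantly enriched annotation clusters of the 1025
#' growth/short-stature gene network, with their gene counts, mean fold
#' enrichments, and the high/medium-confidence candidate genes mapped to
#' each (high-confidence gene lists as published; some cluster rows carry
#' counts without itemised gene lists).
#'
#' @return Tibble with one row per cluster.
#' @export
growth_clusters <- function() {
  readr::read_tsv(fixture_path("growth_gene_clusters.tsv"),
                  col_types = readr::cols(
                    cluster = readr::col_character(),
                    high_conf_genes = readr::col_character(),
                    n_growth_genes = readr::col_integer(),
                    n_high_conf = readr::col_integer(),
                    n_medium_conf = readr::col_integer(),
                    .default = readr::col_double()),
                  progress = FALSE)
}

#' Growth-cluster fixture as a `term_clusters` object
#'
#' Recasts [growth_clusters()] so cluster-level operations such as
#' [map_candidates()] and [treemap_layout()] can consume it: each cluster
#' becomes a single pseudo member term whose gene set is the itemised
#' high-confidence candidate list (clusters without an itemised list get an
#' empty gene union).
#'
#' @return A `term_clusters` tibble.
#' @export
growth_clusters_as_term_clusters <- function() {
  g <- growth_clusters()
  genes <- map(g$high_conf_genes, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
  })
  out <- tibble(
    cluster_id = sprintf("C%02d", seq_len(nrow(g))),
    representative_label = g$cluster,
    n_terms = 1L,
    member_terms = as.list(g$cluster),
    gene_union = genes,
    gene_union_size = g$n_growth_genes,
    enrichment_score = NA_real_,
    mean_fold_enrichment = g$mean_fold_enrichment
  )
  class(out) <- c("term_clusters", class(out))
  out
}

#' Full 63-candidate tier table (reference plus synthetic stand-ins)
#'
#' The screen reported 63 candidate genes: the 13 high-confidence genes
#' (transcribed, [iss_candidates()]) and 50 medium-confidence genes of
#' which only the 5 previously reported ones are itemised in the main text.
#' This builds the complete table by combining the transcribed rows with
#' deterministic synthetic stand-ins (genes `SYNMED01`..`SYNMED45`,
#' `synthetic = TRUE`) for the non-itemised medium-confidence genes:
#' single-family candidates with a VUS and modest gene-level support, which
#' the default thresholds place in the medium tier.
#'
#' @return Tibble consumable by [tier_genes()], 63 rows.
#' @export
iss_cohort_candidates <- function() {
  high <- iss_candidates() |>
    select("gene", "n_families", "n_class_V", "n_class_IV", "n_class_III",
           "category_count", "score_min", "score_max") |>
    mutate(synthetic = FALSE)
  named_medium <- iss_reported_candidates() |>
    filter(.data$confidence == "medium") |>
    transmute(gene = .data$gene, n_families = .data$n_families,
              n_class_V = 0L, n_class_IV = 0L, n_class_III = .data$n_families,
              category_count = 2L, score_min = 2L, score_max = 2L,
              synthetic = FALSE)
  n_syn <- 50L - nrow(named_medium)
  synthetic_medium <- tibble(
    gene = sprintf("SYNMED%02d", seq_len(n_syn)),
    n_families = 1L, n_class_V = 0L, n_class_IV = 0L, n_class_III = 1L,
    category_count = rep_len(1:4, n_syn), score_min = 2L, score_max = 2L,
    synthetic = TRUE)
  bind_rows(high, named_medium, synthetic_medium)
}
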