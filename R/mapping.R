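#' Map candidate genes onto enriched term clusters
#'
#' A candidate maps to a cluster when it belongs to at least one member
#' term's gene set (equivalently, to the cluster's gene union); set
#' semantics, so multiple member-term hits count once per cluster. Also
#' reports the candidates that map to no cluster and the number of clusters
#' hit.
#'
#' @param clusters A `term_clusters` tibble (needs cluster_id,
#'   gene_union).
#' @param candidates Character vector of candidate gene symbols.
#' @return A `cluster_mapping` tibble with one row per cluster:
#'   cluster_id, representative_label (when present),
#'   candidate_genes_in_cluster (list-column), n_candidates. Attributes
#'   `mapped`, `unmapped` and `n_clusters_hit` carry the cross-cluster
#'   summary; [glance()] tidies them.
#' @export
map_candidates <- function(clusters, candidates) {
  if (length(candidates) == 0) abort("`candidates` must be non-empty")
  candidates <- unique(toupper(candidates))
  hits <- map(clusters$gene_union,
              function(g) sort(intersect(unique(toupper(g)), candidates)))
  out <- tibble(cluster_id = clusters$cluster_id)
  if ("representative_label" %in% names(clusters)) {
    out$representative_label <- clusters$representative_label
  }
  out$candidate_genes_in_cluster <- hits
  out$n_candidates <- lengths(hits)
  mapped <- sort(unique(unlist(hits)))
  attr(out, "mapped") <- mapped
  attr(out, "unmapped") <- sort(setdiff(candidates, mapped))
  attr(out, "n_clusters_hit") <- sum(lengths(hits) > 0)
  class(out) <- c("cluster_mapping", class(out))
  out
}

#' @exportS3Method generics::glance
glance.cluster_mapping <- function(x, ...) {
  mapped <- attr(x, "mapped")
  unmapped <- attr(x, "unmapped")
  total <- length(mapped) + length(unmapped)
  tibble(n_clusters = nrow(x),
         n_clusters_hit = attr(x, "n_clusters_hit"),
         n_candidates = total,
         n_mapped = length(mapped),
         pct_mapped = if (total > 0) round_half_up(100 * length(mapped) / total) else 0,
         unmapped = list(unmapped))
}

#' Unmapped candidates of a cluster mapping
#' @param mapping A `cluster_mapping` from [map_candidates()].
#' @return Character vector.
#' @export
unmapped_candidates <- function(mapping) attr(mapping, "unmapped")

#' Mean fold enrichment of the candidate list across a cluster's terms
#'
#' Recomputes each member term's fold enrichment with the candidate list as
#' the query list against the background, and averages arithmetically.
#' Returns 0 when no candidate hits any member term.
#'
#' @param cluster One row of a `term_clusters` tibble (or a list with
#'   `member_terms`).
#' @param candidates Character candidate gene list.
#' @param terms Term tibble with `term` and `genes` list-column.
#' @param background Character gene universe (must cover the candidates).
#' @return A single numeric mean fold enrichment.
#' @export
candidate_fold_enrichment <- function(cluster, candidates, terms, background) {
  if (length(background) == 0) abort("`background` must be non-empty")
  members <- if (is.data.frame(cluster)) cluster$member_terms[[1]] else cluster$member_terms
  sub <- terms[match(members, terms$term), ]
  if (anyNA(sub$term)) abort("cluster member term missing from `terms`")
  enr <- term_enrichment(candidates, sub, background)
  if (all(enr$a == 0)) return(0)
  mean(enr$fold_enrichment)
}

#' Assemble the final candidate-gene report
#'
#' Writes the machine-readable bundle of the analysis: `report.json`
#' (summary, tier table, cluster mapping), `table2_like.tsv` (per-gene:
#' family count, class tallies, category count, combined score range,
#' tier) and `table4_like.tsv` (per-cluster: representative label, term
#' and gene counts, enrichment summaries, mapped candidates). Writing is
#' idempotent: re-running on the same inputs reproduces identical files.
#'
#' @param tiered Tiered candidate tibble from [tier_genes()].
#' @param mapping Optional `cluster_mapping` from [map_candidates()].
#' @param clusters Optional `term_clusters` used to fill cluster columns.
#' @param summary Optional one-row cohort summary from
#'   [summarize_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written paths and the tables.
#' @export
build_report <- function(tiered, mapping = NULL, clusters = NULL,
                         summary = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  table2 <- tiered |>
    as_tibble() |>
    arrange(factor(.data$tier, levels = c("high", "medium", "rejected")),
            desc(.data$n_families), .data$gene)
  table2_path <- file.path(dir, "table2_like.tsv")
  readr::write_tsv(table2, table2_path)

  table4 <- NULL
  table4_path <- NULL
  if (!is.null(mapping)) {
    table4 <- as_tibble(mapping) |>
      mutate(candidate_genes_in_cluster = map_chr(
        .data$candidate_genes_in_cluster, paste, collapse = ","))
    if (!is.null(clusters)) {
      table4 <- as_tibble(clusters) |>
        select("cluster_id", "n_terms", "gene_union_size",
               "enrichment_score", "mean_fold_enrichment") |>
        right_join(table4, by = "cluster_id") |>
        relocate("representative_label", .after = "cluster_id")
    }
    table4_path <- file.path(dir, "table4_like.tsv")
    readr::write_tsv(table4, table4_path)
  }

  report <- list(
    summary = if (is.null(summary)) NULL else
      as.list(summary |> select(-dplyr::any_of(
        c("inheritance_spectrum", "consequence_spectrum")))),
    tiers = as.list(table(table2$tier)),
    genes = table2,
    clusters = table4,
    mapping = if (is.null(mapping)) NULL else list(
      mapped = attr(mapping, "mapped"),
      unmapped = attr(mapping, "unmapped"),
      n_clusters_hit = attr(mapping, "n_clusters_hit"))
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(report = report,
                 paths = c(json = json_path, table2 = table2_path,
                           table4 = table4_path)))
}
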