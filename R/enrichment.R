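#' Per-term enrichment of a gene list against a background
#'
#' For each annotation term, forms the 2x2 table of list membership versus
#' term membership over the background universe: `a` list genes with the
#' term out of `A` list genes, `b` non-list genes with the term out of `B`
#' non-list genes. Computes the one-sided (over-representation) Fisher exact
#' p-value (the upper hypergeometric tail), the odds ratio
#' `(a/(A-a)) / (b/(B-b))`, the fold enrichment `(a/A) / ((a+b)/(A+B))`, and
#' Benjamini-Hochberg adjusted p-values across the supplied terms.
#'
#' Gene identifiers are harmonised by case-insensitive exact match only.
#' Degenerate cells follow documented sentinels: `a = 0` gives odds ratio
#' and fold enrichment 0; `A - a = 0` or `b = 0` (with term genes outside
#' the list possible) gives odds ratio `Inf`.
#'
#' @param gene_list Character vector of query genes (must be contained in
#'   `background`).
#' @param terms Tibble with `term` (or `term_id`) and a `genes` list-column,
#'   as returned by [read_gmt()] or [simulate_annotation_corpus()].
#' @param background Character vector: the gene universe.
#' @param alternative "greater" (over-representation, default) or
#'   "two.sided" (classical Fisher via [stats::fisher.test()]).
#' @param ease If TRUE, apply the EASE-style conservative adjustment: the
#'   tail is computed with one list hit removed (`a - 1`).
#' @return Tibble: term_id, a, A, b, B, p_raw, fdr, odds_ratio,
#'   fold_enrichment, ordered as the input terms.
#' @export
term_enrichment <- function(gene_list, terms, background,
                            alternative = c("greater", "two.sided"),
                            ease = FALSE) {
  alternative <- match.arg(alternative)
  background <- unique(toupper(background))
  gene_list <- unique(toupper(gene_list))
  if (length(background) == 0) abort("`background` must be non-empty")
  if (length(gene_list) == 0) abort("`gene_list` must be non-empty")
  outside <- setdiff(gene_list, background)
  if (length(outside) > 0) {
    abort(sprintf("gene_list members outside the background: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  id_col <- if ("term_id" %in% names(terms)) "term_id" else "term"
  A <- length(gene_list)
  B <- length(background) - A

  term_genes <- map(terms$genes, function(g) intersect(unique(toupper(g)), background))
  a <- map_int(term_genes, function(g) length(intersect(g, gene_list)))
  m <- lengths(term_genes)
  b <- m - a

  if (alternative == "greater") {
    a_eff <- if (ease) pmax(a - 1L, 0L) else a
    p <- phyper(a_eff - 1L, A, B, a_eff + b, lower.tail = FALSE)
  } else {
    p <- vapply(seq_along(a), function(i) {
      stats::fisher.test(matrix(c(a[i], A - a[i], b[i], B - b[i]), 2))$p.value
    }, numeric(1))
  }
  p <- pmin(p, 1)

  odds_ratio <- rep(NA_real_, length(a))
  zero <- a == 0
  inf <- !zero & (A - a == 0 | b == 0)
  finite <- !zero & !inf
  odds_ratio[zero] <- 0
  odds_ratio[inf] <- Inf
  odds_ratio[finite] <- (a[finite] / (A - a[finite])) /
    (b[finite] / (B - b[finite]))
  fold <- ifelse(a == 0, 0, (a / A) / ((a + b) / (A + B)))

  tibble(term_id = terms[[id_col]], a = a, A = A, b = b, B = B,
         p_raw = p, fdr = bh_fdr(p), odds_ratio = odds_ratio,
         fold_enrichment = fold)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement; each input
#' value receives its adjusted value in place, so the result is invariant
#' to permutation of the input.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Filter significantly enriched terms
#'
#' Keeps terms with BH-adjusted p at or below `alpha`, sorted by raw p
#' ascending with ties broken lexicographically by term id.
#'
#' @param results Tibble from [term_enrichment()] (needs term_id, p_raw,
#'   fdr).
#' @param alpha FDR threshold (default 0.05).
#' @return Filtered, sorted tibble.
#' @export
significant_terms <- function(results, alpha = 0.05) {
  results |>
    filter(.data$fdr <= alpha) |>
    arrange(.data$p_raw, .data$term_id)
}
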