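#' Parameters for kappa-based fuzzy annotation clustering
#'
#' Defaults follow the settings used for the growth-gene network: term
#' pairs must share at least 5 genes before their kappa is considered
#' (`min_gene_overlap`), initial seeds and final clusters must hold at
#' least 5 terms, merging requires a 50% membership linkage, and the kappa
#' similarity threshold is 0.20 (the upstream clustering tool takes this
#' parameter as an integer x100, hence "kappa = 20").
#'
#' @param min_gene_overlap Minimum shared genes for a term pair to score.
#' @param initial_seed_size Minimum seed size.
#' @param final_cluster_size Minimum size of a reported cluster.
#' @param linkage_threshold Shared-member fraction required to merge.
#' @param kappa_threshold Kappa similarity threshold in (0, 1].
#' @param membership_fraction Minimum fraction of within-seed term pairs
#'   that must pass the kappa threshold.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(min_gene_overlap = 5, initial_seed_size = 5,
                              final_cluster_size = 5, linkage_threshold = 0.5,
                              kappa_threshold = 0.20,
                              membership_fraction = 0.5) {
  for (f in c("linkage_threshold", "kappa_threshold", "membership_fraction")) {
    v <- get(f)
    if (v <= 0 || v > 1) abort(sprintf("`%s` must lie in (0, 1]", f))
  }
  if (initial_seed_size < 2 || final_cluster_size < 2) {
    abort("seed and cluster sizes must be at least 2")
  }
  structure(list(min_gene_overlap = min_gene_overlap,
                 initial_seed_size = initial_seed_size,
                 final_cluster_size = final_cluster_size,
                 linkage_threshold = linkage_threshold,
                 kappa_threshold = kappa_threshold,
                 membership_fraction = membership_fraction),
            class = "clustering_params")
}

#' Pairwise Cohen's kappa between annotation terms
#'
#' For every pair of terms, forms the 2x2 agreement table of their binary
#' gene-annotation vectors over the universe (a = genes in both, b/c = in
#' one only, d = in neither; T = universe size) and computes
#' kappa = (Po - Pe) / (1 - Pe) with Po = (a + d) / T and
#' Pe = ((a+b)(a+c) + (c+d)(b+d)) / T^2. Pairs sharing fewer than
#' `min_gene_overlap` genes are gated to 0; the diagonal is 1. Degenerate
#' pairs with Pe = 1 (constant annotation vectors) are set to 0 with a
#' warning.
#'
#' @param terms Tibble with `term` and `genes` list-column.
#' @param universe Character gene universe covering all term genes.
#' @param params A [clustering_params()].
#' @return Symmetric numeric matrix with term ids as dimnames.
#' @export
kappa_matrix <- function(terms, universe, params = clustering_params()) {
  universe <- unique(toupper(universe))
  Tn <- length(universe)
  ids <- terms$term
  M <- matrix(0, nrow(terms), Tn, dimnames = list(ids, NULL))
  for (i in seq_len(nrow(terms))) {
    g <- unique(toupper(terms$genes[[i]]))
    idx <- match(g, universe)
    if (anyNA(idx)) abort(sprintf("term %s has genes outside the universe", ids[i]))
    M[i, idx] <- 1
  }
  a <- M %*% t(M)
  size <- rowSums(M)
  bm <- outer(size, size, function(x, y) x) - a  # b: in row term only
  cm <- outer(size, size, function(x, y) y) - a  # c: in column term only
  dm <- Tn - a - bm - cm
  po <- (a + dm) / Tn
  pe <- ((a + bm) * (a + cm) + (cm + dm) * (bm + dm)) / Tn^2
  kappa <- (po - pe) / (1 - pe)
  degen <- abs(1 - pe) < 1e-12
  if (any(degen & row(a) != col(a))) {
    warn("degenerate constant annotation pair(s); kappa set to 0")
  }
  kappa[degen] <- 0
  kappa[a < params$min_gene_overlap] <- 0
  diag(kappa) <- 1
  dimnames(kappa) <- list(ids, ids)
  kappa
}

#' Form initial fuzzy seeds from a kappa matrix
#'
#' Each term seeds a candidate group consisting of itself plus all
#' neighbours whose kappa reaches `kappa_threshold`. A seed is kept when it
#' holds at least `initial_seed_size` terms and at least
#' `membership_fraction` of all within-seed term pairs pass the kappa
#' threshold; duplicated seeds are removed.
#'
#' @param kappa Matrix from [kappa_matrix()].
#' @param params A [clustering_params()].
#' @return List of character vectors (sorted term ids), one per seed.
#' @export
form_seeds <- function(kappa, params = clustering_params()) {
  ids <- rownames(kappa)
  seeds <- list()
  for (i in seq_along(ids)) {
    members <- sort(union(ids[i], ids[kappa[i, ] >= params$kappa_threshold]))
    if (length(members) < params$initial_seed_size) next
    sub <- kappa[members, members, drop = FALSE]
    tight <- sum(sub[upper.tri(sub)] >= params$kappa_threshold)
    if (tight / choose(length(members), 2) >= params$membership_fraction) {
      seeds[[length(seeds) + 1]] <- members
    }
  }
  unique(seeds)
}

#' Merge fuzzy seeds into final clusters
#'
#' Iteratively merges the pair of groups sharing the largest member
#' fraction (intersection size over the smaller group's size) at or above
#' `linkage_threshold`, breaking ties by the smaller merged size and then
#' by the lexicographically smallest member, until no pair qualifies.
#' Groups smaller than `final_cluster_size` are then discarded. The
#' procedure is deterministic and invariant to input order.
#'
#' @param seeds List of character vectors from [form_seeds()].
#' @param params A [clustering_params()].
#' @return Tibble: cluster_id, member_terms (list-column of sorted ids),
#'   n_terms.
#' @export
merge_clusters <- function(seeds, params = clustering_params()) {
  groups <- unique(lapply(seeds, function(s) sort(unique(s))))
  # canonical order so the tie-break is independent of input order
  groups <- groups[order(map_chr(groups, function(g) paste(g, collapse = "\r")))]
  repeat {
    n <- length(groups)
    if (n < 2) break
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ov <- length(intersect(groups[[i]], groups[[j]]))
        share <- ov / min(length(groups[[i]]), length(groups[[j]]))
        if (share < params$linkage_threshold) next
        merged <- sort(union(groups[[i]], groups[[j]]))
        cand <- list(share = share, size = length(merged),
                     first = merged[1], i = i, j = j)
        if (is.null(best) ||
            cand$share > best$share ||
            (cand$share == best$share && cand$size < best$size) ||
            (cand$share == best$share && cand$size == best$size &&
             cand$first < best$first)) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    merged <- sort(union(groups[[best$i]], groups[[best$j]]))
    groups <- groups[-c(best$i, best$j)]
    groups <- unique(c(groups, list(merged)))
    groups <- groups[order(map_chr(groups, function(g) paste(g, collapse = "\r")))]
  }
  groups <- groups[lengths(groups) >= params$final_cluster_size]
  groups <- groups[order(-lengths(groups), map_chr(groups, function(g) g[1] %||% ""))]
  tibble(cluster_id = sprintf("C%02d", seq_along(groups)),
         member_terms = groups,
         n_terms = lengths(groups))
}

#' Cluster annotation terms end to end
#'
#' Convenience wrapper: [kappa_matrix()] then [form_seeds()] then
#' [merge_clusters()].
#'
#' @inheritParams kappa_matrix
#' @return Tibble of clusters as from [merge_clusters()].
#' @export
cluster_terms <- function(terms, universe, params = clustering_params()) {
  kappa <- kappa_matrix(terms, universe, params)
  merge_clusters(form_seeds(kappa, params), params)
}

#' Prune clusters by FDR and summarise them
#'
#' Raw p-values drive the clustering; only afterwards are member terms with
#' FDR above `alpha` pruned. Clusters that fall below `final_cluster_size`
#' are dropped unless `keep_small = TRUE`. Each surviving cluster is
#' summarised by its representative term (lowest raw p, ties broken by
#' larger gene set then lexicographically), the union of member gene sets,
#' the enrichment score (-log10 of the geometric mean of member raw
#' p-values) and the arithmetic mean fold enrichment.
#'
#' @param clusters Tibble from [merge_clusters()] / [cluster_terms()].
#' @param enrichment Tibble from [term_enrichment()] covering every member
#'   term (a missing term is an error).
#' @param terms Term tibble with `genes` list-column, for gene unions.
#' @param alpha FDR pruning threshold (default 0.05).
#' @param params A [clustering_params()].
#' @param keep_small Keep clusters below `final_cluster_size` after
#'   pruning.
#' @return A `term_clusters` tibble: cluster_id, representative_label,
#'   n_terms, member_terms, gene_union, gene_union_size, enrichment_score,
#'   mean_fold_enrichment.
#' @export
prune_and_summarize <- function(clusters, enrichment, terms, alpha = 0.05,
                                params = clustering_params(),
                                keep_small = FALSE) {
  id_col <- if ("term_id" %in% names(enrichment)) "term_id" else "term"
  all_members <- unique(unlist(clusters$member_terms))
  missing <- setdiff(all_members, enrichment[[id_col]])
  if (length(missing) > 0) {
    abort(sprintf("no enrichment result for term(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  enr <- enrichment
  enr$.term <- enr[[id_col]]
  gene_sets <- setNames(map(terms$genes, function(g) unique(toupper(g))), terms$term)

  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    members <- clusters$member_terms[[i]]
    e <- enr[match(members, enr$.term), ]
    keep <- e$fdr <= alpha
    members <- members[keep]
    e <- e[keep, ]
    if (length(members) == 0) next
    if (!keep_small && length(members) < params$final_cluster_size) next
    set_size <- lengths(gene_sets[members])
    ord <- order(e$p_raw, -set_size, members)
    rep_label <- members[ord[1]]
    union_genes <- sort(unique(unlist(gene_sets[members])))
    rows[[length(rows) + 1]] <- tibble(
      cluster_id = clusters$cluster_id[i],
      representative_label = rep_label,
      n_terms = length(members),
      member_terms = list(members),
      gene_union = list(union_genes),
      gene_union_size = length(union_genes),
      enrichment_score = -mean(log10(e$p_raw)),
      mean_fold_enrichment = mean(e$fold_enrichment)
    )
  }
  out <- if (length(rows) == 0) {
    tibble(cluster_id = character(), representative_label = character(),
           n_terms = integer(), member_terms = list(), gene_union = list(),
           gene_union_size = integer(), enrichment_score = numeric(),
           mean_fold_enrichment = numeric())
  } else {
    bind_rows(rows)
  }
  class(out) <- c("term_clusters", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.term_clusters <- function(x, ...) {
  x |>
    as_tibble() |>
    select("cluster_id", "representative_label", "member_terms") |>
    unnest(cols = "member_terms") |>
    rename(term = "member_terms")
}

#' @exportS3Method generics::glance
glance.term_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_terms = sum(x$n_terms),
         n_genes = length(unique(unlist(x$gene_union))),
         max_cluster_genes = if (nrow(x)) max(x$gene_union_size) else NA_integer_)
}

#' Squarified treemap layout for clusters
#'
#' Lays the clusters out as a treemap on a 100x100 canvas, rectangle area
#' proportional to `gene_union_size` (or any other area column). Clusters
#' are placed in deterministic order: area descending, ties broken
#' lexicographically by label.
#'
#' @param clusters A `term_clusters` tibble, or any tibble with a label and
#'   an area column.
#' @param area Name of the area column (default "gene_union_size").
#' @param label Name of the label column (default "representative_label").
#' @return Tibble: cluster_id (if present), label, area, xmin, ymin, xmax,
#'   ymax.
#' @export
treemap_layout <- function(clusters, area = "gene_union_size",
                           label = "representative_label") {
  df <- as_tibble(clusters)
  if (nrow(df) == 0) {
    return(tibble(label = character(), area = numeric(), xmin = numeric(),
                  ymin = numeric(), xmax = numeric(), ymax = numeric()))
  }
  df <- df[order(-df[[area]], df[[label]]), ]
  areas <- df[[area]] / sum(df[[area]]) * 100 * 100
  rects <- squarify(areas, 0, 0, 100, 100)
  out <- tibble(label = df[[label]], area = df[[area]],
                xmin = rects$x, ymin = rects$y,
                xmax = rects$x + rects$w, ymax = rects$y + rects$h)
  if ("cluster_id" %in% names(df)) out <- bind_cols(tibble(cluster_id = df$cluster_id), out)
  out
}

# classic squarified treemap: fill rows along the shorter side, fixing a
# row when adding the next area would worsen its worst aspect ratio
squarify <- function(areas, x, y, w, h) {
  n <- length(areas)
  if (n == 0) return(tibble(x = numeric(), y = numeric(), w = numeric(), h = numeric()))
  worst <- function(row, side) {
    s <- sum(row)
    mx <- max(row); mn <- min(row)
    max(side^2 * mx / s^2, s^2 / (side^2 * mn))
  }
  layout_row <- function(row, x, y, w, h) {
    s <- sum(row)
    if (w >= h) {  # lay the row vertically along the left edge
      rw <- s / h
      ys <- y + c(0, cumsum(row / rw))[seq_along(row)]
      list(rects = tibble(x = x, y = ys, w = rw, h = row / rw),
           x = x + rw, y = y, w = w - rw, h = h)
    } else {
      rh <- s / w
      xs <- x + c(0, cumsum(row / rh))[seq_along(row)]
      list(rects = tibble(x = xs, y = y, w = row / rh, h = rh),
           x = x, y = y + rh, w = w, h = h - rh)
    }
  }
  out <- list()
  i <- 1
  while (i <= n) {
    side <- min(w, h)
    row <- areas[i]
    j <- i
    while (j < n) {
      if (worst(c(row, areas[j + 1]), side) <= worst(row, side)) {
        j <- j + 1
        row <- c(row, areas[j])
      } else break
    }
    placed <- layout_row(row, x, y, w, h)
    out[[length(out) + 1]] <- placed$rects
    x <- placed$x; y <- placed$y; w <- placed$w; h <- placed$h
    i <- j + 1
  }
  bind_rows(out)
}

#' Plot a cluster treemap
#'
#' @param clusters A `term_clusters` tibble (or a precomputed
#'   [treemap_layout()]).
#' @param ... Passed to [treemap_layout()].
#' @return A ggplot object.
#' @export
plot_treemap <- function(clusters, ...) {
  layout <- if (all(c("xmin", "xmax") %in% names(clusters))) {
    clusters
  } else {
    treemap_layout(clusters, ...)
  }
  ggplot2::ggplot(layout,
                  ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                               ymin = .data$ymin, ymax = .data$ymax)) +
    ggplot2::geom_rect(ggplot2::aes(fill = .data$area),
                       colour = "white", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$label),
                       size = 3, lineheight = 0.8) +
    ggplot2::scale_fill_gradient(low = "#c6dbef", high = "#2171b5",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.term_clusters <- function(object, ...) plot_treemap(object, ...)
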