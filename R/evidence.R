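#' Build gene evidence profiles
#'
#' Validates the 8 boolean evidence-category columns (see
#' [evidence_categories()]) and derives `category_count`, the number of
#' categories supporting each gene (0-8).
#'
#' @param evidence Tibble with `gene` plus the 8 category columns, holding
#'   logicals or 0/1/TRUE/FALSE strings (as read by [read_evidence()]).
#' @return Tibble `gene`, the 8 logical flags, `category_count`.
#' @export
build_evidence_profiles <- function(evidence) {
  cats <- evidence_categories()
  missing <- setdiff(cats, names(evidence))
  if (length(missing) > 0) {
    abort(sprintf("evidence table lacks category column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(gene = toupper(as.character(evidence$gene)))
  for (cat in cats) {
    parsed <- parse_flag(evidence[[cat]])
    if (anyNA(parsed)) {
      bad <- out$gene[which(is.na(parsed))[1]]
      abort(sprintf("unparseable evidence flag for gene %s, column %s", bad, cat))
    }
    out[[cat]] <- parsed
  }
  out$category_count <- as.integer(rowSums(as.matrix(out[cats])))
  out
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Default combined-score decision table
#'
#' The 3x9 lookup mapping (best variant class III-V, gene-level category
#' count 0-8) to the combined score on the 1-4 scale. The default is
#' `clamp(1 + (class - 3) + (count >= 3) + (count >= 6), 1, 4)`: the scale
#' floor is a VUS with no gene-level support, the ceiling a pathogenic
#' variant in a gene with broad support, and the score is monotone
#' non-decreasing in both inputs. Users may supply any 3x9 matrix with the
#' same monotonicity in its place.
#'
#' @return Integer matrix with rownames "3".."5" and colnames "0".."8".
#' @export
default_score_table <- function() {
  tab <- outer(3:5, 0:8, function(cl, ct) {
    pmin(4L, pmax(1L, 1L + (cl - 3L) + (ct >= 3L) + (ct >= 6L)))
  })
  dimnames(tab) <- list(as.character(3:5), as.character(0:8))
  tab
}

#' Combine variant class and gene-level category count into a score
#'
#' Merges the variant-level classification (III, IV or V; benign classes
#' must already be excluded) with the gene-level evidence category count
#' into the combined 1-4 score via a decision table
#' ([default_score_table()] unless replaced).
#'
#' @param variant_class Integer vector in {3, 4, 5}.
#' @param category_count Integer vector in 0..8 (recycled).
#' @param table A 3x9 decision table.
#' @return Integer scores in 1..4.
#' @export
#' @examples
#' combine_scores(5, 5)  # pathogenic variant, 5 evidence categories -> 4
#' combine_scores(3, 4)  # VUS, 4 categories -> 2
combine_scores <- function(variant_class, category_count,
                           table = default_score_table()) {
  if (any(variant_class < 3 | variant_class > 5)) {
    abort("`variant_class` must be 3, 4 or 5 (benign variants must be excluded first)")
  }
  if (any(category_count < 0 | category_count > 8)) {
    abort("`category_count` must lie in 0..8")
  }
  n <- max(length(variant_class), length(category_count))
  variant_class <- rep_len(as.integer(variant_class), n)
  category_count <- rep_len(as.integer(category_count), n)
  as.integer(table[cbind(variant_class - 2L, category_count + 1L)])
}

#' Aggregate surviving variants into per-gene candidates
#'
#' For each gene, counts independent families (distinct `family_id` with at
#' least one surviving class >= III variant), tallies variants per class,
#' attaches the gene's evidence category count, computes the per-family
#' combined score from each family's best variant class, and reports the
#' gene-level score as the min-max range across families (the maximum is
#' what tiering uses).
#'
#' @param classified Surviving variants (after [exclude_benign()]) with
#'   `GENE`, `family_id`, `variant_class`.
#' @param profiles Output of [build_evidence_profiles()]; genes without a
#'   profile get category count 0.
#' @param score_table Decision table for [combine_scores()].
#' @return Tibble: gene, n_families, n_class_III/IV/V, category_count,
#'   score_min, score_max.
#' @export
score_candidates <- function(classified, profiles = NULL,
                             score_table = default_score_table()) {
  if (nrow(classified) == 0) {
    return(tibble(gene = character(), n_families = integer(),
                  n_class_III = integer(), n_class_IV = integer(),
                  n_class_V = integer(), category_count = integer(),
                  score_min = integer(), score_max = integer()))
  }
  if (any(classified$variant_class < 3)) {
    abort("benign variants present; run exclude_benign() first")
  }
  counts <- if (is.null(profiles)) {
    tibble(gene = character(), category_count = integer())
  } else {
    profiles |> select("gene", "category_count")
  }
  per_family <- classified |>
    mutate(gene = toupper(.data$GENE)) |>
    group_by(.data$gene, .data$family_id) |>
    summarise(best_class = max(.data$variant_class),
              n_III = sum(.data$variant_class == 3L),
              n_IV = sum(.data$variant_class == 4L),
              n_V = sum(.data$variant_class == 5L),
              .groups = "drop") |>
    left_join(counts, by = "gene") |>
    mutate(category_count = coalesce(.data$category_count, 0L),
           family_score = combine_scores(.data$best_class, .data$category_count,
                                         table = score_table))
  per_family |>
    group_by(.data$gene) |>
    summarise(n_families = dplyr::n_distinct(.data$family_id),
              n_class_III = sum(.data$n_III),
              n_class_IV = sum(.data$n_IV),
              n_class_V = sum(.data$n_V),
              category_count = .data$category_count[1],
              score_min = min(.data$family_score),
              score_max = max(.data$family_score),
              .groups = "drop") |>
    arrange(desc(.data$n_families), .data$gene)
}

#' Tier candidate genes into high / medium confidence
#'
#' A gene is a high-confidence candidate when it was hit in at least
#' `min_families_high` independent families and its maximum combined score
#' reaches `high_score_min`; otherwise it is medium-confidence when its
#' score reaches `medium_score_min` or any gene-level evidence category
#' supports it; otherwise it is rejected. Deterministic, and a fixed point:
#' re-tiering a tiered table changes nothing.
#'
#' @param candidates Tibble from [score_candidates()] (needs n_families,
#'   score_max; category_count used for the functional-evidence fallback).
#' @param high_score_min Minimum max combined score for high confidence
#'   (default 3).
#' @param medium_score_min Minimum max combined score for medium confidence
#'   (default 2).
#' @param min_families_high Minimum independent families for high
#'   confidence (default 2).
#' @return Input with a `tier` column ("high", "medium", "rejected").
#' @export
tier_genes <- function(candidates, high_score_min = 3, medium_score_min = 2,
                       min_families_high = 2) {
  if (nrow(candidates) == 0) {
    candidates$tier <- character()
    return(candidates)
  }
  cat_count <- candidates$category_count %||% rep(0L, nrow(candidates))
  candidates$tier <- dplyr::case_when(
    candidates$n_families >= min_families_high &
      candidates$score_max >= high_score_min ~ "high",
    candidates$score_max >= medium_score_min | cat_count >= 1 ~ "medium",
    TRUE ~ "rejected"
  )
  candidates
}

#' Summarise a tiered cohort
#'
#' Computes the headline bookkeeping of a candidate-gene screen: the
#' fraction of families carrying any candidate, genes per confidence tier,
#' the previously-reported fraction among candidates, and (when a variant
#' table is supplied) the inheritance-mode and consequence-type spectra.
#' Cohort percentages are rounded half-up to integers; the
#' previously-reported fraction is reported to one decimal.
#'
#' @param candidates Tiered candidate tibble (from [tier_genes()]), or NULL.
#' @param n_families_total Number of families analysed.
#' @param n_families_with_candidate Families with at least one candidate; if
#'   NULL it is derived from `variants` restricted to candidate genes.
#' @param n_previously_reported Number of candidates already reported in the
#'   literature (default 0).
#' @param variants Optional surviving-variant table (with `inheritance`,
#'   `CSQ`, `family_id`, `GENE`) for spectra and family counting.
#' @return A one-row tibble of counts and percentages; mode and consequence
#'   spectra are nested list-columns when available.
#' @export
summarize_cohort <- function(candidates = NULL, n_families_total,
                             n_families_with_candidate = NULL,
                             n_previously_reported = 0,
                             variants = NULL) {
  n_cand <- if (is.null(candidates)) 0L else nrow(candidates)
  n_high <- if (is.null(candidates) || n_cand == 0) 0L else sum(candidates$tier == "high")
  n_medium <- if (is.null(candidates) || n_cand == 0) 0L else sum(candidates$tier == "medium")
  if (is.null(n_families_with_candidate)) {
    n_families_with_candidate <- if (is.null(variants) || is.null(candidates) || n_cand == 0) {
      0L
    } else {
      variants |>
        filter(toupper(.data$GENE) %in% candidates$gene) |>
        pull(.data$family_id) |> dplyr::n_distinct()
    }
  }
  pct_families <- if (n_families_total > 0) {
    round_half_up(100 * n_families_with_candidate / n_families_total)
  } else 0
  pct_reported <- if (n_cand > 0) {
    round_half_up(100 * n_previously_reported / n_cand, 1)
  } else 0

  spectrum <- function(x) {
    if (is.null(variants) || !x %in% names(variants) || nrow(variants) == 0) {
      return(list(tibble(level = character(), n = integer(), pct = numeric())))
    }
    tab <- variants |>
      count(level = .data[[x]]) |>
      mutate(pct = round_half_up(100 * .data$n / sum(.data$n))) |>
      arrange(desc(.data$n))
    list(tab)
  }

  tibble(
    n_families_total = as.integer(n_families_total),
    n_families_with_candidate = as.integer(n_families_with_candidate),
    pct_families_with_candidate = pct_families,
    n_candidate_genes = n_cand,
    n_high_confidence = n_high,
    n_medium_confidence = n_medium,
    n_previously_reported = as.integer(n_previously_reported),
    pct_previously_reported = pct_reported,
    inheritance_spectrum = spectrum("inheritance"),
    consequence_spectrum = spectrum("CSQ")
  )
}
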