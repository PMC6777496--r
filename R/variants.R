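# genotype grammar: diploid "a/b" or "a|b", hemizygous single allele "a",
# with a, b in {0, 1, .}; "." marks a missing call

gt_alt_count <- function(gt) {
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

gt_ploidy <- function(gt) {
  lengths(strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE))
}

gt_valid <- function(gt) {
  grepl("^[01.]([/|][01.])?$", gt)
}

#' Detect trio inheritance patterns
#'
#' Labels each variant with the inheritance pattern supported by the trio
#' genotypes: `de_novo` (child carries an alternate allele absent in both
#' parents), `homozygous` (child homozygous alternate, both parents
#' heterozygous carriers), `compound_het` (two or more heterozygous variants
#' in the same gene with opposite parental origin), `x_linked_recessive`
#' (X-chromosome variant, hemizygous alternate male child, carrier mother,
#' reference father), `dominant_inherited` (heterozygous variant carried by
#' a parent), or `unresolved` (affected-only family or missing genotypes).
#' Mendelian-inconsistent genotype combinations (e.g. a homozygous-alternate
#' child with a homozygous-reference parent) are flagged `mendel_error` and
#' excluded from pattern labels.
#'
#' Variants heterozygous in the child and in both parents are phase-unknown
#' from trio data alone and are not counted toward compound heterozygosity.
#' All X-chromosome variants in males are treated as hemizygous
#' (pseudoautosomal regions are not modelled).
#'
#' @param variants Tibble with at least CHROM, POS, GENE, GT_child,
#'   GT_mother, GT_father and family_id (as read by [read_variants()] or
#'   produced by [simulate_trio_cohort()]).
#' @param ped Pedigree tibble (family_id, individual_id, father_id,
#'   mother_id, sex, affected) used for the child's sex and to recognise
#'   affected-only families.
#' @return The input with `inheritance` and `mendel_error` columns added.
#' @export
detect_inheritance <- function(variants, ped) {
  child_rows <- ped |>
    filter(.data$affected == 2L) |>
    group_by(.data$family_id) |>
    slice(1) |>
    ungroup() |>
    transmute(family_id = .data$family_id, child_sex = .data$sex,
              has_trio = .data$father_id != "0" & .data$mother_id != "0")

  v <- variants |>
    left_join(child_rows, by = "family_id")
  if (anyNA(v$child_sex)) {
    abort("pedigree lacks an affected child for some family in `variants`")
  }

  cn <- gt_alt_count(v$GT_child)
  mn <- gt_alt_count(v$GT_mother)
  fn <- gt_alt_count(v$GT_father)
  on_x <- toupper(v$CHROM) %in% c("X", "CHRX")
  male <- v$child_sex == 1L
  hemi <- on_x & male

  n <- nrow(v)
  label <- rep("unresolved", n)
  mendel <- rep(FALSE, n)
  origin <- rep(NA_character_, n)  # parental origin for comp-het phasing

  complete <- v$has_trio & !is.na(cn) & !is.na(mn) & !is.na(fn)

  for (i in which(complete)) {
    if (hemi[i]) {
      # son's X is maternal; treat any alternate call as hemizygous
      if (cn[i] == 0) next
      if (mn[i] == 0) {
        label[i] <- "de_novo"
      } else if (mn[i] == 1 && fn[i] == 0) {
        label[i] <- "x_linked_recessive"
      } else {
        label[i] <- "dominant_inherited"
      }
      next
    }
    if (cn[i] == 0) next
    if (cn[i] == 1) {
      if (mn[i] == 0 && fn[i] == 0) {
        label[i] <- "de_novo"
      } else if (mn[i] == 2 && fn[i] == 2) {
        mendel[i] <- TRUE
      } else {
        label[i] <- "dominant_inherited"
        if (mn[i] >= 1 && fn[i] == 0) origin[i] <- "mother"
        if (fn[i] >= 1 && mn[i] == 0) origin[i] <- "father"
      }
    } else {  # child homozygous alternate
      if (mn[i] == 0 || fn[i] == 0) {
        mendel[i] <- TRUE
      } else if (mn[i] == 1 && fn[i] == 1) {
        label[i] <- "homozygous"
      } else {
        label[i] <- "dominant_inherited"
      }
    }
  }
  label[mendel] <- "unresolved"

  # compound heterozygosity: within a family and gene, heterozygous variants
  # with at least one maternal-only and one paternal-only origin
  key <- paste(v$family_id, v$GENE, sep = "\r")
  for (k in unique(key[!is.na(origin)])) {
    idx <- which(key == k & !is.na(origin))
    if (any(origin[idx] == "mother") && any(origin[idx] == "father")) {
      label[idx] <- "compound_het"
    }
  }

  variants$inheritance <- label
  variants$mendel_error <- mendel
  variants
}

#' Default variant classification rules
#'
#' A frequency-dominant, ACMG-like rule table for the five-class scheme
#' (I benign, II likely benign, III VUS, IV likely pathogenic, V
#' pathogenic): variants at or above `benign_af` are class I; variants in
#' `[likely_benign_af, benign_af)` that are not loss-of-function are class
#' II; rare loss-of-function variants (nonsense, frameshift, canonical
#' splice) with a de novo or recessive-fitting inheritance pattern are class
#' V; rare loss-of-function otherwise, or de novo missense/in-frame, are
#' class IV; everything else is class III. Every threshold is configurable,
#' and a YAML rule file ([read_rules()]) can replace the defaults.
#'
#' @param benign_af Class-I allele-frequency threshold (default 0.01).
#' @param likely_benign_af Class-II lower threshold (default 0.001).
#' @param lof_consequences Consequences treated as loss-of-function.
#' @return A `classification_rules` list.
#' @export
default_rules <- function(benign_af = 0.01, likely_benign_af = 0.001,
                          lof_consequences = c("nonsense", "frameshift", "splice")) {
  structure(list(benign_af = benign_af,
                 likely_benign_af = likely_benign_af,
                 lof_consequences = lof_consequences),
            class = "classification_rules")
}

#' Classify variants on the five-class scale
#'
#' Applies a [default_rules()]-style rule table to allele frequency,
#' consequence and inheritance pattern. Missing allele frequencies are
#' treated as 0 (absence from population controls is the strongest rarity
#' signal). An unknown consequence string yields class III with a warning.
#' If the input carries a logical `structural_override` column, variants of
#' class III with the flag set are raised to class IV (the only move a
#' structural reclassification may make) and annotated.
#'
#' @param variants Output of [detect_inheritance()] (needs CSQ, AF,
#'   inheritance).
#' @param rules A rule table from [default_rules()] or [read_rules()].
#' @return Input with `variant_class` (integer 1-5) and, when overrides are
#'   applied, `override_applied` columns.
#' @export
classify_variants <- function(variants, rules = default_rules()) {
  stopifnot(inherits(rules, "classification_rules"))
  known_csq <- c("missense", "nonsense", "frameshift", "splice",
                 "inframe_indel", "synonymous", "other")
  csq <- tolower(variants$CSQ)
  if (any(!csq %in% known_csq)) {
    warn(sprintf("unknown consequence value(s) %s treated as class III",
                 paste(unique(csq[!csq %in% known_csq]), collapse = ", ")))
  }
  af <- variants$AF
  af[is.na(af)] <- 0
  if (any(af < 0 | af > 1)) abort("AF must lie in [0, 1] or be missing")
  lof <- csq %in% rules$lof_consequences
  inh <- variants$inheritance
  pattern_fit <- inh %in% c("de_novo", "homozygous", "compound_het",
                            "x_linked_recessive")

  cls <- rep(3L, nrow(variants))
  cls[lof & pattern_fit] <- 5L
  cls[(lof & !pattern_fit) | (csq %in% c("missense", "inframe_indel") & inh == "de_novo")] <- 4L
  cls[af >= rules$likely_benign_af & af < rules$benign_af & !lof] <- 2L
  cls[af >= rules$benign_af] <- 1L
  cls[!csq %in% known_csq] <- 3L

  variants$variant_class <- cls
  if ("structural_override" %in% names(variants)) {
    raise <- isTRUE_vec(variants$structural_override) & cls == 3L
    variants$variant_class[raise] <- 4L
    variants$override_applied <- raise
  }
  variants
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Drop benign and likely benign variants
#'
#' Keeps exactly the variants of class III and above (VUS, likely
#' pathogenic, pathogenic), preserving input order. Idempotent.
#'
#' @param classified Output of [classify_variants()].
#' @return The surviving rows.
#' @export
exclude_benign <- function(classified) {
  if (!"variant_class" %in% names(classified)) {
    abort("`classified` must carry a `variant_class` column")
  }
  n0 <- nrow(classified)
  out <- classified[classified$variant_class >= 3L, , drop = FALSE]
  inform(sprintf("exclude_benign: %d variants in, %d retained (class >= III)",
                 n0, nrow(out)))
  out
}

#' Screen affected-only exomes against candidate genes
#'
#' For individuals sequenced without parents, inheritance cannot be resolved
#' directly; instead, variants in listed candidate genes are screened for
#' zygosity compatible with the gene's expected mode of inheritance:
#' `mono_allelic` (one heterozygous or homozygous variant suffices),
#' `bi_allelic` (a homozygous variant, or at least two heterozygous variants
#' in the gene), or `hemizygous` (hemizygous alternate on X in a male).
#'
#' @param variants Classified variants from affected-only families (parental
#'   genotypes missing).
#' @param gene_modes Tibble with `gene` and `mode` (one of "mono_allelic",
#'   "bi_allelic", "hemizygous") giving the zygosity expected per candidate
#'   gene. Variants in genes absent from this table are skipped with a
#'   warning.
#' @param ped Pedigree tibble, used for child sex on X.
#' @return The compatible variants.
#' @export
screen_affected_only <- function(variants, gene_modes, ped = NULL) {
  gene_modes <- gene_modes |> mutate(gene = toupper(.data$gene))
  v <- variants |> mutate(.row = dplyr::row_number())
  missing_genes <- setdiff(unique(toupper(v$GENE)), gene_modes$gene)
  if (length(missing_genes) > 0) {
    warn(sprintf("screened genes without expected-mode annotation skipped: %s",
                 paste(sort(missing_genes), collapse = ", ")))
  }
  sex_map <- NULL
  if (!is.null(ped)) {
    sex_map <- ped |> filter(.data$affected == 2L) |>
      distinct(.data$family_id, .keep_all = TRUE) |>
      select("family_id", child_sex = "sex")
  }
  v <- v |>
    mutate(GENE = toupper(.data$GENE)) |>
    inner_join(gene_modes, by = c(GENE = "gene"))
  if (!is.null(sex_map)) v <- v |> left_join(sex_map, by = "family_id")
  else v$child_sex <- NA_integer_

  v <- v |>
    mutate(alt_n = gt_alt_count(.data$GT_child),
           hemi = toupper(.data$CHROM) %in% c("X", "CHRX") &
             (.data$child_sex %in% 1L | gt_ploidy(.data$GT_child) == 1))
  keep <- v |>
    group_by(.data$family_id, .data$GENE) |>
    mutate(n_het = sum(.data$alt_n == 1, na.rm = TRUE),
           compatible = case_when(
             mode == "mono_allelic" ~ alt_n >= 1,
             mode == "bi_allelic" ~ (alt_n == 2 & !hemi) |
               (alt_n >= 1 & n_het >= 2),
             mode == "hemizygous" ~ hemi & alt_n >= 1,
             TRUE ~ FALSE
           )) |>
    ungroup() |>
    filter(.data$compatible)
  variants[sort(keep$.row), , drop = FALSE]
}
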