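#' Simulation configuration for synthetic short-stature cohorts
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults reproduce the composition of the study cohort the package
#' models: 254 families of which 69 lack parental exomes (affected-only),
#' an inheritance mix dominated by de novo dominant variants (71%), with
#' X-linked recessive (17%) and autosomal recessive (11%, split between
#' homozygous and compound heterozygous), and a consequence spectrum of
#' 78% missense, 15% nonsense, 6% splice and 1% in-frame indel.
#'
#' @param n_families Number of families to simulate.
#' @param affected_only_fraction Fraction of families without parental
#'   genotypes (default 69/254, the cohort's affected-only share).
#' @param n_genes Size of the gene universe.
#' @param n_background_variants Non-causal variants added per family; these
#'   carry common allele frequencies so the benign-exclusion rules are
#'   exercised.
#' @param inheritance_mix Named proportions over
#'   `de_novo`, `comp_het`, `homozygous`, `x_linked`; must sum to 1.
#' @param consequence_mix Named proportions over
#'   `missense`, `nonsense`, `splice`, `inframe_indel`; must sum to 1.
#' @param rare_af_range,common_af_range Allele-frequency intervals for
#'   planted causal (rare) and background (common) variants. The rare upper
#'   bound must sit below the common lower bound.
#' @param evidence_flag_prob Per-category Bernoulli probability for the 8
#'   gene-level evidence flags; scalar or named length-8 vector.
#' @param n_terms Total number of annotation terms in a simulated corpus.
#' @param planted_cluster_blocks List of `c(n_terms_in_block,
#'   n_shared_genes)` pairs describing correlated term blocks planted in the
#'   annotation corpus.
#' @param term_size Number of genes per annotation term.
#' @param growth_list_size Size of the simulated known-growth-gene list.
#' @param growth_core_inclusion Probability that a planted block core gene
#'   is included in the growth-gene list; drives the planted enrichment.
#' @param annotation_noise Probability that a block core gene is dropped
#'   from an individual term and replaced by a random gene.
#' @param seed Root random seed; per-stage streams are derived from it so
#'   cohort, corpus and evidence flags can be regenerated independently.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_families = 20, seed = 7)
#' cohort <- simulate_trio_cohort(cfg)
#' names(cohort)
sim_config <- function(n_families = 254,
                       affected_only_fraction = 69 / 254,
                       n_genes = 1000,
                       n_background_variants = 50,
                       inheritance_mix = c(de_novo = 0.71, comp_het = 0.06,
                                           homozygous = 0.06, x_linked = 0.17),
                       consequence_mix = c(missense = 0.78, nonsense = 0.15,
                                           splice = 0.06, inframe_indel = 0.01),
                       rare_af_range = c(0, 5e-4),
                       common_af_range = c(0.01, 0.2),
                       evidence_flag_prob = 0.1,
                       n_terms = 60,
                       planted_cluster_blocks = list(c(6, 12), c(6, 12), c(6, 12)),
                       term_size = 18,
                       growth_list_size = 100,
                       growth_core_inclusion = 0.8,
                       annotation_noise = 0,
                       seed = 1L) {
  check_proportions <- function(p, field, expected) {
    if (!setequal(names(p), expected)) {
      abort(sprintf("`%s` must be named over {%s}", field,
                    paste(expected, collapse = ", ")))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("`%s` must be non-negative proportions summing to 1", field))
    }
    p[expected]
  }
  if (n_families < 1) abort("`n_families` must be at least 1")
  inheritance_mix <- check_proportions(
    inheritance_mix, "inheritance_mix",
    c("de_novo", "comp_het", "homozygous", "x_linked"))
  consequence_mix <- check_proportions(
    consequence_mix, "consequence_mix",
    c("missense", "nonsense", "splice", "inframe_indel"))
  if (rare_af_range[2] >= common_af_range[1]) {
    abort("`rare_af_range` upper bound must be below `common_af_range` lower bound")
  }
  if (any(evidence_flag_prob < 0) || any(evidence_flag_prob > 1)) {
    abort("`evidence_flag_prob` must lie in [0, 1]")
  }
  for (blk in planted_cluster_blocks) {
    if (length(blk) != 2 || blk[1] < 1 || blk[2] < 1) {
      abort("`planted_cluster_blocks` entries must be c(n_terms, n_shared_genes)")
    }
    if (blk[2] > n_genes) {
      abort("`planted_cluster_blocks`: shared-gene count exceeds `n_genes`")
    }
    if (blk[2] > term_size) {
      abort("`planted_cluster_blocks`: shared-gene count exceeds `term_size`")
    }
  }
  if (sum(vapply(planted_cluster_blocks, `[`, numeric(1), 1)) > n_terms) {
    abort("`planted_cluster_blocks` hold more terms than `n_terms`")
  }
  if (annotation_noise < 0 || annotation_noise > 1) {
    abort("`annotation_noise` must lie in [0, 1]")
  }
  structure(list(
    n_families = as.integer(n_families),
    affected_only_fraction = affected_only_fraction,
    n_genes = as.integer(n_genes),
    n_background_variants = as.integer(n_background_variants),
    inheritance_mix = inheritance_mix,
    consequence_mix = consequence_mix,
    rare_af_range = rare_af_range,
    common_af_range = common_af_range,
    evidence_flag_prob = evidence_flag_prob,
    n_terms = as.integer(n_terms),
    planted_cluster_blocks = planted_cluster_blocks,
    term_size = as.integer(term_size),
    growth_list_size = as.integer(growth_list_size),
    growth_core_inclusion = growth_core_inclusion,
    annotation_noise = annotation_noise,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_genes <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  # roughly 5% of genes placed on X so X-linked families have targets
  n_x <- max(2L, as.integer(round(config$n_genes * 0.05)))
  chrom <- c(rep("X", n_x),
             as.character(rep_len(1:22, config$n_genes - n_x)))
  tibble(gene = genes, chrom = chrom)
}

rand_af <- function(n, range) runif(n, range[1], range[2])

#' Simulate a trio / affected-only exome cohort with planted inheritance
#'
#' Generates one causal variant (two for compound heterozygous families) per
#' family whose trio genotypes follow the family's assigned inheritance
#' mode, plus a configurable number of common-frequency background variants
#' with Mendelian-consistent inherited genotypes. Affected-only families
#' carry missing parental genotypes and single-member pedigree rows.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `variants` (VCF-like: CHROM, POS, REF, ALT,
#'   GENE, CSQ, AF, GT_child, GT_mother, GT_father, family_id), `pedigree`
#'   (PED columns) and `truth` (planted mode, gene and intended variant
#'   class per family).
#' @export
simulate_trio_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  gene_map <- sim_genes(config)
  autosomal <- gene_map$gene[gene_map$chrom != "X"]
  x_genes <- gene_map$gene[gene_map$chrom == "X"]
  modes <- names(config$inheritance_mix)
  bases <- c("A", "C", "G", "T")

  fam_ids <- sprintf("FAM%04d", seq_len(config$n_families))
  fam_mode <- sample(modes, config$n_families, replace = TRUE,
                     prob = config$inheritance_mix)
  fam_affected_only <- runif(config$n_families) < config$affected_only_fraction
  fam_sex <- ifelse(fam_mode == "x_linked", 1L,
                    sample(1:2, config$n_families, replace = TRUE))

  variants <- vector("list", config$n_families)
  ped <- vector("list", config$n_families)
  truth <- vector("list", config$n_families)

  # intended class under the frequency-dominant rule defaults: rare
  # loss-of-function with a de novo or recessive-fitting pattern is class V,
  # rare missense/in-frame de novo is IV, inherited missense/in-frame is III
  intended_class <- function(csq, mode) {
    lof <- csq %in% c("nonsense", "splice", "frameshift")
    if (lof) return(5L)
    if (mode == "de_novo") return(4L)
    3L
  }

  for (i in seq_len(config$n_families)) {
    fam <- fam_ids[i]
    mode <- fam_mode[i]
    sex <- fam_sex[i]
    aff_only <- fam_affected_only[i]
    gene <- if (mode == "x_linked") sample(x_genes, 1) else sample(autosomal, 1)
    chrom <- gene_map$chrom[match(gene, gene_map$gene)]
    n_causal <- if (mode == "comp_het") 2L else 1L
    csq <- sample(names(config$consequence_mix), n_causal, replace = TRUE,
                  prob = config$consequence_mix)

    gt <- switch(mode,
      de_novo    = list(c("0/1"), c("0/0"), c("0/0")),
      homozygous = list(c("1/1"), c("0/1"), c("0/1")),
      comp_het   = list(c("0/1", "0/1"), c("0/1", "0/0"), c("0/0", "0/1")),
      x_linked   = list(c("1"), c("0/1"), c("0"))
    )
    ref <- sample(bases, n_causal, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    causal <- tibble(
      CHROM = chrom,
      POS = sort(sample.int(2e8, n_causal)),
      REF = ref, ALT = alt, GENE = gene, CSQ = csq,
      AF = rand_af(n_causal, config$rare_af_range),
      GT_child = gt[[1]],
      GT_mother = if (aff_only) rep(".", n_causal) else gt[[2]],
      GT_father = if (aff_only) rep(".", n_causal) else gt[[3]],
      family_id = fam
    )

    nb <- config$n_background_variants
    bg <- NULL
    if (nb > 0) {
      bg_gene <- sample(autosomal, nb, replace = TRUE)
      from_mother <- runif(nb) < 0.5
      bg_ref <- sample(bases, nb, replace = TRUE)
      bg <- tibble(
        CHROM = gene_map$chrom[match(bg_gene, gene_map$gene)],
        POS = sample.int(2e8, nb),
        REF = bg_ref,
        ALT = vapply(bg_ref, function(r) sample(setdiff(bases, r), 1), character(1)),
        GENE = bg_gene,
        CSQ = sample(c(names(config$consequence_mix), "synonymous"), nb,
                     replace = TRUE, prob = c(config$consequence_mix, 1) / 2),
        AF = rand_af(nb, config$common_af_range),
        GT_child = "0/1",
        GT_mother = if (aff_only) "." else ifelse(from_mother, "0/1", "0/0"),
        GT_father = if (aff_only) "." else ifelse(from_mother, "0/0", "0/1"),
        family_id = fam
      )
    }
    variants[[i]] <- bind_rows(causal, bg)

    child <- paste0(fam, "_C")
    if (aff_only) {
      ped[[i]] <- tibble(family_id = fam, individual_id = child,
                         father_id = "0", mother_id = "0",
                         sex = sex, affected = 2L)
    } else {
      ped[[i]] <- tibble(
        family_id = fam,
        individual_id = c(child, paste0(fam, "_M"), paste0(fam, "_F")),
        father_id = c(paste0(fam, "_F"), "0", "0"),
        mother_id = c(paste0(fam, "_M"), "0", "0"),
        sex = c(sex, 2L, 1L),
        affected = c(2L, 1L, 1L)
      )
    }
    truth[[i]] <- tibble(
      family_id = fam, gene = gene, mode = mode,
      affected_only = aff_only,
      n_causal_variants = n_causal,
      consequence = paste(csq, collapse = ","),
      expected_class = max(vapply(csq, intended_class, integer(1), mode = mode))
    )
  }

  list(variants = bind_rows(variants),
       pedigree = bind_rows(ped),
       truth = bind_rows(truth))
}

#' Simulate an annotation corpus with planted correlated term blocks
#'
#' Builds a GMT-style term-by-gene corpus in which configurable blocks of
#' terms share a common core gene set (giving high within-block Cohen's
#' kappa), the remaining terms are random gene sets, and a growth-gene list
#' is enriched for block core genes so planted terms are recoverable by
#' enrichment analysis.
#'
#' @param config A [sim_config()].
#' @return A list with `terms` (tibble: term, description, genes list-column,
#'   source), `growth_genes` (character), `universe` (character) and `truth`
#'   (tibble: term, block; `NA` block for null terms).
#' @export
simulate_annotation_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  universe <- sprintf("G%04d", seq_len(config$n_genes))
  blocks <- config$planted_cluster_blocks
  n_block_terms <- sum(vapply(blocks, `[`, numeric(1), 1))

  core_pool <- sample(universe)
  cores <- list(); used <- 0
  for (k in seq_along(blocks)) {
    n_shared <- blocks[[k]][2]
    cores[[k]] <- core_pool[(used + 1):(used + n_shared)]
    used <- used + n_shared
  }
  core_all <- unlist(cores)
  non_core <- setdiff(universe, core_all)

  in_list <- core_all[runif(length(core_all)) < config$growth_core_inclusion]
  filler <- sample(non_core, max(0, config$growth_list_size - length(in_list)))
  growth_genes <- sort(c(in_list, filler)[seq_len(
    min(config$growth_list_size, length(in_list) + length(filler)))])

  make_term <- function(core) {
    keep <- core[runif(length(core)) >= config$annotation_noise]
    extra <- sample(non_core, config$term_size - length(keep))
    sort(c(keep, extra))
  }
  terms <- list(); truth <- list(); idx <- 0
  for (k in seq_along(blocks)) {
    for (j in seq_len(blocks[[k]][1])) {
      idx <- idx + 1
      id <- sprintf("BLK%d_T%02d", k, j)
      terms[[idx]] <- tibble(term = id,
                             description = sprintf("planted block %d term %d", k, j),
                             genes = list(make_term(cores[[k]])),
                             source = "SIM")
      truth[[idx]] <- tibble(term = id, block = k)
    }
  }
  for (j in seq_len(config$n_terms - n_block_terms)) {
    idx <- idx + 1
    id <- sprintf("NULL_T%03d", j)
    terms[[idx]] <- tibble(term = id, description = "null term",
                           genes = list(sort(sample(universe, config$term_size))),
                           source = "SIM")
    truth[[idx]] <- tibble(term = id, block = NA_integer_)
  }

  list(terms = bind_rows(terms), growth_genes = growth_genes,
       universe = universe, truth = bind_rows(truth))
}

#' The 8 gene-level evidence categories
#'
#' Association studies, copy-number variants, growth-related GO terms,
#' protein-protein interaction with a growth gene, mouse model, zebrafish
#' model, a prior exome study, and expression in chondrocytes.
#'
#' @return Character vector of 8 category names.
#' @export
evidence_categories <- function() {
  c("association_study", "copy_number_variant", "go_growth_term",
    "ppi_growth_gene", "mouse_model", "zebrafish_model",
    "prior_exome_study", "chondrocyte_expression")
}

#' Simulate per-gene evidence flags
#'
#' Draws independent Bernoulli flags for each of the 8 gene-level evidence
#' categories.
#'
#' @param config A [sim_config()]; `evidence_flag_prob` may be a scalar or a
#'   named length-8 vector of per-category probabilities.
#' @param genes Character vector of gene symbols (one output row each).
#' @return Tibble with `gene` and 8 logical columns.
#' @export
simulate_evidence_flags <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  cats <- evidence_categories()
  prob <- config$evidence_flag_prob
  if (length(prob) == 1) prob <- setNames(rep(prob, 8), cats)
  if (!setequal(names(prob), cats)) {
    abort("`evidence_flag_prob` must be scalar or named over the 8 categories")
  }
  out <- tibble(gene = toupper(genes))
  for (cat in cats) {
    out[[cat]] <- runif(length(genes)) < prob[[cat]]
  }
  out
}
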