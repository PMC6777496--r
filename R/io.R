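#' Read a GMT gene-set file
#'
#' One term per line: term name, description, then tab-separated genes.
#' Duplicate genes within a term are deduplicated with a warning; a line
#' without any gene is an error.
#'
#' @param path Path to a GMT file.
#' @return Tibble: term, description, genes (list-column of unique
#'   upper-cased symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !nzchar(f[1])) {
      abort(sprintf("malformed GMT line %d: need term, description and >= 1 gene", i))
    }
    genes <- toupper(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(sprintf("malformed GMT line %d: empty gene set", i))
    }
    if (anyDuplicated(genes)) {
      warn(sprintf("GMT line %d (%s): duplicate genes deduplicated", i, f[1]))
      genes <- unique(genes)
    }
    out[[i]] <- tibble(term = f[1], description = f[2], genes = list(genes))
  }
  bind_rows(out)
}

#' Write a GMT gene-set file
#' @param terms Tibble with term, description, genes list-column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term[i], terms$description[i] %||% "", terms$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

variant_cols <- c("CHROM", "POS", "REF", "ALT", "GENE", "CSQ", "AF",
                  "GT_child", "GT_mother", "GT_father", "family_id")

#' Read a VCF-like tab-separated variant table
#'
#' Expects the columns CHROM, POS (1-based), REF, ALT, GENE, CSQ, AF,
#' GT_child, GT_mother, GT_father, family_id. Positions must be positive
#' integers, AF in \[0, 1\] or missing, and genotypes must match the grammar
#' `a/b`, `a|b` or hemizygous `a` with alleles 0, 1 or `.`; violations are
#' reported with their row number. Gene symbols are upper-cased on ingest.
#'
#' @param path Path to the TSV.
#' @return A typed tibble.
#' @export
read_variants <- function(path) {
  v <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    CHROM = readr::col_character(), POS = readr::col_double(),
    REF = readr::col_character(), ALT = readr::col_character(),
    GENE = readr::col_character(), CSQ = readr::col_character(),
    AF = readr::col_double(), GT_child = readr::col_character(),
    GT_mother = readr::col_character(), GT_father = readr::col_character(),
    family_id = readr::col_character()), progress = FALSE))
  missing <- setdiff(variant_cols, names(v))
  if (length(missing) > 0) {
    abort(sprintf("variant table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad_pos <- which(is.na(v$POS) | v$POS < 1 | v$POS != floor(v$POS))
  if (length(bad_pos) > 0) {
    abort(sprintf("invalid 1-based position at row %d", bad_pos[1]))
  }
  bad_af <- which(!is.na(v$AF) & (v$AF < 0 | v$AF > 1))
  if (length(bad_af) > 0) {
    abort(sprintf("allele frequency outside [0, 1] at row %d", bad_af[1]))
  }
  for (col in c("GT_child", "GT_mother", "GT_father")) {
    bad <- which(is.na(v[[col]]) | !gt_valid(v[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("bad genotype string in %s at row %d", col, bad[1]))
    }
  }
  v$POS <- as.integer(v$POS)
  v$GENE <- toupper(v$GENE)
  v
}

#' Write a variant table
#' @param variants Tibble of variants.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Read a PED pedigree file
#'
#' Tab-separated with header: family_id, individual_id, father_id,
#' mother_id, sex (1 male / 2 female / 0 unknown), affected (2 affected /
#' 1 unaffected / 0 unknown). A parent id of "0" marks a missing parent;
#' trio analyses are disabled for such families.
#'
#' @param path Path to the PED file.
#' @return A typed tibble.
#' @export
read_ped <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    family_id = readr::col_character(), individual_id = readr::col_character(),
    father_id = readr::col_character(), mother_id = readr::col_character(),
    sex = readr::col_integer(), affected = readr::col_integer()),
    progress = FALSE)
  bad <- which(!p$sex %in% 0:2 | !p$affected %in% 0:2)
  if (length(bad) > 0) {
    abort(sprintf("invalid PED sex/affected code at row %d", bad[1]))
  }
  p
}

#' Write a PED pedigree file
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path) {
  readr::write_tsv(ped, path)
  invisible(path)
}

#' Read a gene-level evidence flag table
#'
#' Tab-separated with a `gene` column and the 8 evidence-category columns;
#' parsed and validated by [build_evidence_profiles()].
#'
#' @param path Path to the TSV.
#' @return Evidence profile tibble with `category_count`.
#' @export
read_evidence <- function(path) {
  build_evidence_profiles(readr::read_tsv(path, col_types = readr::cols(),
                                          progress = FALSE))
}

#' Read / write a plain gene list (one symbol per line)
#' @param path File path.
#' @return Character vector of unique upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  x <- toupper(trimws(readLines(path, warn = FALSE)))
  unique(x[nzchar(x)])
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a classification rule table from YAML
#'
#' Recognised keys: `benign_af`, `likely_benign_af`, `lof_consequences`;
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `classification_rules` list.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("benign_af", "likely_benign_af", "lof_consequences")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown rule key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(default_rules, y)
}

#' Read and validate a pipeline configuration
#'
#' YAML with file paths (`variants`, `ped`, `evidence`, `gmt`,
#' `growth_genes`, `background`), optional `rules` (path or inline),
#' optional `clustering` (inline [clustering_params()] fields), `alpha` and
#' `seed`. Every referenced file must exist; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated named list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("variants", "ped", "evidence", "gmt", "growth_genes",
             "background", "rules", "clustering", "alpha", "seed", "outdir")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in c("variants", "ped", "evidence", "gmt", "growth_genes",
                "background")) {
    if (!is.null(y[[key]]) && !file.exists(y[[key]])) {
      abort(sprintf("config file for `%s` does not exist: %s", key, y[[key]]))
    }
  }
  y$alpha <- y$alpha %||% 0.05
  y$seed <- y$seed %||% 1L
  y
}

#' Run the full candidate-gene discovery pipeline
#'
#' Chains every stage: inheritance detection, classification,
#' benign exclusion, per-gene scoring and tiering; enrichment of the
#' growth-gene list over the annotation corpus, kappa clustering with FDR
#' pruning; candidate-to-cluster mapping; cohort summary; and, when
#' `outdir` is given, the written report bundle. Each filtering stage logs
#' one line with records in/out.
#'
#' @param variants Variant tibble (or path, read via [read_variants()]).
#' @param ped Pedigree tibble (or path).
#' @param evidence Evidence profile tibble (or path).
#' @param terms Annotation term tibble (or GMT path).
#' @param growth_genes Character vector (or path) of known growth genes.
#' @param background Character vector (or path): gene universe.
#' @param rules Classification rules ([default_rules()] default).
#' @param params Clustering parameters ([clustering_params()] default).
#' @param alpha FDR threshold for enrichment and pruning.
#' @param outdir Optional report output directory.
#' @return List: classified, candidates (tiered), enrichment, clusters,
#'   mapping, summary, and report paths when written.
#' @export
run_pipeline <- function(variants, ped, evidence, terms, growth_genes,
                         background, rules = default_rules(),
                         params = clustering_params(), alpha = 0.05,
                         outdir = NULL) {
  if (is.character(variants)) variants <- read_variants(variants)
  if (is.character(ped)) ped <- read_ped(ped)
  if (is.character(evidence)) evidence <- read_evidence(evidence)
  if (is.character(terms)) terms <- read_gmt(terms)
  if (is.character(growth_genes) && length(growth_genes) == 1 &&
      file.exists(growth_genes)) growth_genes <- read_gene_list(growth_genes)
  if (is.character(background) && length(background) == 1 &&
      file.exists(background)) background <- read_gene_list(background)

  profiles <- build_evidence_profiles(evidence)
  classified <- variants |>
    detect_inheritance(ped) |>
    classify_variants(rules)
  surviving <- exclude_benign(classified)
  candidates <- surviving |>
    score_candidates(profiles) |>
    tier_genes()
  inform(sprintf("tiering: %d candidate genes (%d high, %d medium)",
                 nrow(candidates), sum(candidates$tier == "high"),
                 sum(candidates$tier == "medium")))

  enr <- term_enrichment(growth_genes, terms, background)
  clusters <- cluster_terms(terms, background, params) |>
    prune_and_summarize(enr, terms, alpha = alpha, params = params)
  inform(sprintf("clustering: %d terms -> %d clusters after FDR pruning",
                 nrow(terms), nrow(clusters)))

  cand_genes <- candidates$gene[candidates$tier != "rejected"]
  mapping <- if (nrow(clusters) > 0 && length(cand_genes) > 0) {
    map_candidates(clusters, cand_genes)
  } else NULL
  summary <- summarize_cohort(candidates,
                              n_families_total = dplyr::n_distinct(ped$family_id),
                              variants = surviving)
  report <- NULL
  if (!is.null(outdir)) {
    report <- build_report(candidates, mapping, clusters, summary, outdir)
  }
  list(classified = classified, surviving = surviving,
       candidates = candidates, enrichment = enr, clusters = clusters,
       mapping = mapping, summary = summary, report = report)
}
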