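# Independent oracles used to check the package's computations.
# These recompute quantities from first principles (combinatorial sums,
# scalar formulas, exhaustive enumeration) and never call the code paths
# they check.

# upper hypergeometric tail P(X >= a) by explicit combinatorial summation:
# X = list genes with the term, margins: A list genes, B non-list genes,
# n = a + b genes carrying the term
oracle_hyper_tail <- function(a, A, b, B) {
  n <- a + b
  ks <- max(a, 0):min(A, n)
  if (length(ks) == 0 || a > min(A, n)) return(0)
  sum(exp(lchoose(A, ks) + lchoose(B, n - ks) - lchoose(A + B, n)))
}

# Cohen's kappa from the 2x2 agreement table, scalar arithmetic
oracle_kappa <- function(a, b, c, d) {
  t <- a + b + c + d
  po <- (a + d) / t
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / t^2
  (po - pe) / (1 - pe)
}

# Benjamini-Hochberg step-up applied literally: sort, adj(i) = min over
# k >= i of m * p(k) / k, capped at 1, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# trio inheritance rules restated directly from their definitions, for a
# single variant (compound het needs >= 2 variants and is handled by
# dedicated tests)
oracle_inheritance <- function(child, mother, father, on_x = FALSE,
                               male = FALSE) {
  alts <- function(gt) {
    a <- strsplit(gt, "/", fixed = TRUE)[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }
  cn <- alts(child); mn <- alts(mother); fn <- alts(father)
  if (is.na(cn) || is.na(mn) || is.na(fn)) {
    return(list(label = "unresolved", mendel = FALSE))
  }
  if (on_x && male) {
    if (cn == 0) return(list(label = "unresolved", mendel = FALSE))
    if (mn == 0) return(list(label = "de_novo", mendel = FALSE))
    if (mn == 1 && fn == 0) return(list(label = "x_linked_recessive", mendel = FALSE))
    return(list(label = "dominant_inherited", mendel = FALSE))
  }
  if (cn == 0) return(list(label = "unresolved", mendel = FALSE))
  if (cn == 1) {
    if (mn == 0 && fn == 0) return(list(label = "de_novo", mendel = FALSE))
    if (mn == 2 && fn == 2) return(list(label = "unresolved", mendel = TRUE))
    return(list(label = "dominant_inherited", mendel = FALSE))
  }
  # child homozygous alternate
  if (mn == 0 || fn == 0) return(list(label = "unresolved", mendel = TRUE))
  if (mn == 1 && fn == 1) return(list(label = "homozygous", mendel = FALSE))
  list(label = "dominant_inherited", mendel = FALSE)
}

# exhaustive merge oracle: explores every order of qualifying merges and
# returns the set of distinct terminal partitions (as canonical strings)
oracle_all_merge_orders <- function(groups, linkage) {
  canon <- function(gs) {
    paste(sort(vapply(gs, function(g) paste(sort(g), collapse = ","),
                      character(1))), collapse = ";")
  }
  seen <- new.env(parent = emptyenv())
  terminals <- new.env(parent = emptyenv())
  recurse <- function(gs) {
    key <- canon(gs)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    n <- length(gs)
    any_merge <- FALSE
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          share <- length(intersect(gs[[i]], gs[[j]])) /
            min(length(gs[[i]]), length(gs[[j]]))
          if (share >= linkage) {
            any_merge <- TRUE
            merged <- unique(c(gs[-c(i, j)], list(sort(union(gs[[i]], gs[[j]])))))
            recurse(merged)
          }
        }
      }
    }
    if (!any_merge) terminals[[canon(gs)]] <- TRUE
    invisible()
  }
  recurse(lapply(groups, function(g) sort(unique(g))))
  ls(terminals)
}

# single-variant trio rows for inheritance tests
trio_variant_row <- function(gt_c, gt_m, gt_f, chrom = "1", gene = "G1",
                             fam = "F1", pos = 100, af = 1e-4,
                             csq = "missense") {
  tibble::tibble(CHROM = chrom, POS = pos, REF = "A", ALT = "G", GENE = gene,
                 CSQ = csq, AF = af, GT_child = gt_c, GT_mother = gt_m,
                 GT_father = gt_f, family_id = fam)
}

trio_ped <- function(fam = "F1", sex = 2L) {
  tibble::tibble(
    family_id = fam,
    individual_id = paste0(fam, c("_C", "_M", "_F")),
    father_id = c(paste0(fam, "_F"), "0", "0"),
    mother_id = c(paste0(fam, "_M"), "0", "0"),
    sex = c(sex, 2L, 1L),
    affected = c(2L, 1L, 1L))
}

# small deterministic term table builders
term_table <- function(...) term_table_from_list(list(...))

term_table_from_list <- function(sets) {
  tibble::tibble(term = names(sets),
                 description = names(sets),
                 genes = unname(sets))
}

# adjusted Rand index of recovered clusters against planted blocks,
# restricted to block terms; unclustered block terms become singletons
block_ari <- function(clusters, truth) {
  block_terms <- truth$term[!is.na(truth$block)]
  lab_rec <- rep(NA_character_, length(block_terms))
  for (i in seq_len(nrow(clusters))) {
    hit <- block_terms %in% clusters$member_terms[[i]]
    lab_rec[hit] <- clusters$cluster_id[i]
  }
  lab_rec[is.na(lab_rec)] <- paste0("solo_", seq_len(sum(is.na(lab_rec))))
  mclust::adjustedRandIndex(lab_rec, truth$block[!is.na(truth$block)])
}
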