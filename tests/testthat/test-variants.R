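gts <- c("0/0", "0/1", "1/1")

test_that("inheritance labels agree with the brute-force rule enumeration", {
  # all diploid trio combinations on an autosome and on X (female child)
  for (on_x in c(FALSE, TRUE)) {
    chrom <- if (on_x) "X" else "7"
    for (gc in gts) for (gm in gts) for (gf in gts) {
      v <- trio_variant_row(gc, gm, gf, chrom = chrom)
      got <- detect_inheritance(v, trio_ped(sex = 2L))
      want <- oracle_inheritance(gc, gm, gf, on_x = on_x, male = FALSE)
      expect_equal(got$inheritance, want$label,
                   info = sprintf("chrom %s child %s mother %s father %s",
                                  chrom, gc, gm, gf))
      expect_equal(got$mendel_error, want$mendel)
    }
  }
  # hemizygous male child on X
  for (gc in c("0", "1")) for (gm in gts) for (gf in c("0", "1")) {
    v <- trio_variant_row(gc, gm, gf, chrom = "X")
    got <- detect_inheritance(v, trio_ped(sex = 1L))
    want <- oracle_inheritance(gc, gm, gf, on_x = TRUE, male = TRUE)
    expect_equal(got$inheritance, want$label,
                 info = sprintf("X male child %s mother %s father %s", gc, gm, gf))
  }
})

test_that("compound heterozygosity requires opposite parental origin", {
  two <- dplyr::bind_rows(
    trio_variant_row("0/1", "0/1", "0/0", pos = 100),
    trio_variant_row("0/1", "0/0", "0/1", pos = 200))
  got <- detect_inheritance(two, trio_ped())
  expect_equal(got$inheritance, c("compound_het", "compound_het"))

  # same parental origin: plain dominant inheritance
  same <- dplyr::bind_rows(
    trio_variant_row("0/1", "0/1", "0/0", pos = 100),
    trio_variant_row("0/1", "0/1", "0/0", pos = 200))
  expect_equal(detect_inheritance(same, trio_ped())$inheritance,
               c("dominant_inherited", "dominant_inherited"))

  # both parents het: phase unknown from trio data, not counted
  phase_unknown <- dplyr::bind_rows(
    trio_variant_row("0/1", "0/1", "0/1", pos = 100),
    trio_variant_row("0/1", "0/0", "0/1", pos = 200))
  expect_false(any(detect_inheritance(phase_unknown, trio_ped())$inheritance ==
                     "compound_het"))

  # different genes never pair
  diff_gene <- dplyr::bind_rows(
    trio_variant_row("0/1", "0/1", "0/0", pos = 100, gene = "G1"),
    trio_variant_row("0/1", "0/0", "0/1", pos = 200, gene = "G2"))
  expect_false(any(detect_inheritance(diff_gene, trio_ped())$inheritance ==
                     "compound_het"))
})

test_that("affected-only families pass through unresolved", {
  v <- trio_variant_row("0/1", ".", ".")
  ped <- tibble::tibble(family_id = "F1", individual_id = "F1_C",
                        father_id = "0", mother_id = "0",
                        sex = 2L, affected = 2L)
  got <- detect_inheritance(v, ped)
  expect_equal(got$inheritance, "unresolved")
  expect_false(got$mendel_error)
})

test_that("classification follows the frequency-dominant rule table", {
  mk <- function(af, csq, inh) {
    v <- trio_variant_row("0/1", "0/0", "0/0", af = af, csq = csq)
    v$inheritance <- inh
    v
  }
  cls <- function(af, csq, inh) classify_variants(mk(af, csq, inh))$variant_class
  expect_equal(cls(0.05, "missense", "dominant_inherited"), 1L)   # common -> benign
  expect_equal(cls(0.005, "missense", "dominant_inherited"), 2L)
  expect_equal(cls(NA, "missense", "dominant_inherited"), 3L)     # absent from controls, no criteria fire
  expect_equal(cls(1e-5, "frameshift", "de_novo"), 5L)            # de novo premature stop
  expect_equal(cls(1e-5, "nonsense", "homozygous"), 5L)
  expect_equal(cls(1e-5, "nonsense", "dominant_inherited"), 4L)   # inherited LoF
  expect_equal(cls(1e-5, "missense", "de_novo"), 4L)
  expect_warning(out <- classify_variants(mk(1e-5, "weird_csq", "de_novo")),
                 "unknown consequence")
  expect_equal(out$variant_class, 3L)
})

test_that("class is monotone non-increasing in allele frequency", {
  af_grid <- c(0, 1e-5, 1e-4, 5e-4, 1e-3, 5e-3, 9e-3, 0.01, 0.05, 0.5, 1)
  csqs <- c("missense", "nonsense", "frameshift", "splice", "inframe_indel",
            "synonymous")
  inhs <- c("de_novo", "homozygous", "compound_het", "x_linked_recessive",
            "dominant_inherited", "unresolved")
  for (csq in csqs) for (inh in inhs) {
    v <- trio_variant_row("0/1", "0/0", "0/0")[rep(1, length(af_grid)), ]
    v$AF <- af_grid
    v$CSQ <- csq
    v$inheritance <- inh
    cls <- classify_variants(v)$variant_class
    expect_true(all(diff(cls) <= 0),
                info = sprintf("csq %s inh %s: %s", csq, inh,
                               paste(cls, collapse = ",")))
  }
})

test_that("structural override may only raise class III to IV", {
  v <- trio_variant_row("0/1", "0/0", "0/0", af = NA)[rep(1, 3), ]
  v$CSQ <- c("missense", "missense", "nonsense")
  v$inheritance <- c("dominant_inherited", "dominant_inherited", "de_novo")
  v$structural_override <- c(TRUE, FALSE, TRUE)
  out <- classify_variants(v)
  expect_equal(out$variant_class, c(4L, 3L, 5L))  # III->IV; untouched; V stays V
  expect_equal(out$override_applied, c(TRUE, FALSE, FALSE))
})

test_that("benign exclusion keeps exactly class >= III, in order, idempotently", {
  v <- trio_variant_row("0/1", "0/0", "0/0")[rep(1, 5), ]
  v$POS <- 1:5
  v$variant_class <- c(1L, 2L, 3L, 4L, 5L)
  out <- suppressMessages(exclude_benign(v))
  expect_equal(out$variant_class, c(3L, 4L, 5L))
  expect_equal(out$POS, 3:5)
  expect_identical(suppressMessages(exclude_benign(out)), out)
  empty <- v[0, ]
  expect_equal(nrow(suppressMessages(exclude_benign(empty))), 0)
})

test_that("survivor count matches planted truth on a simulated cohort", {
  cfg <- sim_config(n_families = 40, seed = 21)
  cohort <- simulate_trio_cohort(cfg)
  classified <- cohort$variants |>
    detect_inheritance(cohort$pedigree) |>
    classify_variants()
  surv <- suppressMessages(exclude_benign(classified))
  # background variants are common (class I/II); causal variants are rare
  causal <- classified |>
    dplyr::semi_join(cohort$truth, by = c("family_id", GENE = "gene")) |>
    dplyr::filter(AF <= cfg$rare_af_range[2])
  expect_equal(nrow(surv), nrow(causal))
  expect_true(all(surv$AF <= cfg$rare_af_range[2]))
})

test_that("planted causal variants pass the matching inheritance detector", {
  cfg <- sim_config(n_families = 120, affected_only_fraction = 0,
                    n_background_variants = 5, seed = 31)
  cohort <- simulate_trio_cohort(cfg)
  got <- detect_inheritance(cohort$variants, cohort$pedigree) |>
    dplyr::filter(AF <= cfg$rare_af_range[2]) |>
    dplyr::left_join(cohort$truth, by = c("family_id", GENE = "gene"))
  map_label <- c(de_novo = "de_novo", homozygous = "homozygous",
                 comp_het = "compound_het", x_linked = "x_linked_recessive")
  expect_true(all(got$inheritance == map_label[got$mode]))
})

test_that("affected-only screening honours the expected zygosity per gene", {
  ped1 <- tibble::tibble(family_id = "F1", individual_id = "F1_C",
                         father_id = "0", mother_id = "0", sex = 2L,
                         affected = 2L)
  modes <- tibble::tibble(gene = c("G1", "G2"),
                          mode = c("bi_allelic", "mono_allelic"))
  # single het in a bi-allelic gene: excluded
  v1 <- trio_variant_row("0/1", ".", ".", gene = "G1")
  expect_equal(nrow(screen_affected_only(v1, modes, ped1)), 0)
  # het in a mono-allelic gene: included
  v2 <- trio_variant_row("0/1", ".", ".", gene = "G2")
  expect_equal(nrow(screen_affected_only(v2, modes, ped1)), 1)
  # two hets in a bi-allelic gene: included
  v3 <- dplyr::bind_rows(
    trio_variant_row("0/1", ".", ".", gene = "G1", pos = 1),
    trio_variant_row("0/1", ".", ".", gene = "G1", pos = 2))
  expect_equal(nrow(screen_affected_only(v3, modes, ped1)), 2)
  # unknown gene skipped with warning
  v4 <- trio_variant_row("0/1", ".", ".", gene = "G9")
  expect_warning(out <- screen_affected_only(v4, modes, ped1), "G9")
  expect_equal(nrow(out), 0)
})

test_that("screening recovers all planted matches in an affected-only cohort", {
  cfg <- sim_config(n_families = 60, affected_only_fraction = 1,
                    n_background_variants = 0, seed = 41)
  cohort <- simulate_trio_cohort(cfg)
  zyg <- c(de_novo = "mono_allelic", homozygous = "bi_allelic",
           comp_het = "bi_allelic", x_linked = "hemizygous")
  modes <- cohort$truth |>
    dplyr::transmute(gene, mode = zyg[mode]) |>
    dplyr::distinct(gene, .keep_all = TRUE)
  hits <- screen_affected_only(cohort$variants, modes, cohort$pedigree)
  # recall 1: every causal variant screened under its true zygosity is found
  # (a gene planted under different modes in two families is screened under
  # one of them; only the matching families are owed a hit)
  expected <- cohort$variants |>
    dplyr::left_join(cohort$truth, by = c("family_id", GENE = "gene")) |>
    dplyr::left_join(modes, by = c(GENE = "gene")) |>
    dplyr::filter(zyg[mode.x] == mode.y)
  key <- function(d) paste(d$family_id, d$GENE, d$POS)
  expect_true(all(key(expected) %in% key(hits)))
  expect_gt(nrow(expected), 0)
})
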