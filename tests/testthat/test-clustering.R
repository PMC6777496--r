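universe <- sprintf("G%04d", 1:1000)

test_that("kappa matrix matches the scalar agreement-table oracle", {
  # a=10, b=5, c=5, d=980 over T=1000
  t2 <- term_table(TA = universe[1:15], TB = universe[6:20])
  K <- kappa_matrix(t2, universe)
  expect_equal(K["TA", "TB"], oracle_kappa(10, 5, 5, 980), tolerance = 1e-12)
  expect_equal(K["TA", "TA"], 1)
  expect_true(isSymmetric(K))

  # identical gene sets at or above the overlap gate -> kappa 1
  t1 <- term_table(T1 = universe[1:8], T2 = universe[1:8])
  expect_equal(kappa_matrix(t1, universe)["T1", "T2"], 1)

  # pairs sharing fewer than min_gene_overlap genes are gated to 0
  t3 <- term_table(T1 = universe[1:10], T2 = c(universe[1:3], universe[500:506]))
  expect_equal(kappa_matrix(t3, universe)["T1", "T2"], 0)
  expect_gt(kappa_matrix(t3, universe,
                         clustering_params(min_gene_overlap = 1))["T1", "T2"], 0)

  # random instances against the oracle
  set.seed(11)
  for (i in 1:25) {
    g1 <- sample(universe, sample(10:80, 1))
    g2 <- sample(universe, sample(10:80, 1))
    tt <- term_table(U = g1, V = g2)
    K <- kappa_matrix(tt, universe, clustering_params(min_gene_overlap = 0))
    a <- length(intersect(g1, g2))
    expect_equal(K["U", "V"],
                 oracle_kappa(a, length(g1) - a, length(g2) - a,
                              1000 - length(union(g1, g2))),
                 tolerance = 1e-12)
    expect_true(all(K >= -1 & K <= 1))
  }
})

test_that("degenerate constant annotations yield kappa 0 with a warning", {
  tt <- term_table(ALL1 = universe, ALL2 = universe)
  expect_warning(K <- kappa_matrix(tt, universe), "degenerate")
  expect_equal(K["ALL1", "ALL2"], 0)
})

test_that("seed formation enforces size and membership tightness", {
  ids <- sprintf("T%d", 1:6)
  # all pairwise kappa 1: one unique seed of 6
  K1 <- matrix(1, 6, 6, dimnames = list(ids, ids))
  seeds <- form_seeds(K1)
  expect_length(seeds, 1)
  expect_equal(seeds[[1]], sort(ids))

  # star topology: hub tied to 5 leaves, leaves mutually unrelated;
  # qualifying pairs 5 of 15 < 50% -> rejected
  Ks <- diag(6); dimnames(Ks) <- list(ids, ids)
  Ks[1, 2:6] <- Ks[2:6, 1] <- 0.5
  expect_length(form_seeds(Ks), 0)

  # nothing at or above the threshold: no seeds
  K0 <- diag(6) * 1; dimnames(K0) <- list(ids, ids)
  K0[upper.tri(K0)] <- K0[lower.tri(K0)] <- 0.1
  expect_length(form_seeds(K0), 0)
})

test_that("merging follows the linkage threshold", {
  # sharing 3 of the smaller's 5 members (0.6 >= 0.5): merged
  s <- list(sprintf("T%02d", 1:5), sprintf("T%02d", 3:7))
  out <- merge_clusters(s)
  expect_equal(nrow(out), 1)
  expect_equal(out$member_terms[[1]], sprintf("T%02d", 1:7))

  # disjoint seeds stay apart
  s2 <- list(sprintf("A%d", 1:5), sprintf("B%d", 1:5))
  expect_equal(nrow(merge_clusters(s2)), 2)

  # below the final size after merging: discarded
  s3 <- list(sprintf("T%d", 1:3), sprintf("T%d", 2:4))
  expect_equal(nrow(merge_clusters(s3)), 0)
})

test_that("the merge result matches the exhaustive all-orders oracle", {
  seeds <- list(
    sprintf("T%02d", 1:5), sprintf("T%02d", 2:6),    # block A pair
    sprintf("T%02d", 7:11), sprintf("T%02d", 8:12),  # block B pair
    sprintf("T%02d", 5:9))                           # bridge
  terminals <- oracle_all_merge_orders(seeds, 0.5)
  expect_length(terminals, 1)  # the instance is order-independent
  got <- merge_clusters(seeds)
  got_key <- paste(sort(vapply(got$member_terms, paste, character(1),
                               collapse = ",")), collapse = ";")
  expect_equal(got_key, terminals)
})

test_that("clustering is invariant to term input order", {
  cfg <- sim_config(seed = 14)
  corp <- simulate_annotation_corpus(cfg)
  c1 <- cluster_terms(corp$terms, corp$universe)
  set.seed(1)
  shuffled <- corp$terms[sample(nrow(corp$terms)), ]
  c2 <- cluster_terms(shuffled, corp$universe)
  expect_identical(c1$member_terms, c2$member_terms)
})

test_that("noiseless planted blocks are recovered exactly", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(seed = 15)
  corp <- simulate_annotation_corpus(cfg)
  cl <- cluster_terms(corp$terms, corp$universe)
  expect_equal(block_ari(cl, corp$truth), 1)
})

test_that("pruning and summaries follow the documented rules", {
  terms <- term_table(T1 = universe[1:10], T2 = universe[5:14],
                      T3 = universe[1:12], T4 = universe[2:11],
                      T5 = universe[3:12], T6 = universe[900:950])
  clusters <- tibble::tibble(cluster_id = "C01",
                             member_terms = list(sprintf("T%d", 1:6)),
                             n_terms = 6L)
  enr <- tibble::tibble(term_id = sprintf("T%d", 1:6),
                        p_raw = c(1e-4, 1e-6, 1e-3, 1e-3, 1e-3, 0.2),
                        fdr = c(0.001, 0.001, 0.01, 0.01, 0.01, 0.2),
                        fold_enrichment = c(2, 4, 6, 3, 3, 100))
  out <- prune_and_summarize(clusters, enr, terms)
  expect_s3_class(out, "term_clusters")
  expect_equal(out$n_terms, 5L)  # the FDR 0.2 member is pruned, cluster kept
  expect_false("T6" %in% out$member_terms[[1]])
  expect_equal(out$representative_label, "T2")  # lowest raw p
  expect_equal(out$gene_union[[1]], sort(unique(unlist(terms$genes[1:5]))))
  expect_equal(out$mean_fold_enrichment, mean(c(2, 4, 6, 3, 3)))
  # enrichment score: -log10 geometric mean of member raw p
  expect_equal(out$enrichment_score, -mean(log10(enr$p_raw[1:5])))

  # geometric-mean example: p = (1e-4, 1e-6) -> score 5
  cl2 <- tibble::tibble(cluster_id = "C01",
                        member_terms = list(c("T1", "T2")), n_terms = 2L)
  out2 <- prune_and_summarize(cl2, enr, terms, keep_small = TRUE)
  expect_equal(out2$enrichment_score, 5)

  # a member without enrichment is an error naming the term
  expect_error(prune_and_summarize(
    tibble::tibble(cluster_id = "C01", member_terms = list(c("T1", "TX")),
                   n_terms = 2L), enr, terms), "TX")

  # clusters falling below the final size are dropped unless kept
  enr_low <- dplyr::mutate(enr, fdr = c(0.001, 0.001, 0.2, 0.2, 0.2, 0.2))
  expect_equal(nrow(prune_and_summarize(clusters, enr_low, terms)), 0)
  expect_equal(prune_and_summarize(clusters, enr_low, terms,
                                   keep_small = TRUE)$n_terms, 2L)
})

test_that("pruning never increases cluster size or mean raw p", {
  set.seed(22)
  for (i in 1:10) {
    n <- 8
    terms <- term_table_from_list(setNames(
      lapply(1:n, function(j) sample(universe, 20)), sprintf("T%d", 1:n)))
    clusters <- tibble::tibble(cluster_id = "C01",
                               member_terms = list(sprintf("T%d", 1:n)),
                               n_terms = n)
    enr <- tibble::tibble(term_id = sprintf("T%d", 1:n),
                          p_raw = runif(n)^3, fold_enrichment = runif(n, 0, 5))
    enr$fdr <- bh_fdr(enr$p_raw)
    out <- prune_and_summarize(clusters, enr, terms, alpha = 0.5,
                               keep_small = TRUE)
    if (nrow(out) == 0) next
    expect_lte(out$n_terms, n)
    kept <- enr$p_raw[enr$term_id %in% out$member_terms[[1]]]
    expect_lte(mean(kept), mean(enr$p_raw) + 1e-12)
  }
})

test_that("treemap layout areas are proportional and deterministic", {
  one <- tibble::tibble(cluster_id = "C01", representative_label = "only",
                        gene_union_size = 42L)
  l1 <- treemap_layout(one)
  expect_equal(nrow(l1), 1)
  expect_equal(c(l1$xmin, l1$ymin, l1$xmax, l1$ymax), c(0, 0, 100, 100))

  two <- tibble::tibble(cluster_id = c("C01", "C02"),
                        representative_label = c("big", "small"),
                        gene_union_size = c(30L, 10L))
  l2 <- treemap_layout(two)
  area <- (l2$xmax - l2$xmin) * (l2$ymax - l2$ymin)
  expect_equal(area[l2$label == "big"] / area[l2$label == "small"], 3)
  expect_equal(sum(area), 100 * 100)

  fx <- growth_clusters_as_term_clusters()
  lf <- treemap_layout(fx)
  expect_equal(nrow(lf), 29)
  # rectangles tile the canvas without loss
  expect_equal(sum((lf$xmax - lf$xmin) * (lf$ymax - lf$ymin)), 1e4)
  biggest <- lf$label[which.max((lf$xmax - lf$xmin) * (lf$ymax - lf$ymin))]
  expect_equal(biggest, "Skeletal system development")
  p <- plot_treemap(fx)
  expect_s3_class(p, "ggplot")
})
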