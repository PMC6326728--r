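toy_ranking <- function() {
  setNames(10:1, paste0("g", 1:10))
}

test_that("hand-computed extreme enrichment scores reproduce exactly", {
  s <- toy_ranking()
  expect_equal(enrichment_score(s, paste0("g", 1:3)), 1.0)
  expect_equal(enrichment_score(s, paste0("g", 8:10)), -1.0)
  expect_error(enrichment_score(s, "absent"), class = "isrmap_input_error")
  expect_error(enrichment_score(s, names(s)), class = "isrmap_input_error")
})

test_that("weight exponent 0 reduces to the classic KS statistic", {
  set.seed(8)
  stats <- setNames(sort(rnorm(40), decreasing = TRUE), paste0("g", 1:40))
  set <- sample(names(stats), 8)
  es <- enrichment_score(stats, set, weight_exponent = 0)
  # classic two-sample KS between hit and miss rank distributions
  hit <- which(names(stats) %in% set)
  k <- length(hit); n <- length(stats)
  run <- cumsum(ifelse(seq_len(n) %in% hit, 1 / k, -1 / (n - k)))
  expect_equal(abs(es), max(abs(run)), tolerance = 1e-12)
})

test_that("incremental ES matches the definitional recomputation", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    stats <- setNames(sort(round(rnorm(n), 3), decreasing = TRUE),
                      paste0("g", sprintf("%03d", 1:n)))
    set <- sample(names(stats), sample(3:10, 1))
    p <- sample(c(0, 1, 2), 1)
    # rounded stats make exact running-sum ties possible, where the two
    # recomputations may settle on different positions of the same extreme
    expect_equal(enrichment_score(stats, set, p), oracle_es(stats, set, p),
                 tolerance = 1e-12)
  }
})

test_that("the hit-position shortcut matches the full running sum", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    stats <- setNames(sort(rnorm(n), decreasing = TRUE), paste0("g", 1:n))
    k <- sample(3:12, 1)
    idx <- sort(sample(n, k))
    set <- names(stats)[idx]
    for (p in c(0, 1)) {
      expect_equal(isrmap:::es_at_positions(abs(stats)^p, idx, n),
                   enrichment_score(stats, set, p), tolerance = 1e-12)
    }
  }
})

test_that("zero-stat padding outside the set acts only through the miss step", {
  s <- toy_ranking()
  set <- paste0("g", c(2, 4))
  es1 <- enrichment_score(s, set)
  padded <- c(s, setNames(rep(0, 5), paste0("z", 1:5)))
  es2 <- enrichment_score(padded, set)
  # explicit recomputation with the altered miss denominator
  expect_equal(es2, oracle_es(padded, set, 1), tolerance = 1e-12)
  expect_false(identical(es1, es2))
})

test_that("preranked GSEA is reproducible and flags a planted shift", {
  set.seed(14)
  stats <- setNames(sort(rnorm(300), decreasing = TRUE), paste0("g", 1:300))
  planted <- names(stats)[1:25]              # top of the ranking
  random <- sample(names(stats)[50:300], 25)
  sets <- list(planted = planted, random = random)
  r1 <- gsea_preranked(stats, sets, n_perm = 500, seed = 3)
  r2 <- gsea_preranked(stats, sets, n_perm = 500, seed = 3)
  expect_identical(r1, r2)
  expect_lt(r1$p_value[r1$set == "planted"], 0.01)
  expect_gt(r1$ES[r1$set == "planted"], 0)
  expect_gt(r1$p_value[r1$set == "random"], 0.05)
  expect_true(all(r1$q_value >= 0 & r1$q_value <= 1))
  expect_error(gsea_preranked(stats, sets, n_perm = 50),
               class = "isrmap_config_error")
})

test_that("doubling permutations leaves p estimates within Monte-Carlo error", {
  set.seed(15)
  stats <- setNames(sort(rnorm(200), decreasing = TRUE), paste0("g", 1:200))
  set <- list(s = names(stats)[c(3, 9, 20, 31, 44, 70, 90)])
  p1 <- gsea_preranked(stats, set, n_perm = 1000, seed = 1)$p_value
  p2 <- gsea_preranked(stats, set, n_perm = 2000, seed = 2)$p_value
  se <- sqrt(p1 * (1 - p1) / 1000) + sqrt(p2 * (1 - p2) / 2000)
  expect_lt(abs(p1 - p2), 2 * se + 1e-3)
})

test_that("cluster signature analysis localizes planted signals", {
  cfg <- small_sim(seed = 31, basal_signature_fold = 3,
                   genotype_signature_fold = 2,
                   basal_types = 1L, shifted_types = c(1L, 2L))
  sim <- simulate_droplets(cfg)
  keep <- sim$truth$cell_type != "EMPTY"
  norm <- normalize_counts(sim$counts[, sim$truth$barcode[keep]])
  labels <- sim$truth$cell_type[keep]
  geno <- sim$truth$genotype[keep]
  res <- cluster_signature_analysis(norm, labels, geno, sim$signature,
                                    n_perm = 500, seed = 2)
  fam1 <- res[res$family == "basal", ]
  expect_true(fam1$q_value[fam1$cluster == "type01"] < 0.05 &&
                fam1$ES[fam1$cluster == "type01"] > 0)
  others <- fam1[fam1$cluster != "type01", ]
  expect_gt(mean(others$q_value >= 0.05 | others$ES < 0), 0.5)

  fam2 <- res[res$family == "genotype", ]
  flagged <- fam2$cluster[fam2$q_value < 0.05 & fam2$ES > 0]
  expect_setequal(flagged, sim$shifted_types)

  # genotype labels are exchangeable when no genotype effect is planted:
  # the genotype family then flags (almost) nothing
  cfg0 <- small_sim(seed = 32, genotype_signature_fold = 1)
  sim0 <- simulate_droplets(cfg0)
  keep0 <- sim0$truth$cell_type != "EMPTY"
  norm0 <- normalize_counts(sim0$counts[, sim0$truth$barcode[keep0]])
  res0 <- cluster_signature_analysis(norm0,
                                     sim0$truth$cell_type[keep0],
                                     with_seed(5, sample(sim0$truth$genotype[keep0])),
                                     sim0$signature, n_perm = 300, seed = 2,
                                     families = "genotype")
  expect_lte(sum(res0$q_value < 0.05 & res0$ES > 0), 1L)
})
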