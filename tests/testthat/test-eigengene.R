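fake_decomposition <- function(loadings) {
  structure(list(gene_ids = paste0("gene", seq_len(nrow(loadings))),
                 sample_ids = paste0("s", seq_len(ncol(loadings))),
                 loadings = loadings,
                 singular_values = rev(seq_len(ncol(loadings))),
                 eigengenes = diag(ncol(loadings)),
                 variance_fraction = rep(1 / ncol(loadings), ncol(loadings)),
                 log_transform = FALSE, center = FALSE),
            class = "eigengene_decomposition")
}

test_that("SVD identities hold: orthonormality, reconstruction, spectrum", {
  set.seed(6)
  x <- matrix(rlnorm(200 * 8, 3, 1), 200, 8,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  dec <- svd_decompose(x)
  expect_lt(max(abs(crossprod(dec$loadings) - diag(8))), 1e-8)
  expect_lt(max(abs(crossprod(dec$eigengenes) - diag(8))), 1e-8)
  expect_true(all(diff(dec$singular_values) <= 1e-9))
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-9)
  xc <- log1p(x) - rowMeans(log1p(x))
  rec <- dec$loadings %*% diag(dec$singular_values) %*% t(dec$eigengenes)
  expect_lt(norm(rec - xc, "F") / norm(xc, "F"), 1e-6)
  expect_error(svd_decompose(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "isrmap_input_error")
})

test_that("rank-1 input concentrates all variance on one component", {
  x <- outer(seq(1, 3, length.out = 50), seq(2, 5, length.out = 6))
  dimnames(x) <- list(paste0("g", 1:50), paste0("s", 1:6))
  dec <- svd_decompose(x, log_transform = FALSE, center = FALSE)
  expect_equal(dec$variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(scree(dec)[-1], rep(0, 5), tolerance = 1e-9)
  proj <- project_samples(dec)
  expect_equal(unname(proj[, 2]), rep(0, 6), tolerance = 1e-9)
})

test_that("gene classes follow the two-fold-mean loading threshold", {
  r <- gene_classes(fake_decomposition(matrix(c(0.9, 0.1, 0.1, 0.1), 4, 1)))
  expect_equal(r$threshold, 0.6, tolerance = 1e-12)
  expect_identical(r$up_genes, "gene1")
  expect_length(r$down_genes, 0L)

  r2 <- gene_classes(fake_decomposition(matrix(c(0.5, -0.5, 0.5, -0.5), 4, 1)))
  expect_length(r2$up_genes, 0L)
  expect_length(r2$down_genes, 0L)
  expect_error(gene_classes(fake_decomposition(matrix(1, 2, 1)), 5L),
               class = "isrmap_input_error")
})

test_that("gene classes are equivariant to gene order", {
  set.seed(7)
  x <- matrix(rlnorm(100 * 6, 3, 1), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  x[1:10, 4:6] <- x[1:10, 4:6] * 6
  r1 <- gene_classes(svd_decompose(x))
  perm <- sample(nrow(x))
  r2 <- gene_classes(svd_decompose(x[perm, ]))
  expect_setequal(r1$up_genes, r2$up_genes)
  expect_setequal(r1$down_genes, r2$down_genes)
  expect_equal(r1$threshold, r2$threshold, tolerance = 1e-12)
})

test_that("isotropic data spreads variance nearly evenly", {
  # direct-simulation bound for 200 x 20 standard Gaussian data: the
  # variance-fraction ratio max/min stays below the Marchenko-Pastur-style
  # edge ratio ((1+sqrt(0.1))/(1-sqrt(0.1)))^2 ~ 3.7 with margin
  set.seed(8)
  x <- matrix(rnorm(200 * 20), 200, 20,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
  dec <- svd_decompose(x, log_transform = FALSE, center = FALSE)
  vf <- scree(dec)
  expect_lt(max(vf) / min(vf), 4)
})

test_that("sign convention is deterministic and stable", {
  set.seed(9)
  x <- matrix(rlnorm(80 * 6, 3, 1), 80, 6,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:6)))
  d1 <- svd_decompose(x); d2 <- svd_decompose(x)
  expect_identical(d1$loadings, d2$loadings)
  expect_identical(d1$eigengenes, d2$eigengenes)
  for (k in 1:6) {
    j <- which.max(abs(d1$eigengenes[, k]))
    expect_gte(d1$eigengenes[j, k], 0)
  }
})

test_that("planted bulk classes are recovered by the first eigengene", {
  sim <- simulate_bulk(bulk_sim_config(n_genes = 3000L, n_up_genes = 150L,
                                       n_down_genes = 200L, seed = 3))
  dec <- svd_decompose(sim$expr)
  proj <- project_samples(dec)
  wt <- sim$groups == "WT"
  expect_true(max(proj[wt, 1]) < min(proj[!wt, 1]) ||
                min(proj[wt, 1]) > max(proj[!wt, 1]))
  cls <- gene_classes(dec)
  up <- if (mean(proj[!wt, 1]) > mean(proj[wt, 1])) cls$up_genes else cls$down_genes
  down <- if (mean(proj[!wt, 1]) > mean(proj[wt, 1])) cls$down_genes else cls$up_genes
  prec_up <- mean(up %in% sim$truth$up_genes)
  rec_up <- mean(sim$truth$up_genes %in% up)
  prec_dn <- mean(down %in% sim$truth$down_genes)
  rec_dn <- mean(sim$truth$down_genes %in% down)
  expect_true(all(c(prec_up, rec_up, prec_dn, rec_dn) >= 0.9))
})
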