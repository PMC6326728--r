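test_that("normalization scales depth out and log-transforms", {
  cm <- Matrix::sparseMatrix(i = c(1, 2, 1, 2), j = c(1, 1, 2, 2),
                             x = c(2, 2, 3, 9), dims = c(2, 2),
                             dimnames = list(c("g1", "g2"), c("b1", "b2")))
  norm <- normalize_counts(cm)
  expect_equal(norm["g1", "b1"], log1p(5000))
  expect_equal(norm["g2", "b1"], log1p(5000))
  # depth invariance: scaling a barcode's counts leaves its profile unchanged
  cm3 <- cm
  cm3[, 1] <- cm[, 1] * 3
  expect_equal(as.matrix(normalize_counts(cm3)), as.matrix(norm))
  # inverse: expm1 recovers the scaled proportions
  expect_equal(expm1(norm["g1", "b2"]) / 1e4, 3 / 12)
  zero <- cm; zero[, 1] <- 0
  expect_error(normalize_counts(zero), class = "isrmap_input_error")
})

test_that("a single high-dispersion gene is selected in one bin", {
  set.seed(1)
  n <- 60
  vals <- matrix(rnorm(100 * n, mean = 5, sd = 0.05), 100, n)
  vals[7, ] <- rnorm(n, mean = 5, sd = 2)  # ~10x the variance
  vals <- abs(vals)
  dimnames(vals) <- list(paste0("g", 1:100), paste0("b", 1:n))
  sel <- select_variable_genes(as(vals, "CsparseMatrix"), n_bins = 1L,
                               z_cutoff = 1, mean_bounds = c(0, 10))
  expect_identical(sel, "g7")
  # hand z-score: its dispersion z must clear the cutoff by construction
  mu <- rowMeans(vals); v <- apply(vals, 1, var)
  disp <- v / mu
  expect_gt((disp[7] - mean(disp)) / sd(disp), 1)
})

test_that("constant expression yields no variable genes", {
  vals <- matrix(3, 40, 20, dimnames = list(paste0("g", 1:40), paste0("b", 1:20)))
  expect_error(select_variable_genes(as(vals, "CsparseMatrix"), n_bins = 2L),
               class = "isrmap_input_error")
})

test_that("planted markers are recovered as variable genes", {
  sim <- simulate_droplets(small_sim())
  f <- filter_barcodes(sim$counts, find_umi_threshold(build_umi_histogram(sim$counts)))
  vg <- select_variable_genes(normalize_counts(f))
  expect_gte(mean(unlist(sim$marker_ref) %in% vg), 0.9)
})

test_that("PCA satisfies exact linear-algebra identities", {
  set.seed(2)
  # rank-1: all cells on a line in gene space
  line <- outer(runif(5, 1, 2), seq(0.5, 3, length.out = 30))
  dimnames(line) <- list(paste0("g", 1:5), paste0("b", 1:30))
  emb <- compute_pca(as(line, "CsparseMatrix"), rownames(line), n_pcs = 3L)
  expect_equal(emb$variance_explained[1], 1, tolerance = 1e-9)

  # distances in full-rank PC space equal distances in scaled gene space
  x <- matrix(abs(rnorm(8 * 12, 2)), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("b", 1:12)))
  emb <- compute_pca(as(x, "CsparseMatrix"), rownames(x), n_pcs = 8L)
  scaled <- scale(t(x))
  expect_equal(as.matrix(dist(emb$coordinates)), as.matrix(dist(scaled)),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_true(all(diff(emb$variance_explained) <= 1e-12))
  expect_lte(sum(emb$variance_explained), 1 + 1e-9)
  expect_false(any(!is.finite(emb$coordinates)))
})

test_that("embedding is reproducible and equivariant to input order", {
  set.seed(3)
  x <- matrix(abs(rnorm(20 * 40, 2)), 20, 40,
              dimnames = list(paste0("g", 1:20), paste0("b", 1:40)))
  xs <- as(x, "CsparseMatrix")
  e1 <- compute_pca(xs, rownames(x), n_pcs = 5L)
  e2 <- compute_pca(xs, rownames(x), n_pcs = 5L)
  expect_identical(e1$coordinates, e2$coordinates)
  # barcode order: permuting columns permutes coordinates rows
  perm <- sample(ncol(x))
  e3 <- compute_pca(xs[, perm], rownames(x), n_pcs = 5L)
  expect_equal(e3$coordinates, e1$coordinates[perm, ], tolerance = 1e-9)
  # gene order leaves the embedding unchanged
  gperm <- sample(nrow(x))
  e4 <- compute_pca(xs[gperm, ], rownames(x)[gperm], n_pcs = 5L)
  expect_equal(abs(e4$coordinates), abs(e1$coordinates), tolerance = 1e-9)
})

test_that("zero-variance genes are dropped with a warning, tiny inputs error", {
  x <- matrix(abs(rnorm(4 * 10, 2)), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("b", 1:10)))
  x[2, ] <- 1
  expect_message(emb <- compute_pca(as(x, "CsparseMatrix"), rownames(x), 2L),
                 "zero-variance")
  expect_false("g2" %in% emb$variable_genes)
  x[c(1, 3), ] <- 2
  expect_error(suppressMessages(
    compute_pca(as(x, "CsparseMatrix"), rownames(x), 2L)),
    class = "isrmap_input_error")
})
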