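#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom: a gene in the set increments
#' the running sum by `|stat|^p / sum_set |stat|^p` (uniform `1/k` when all
#' set statistics are zero), every other gene decrements it by
#' `1/(N - k)`. The enrichment score is the running-sum value of maximal
#' absolute deviation, signed; an exact tie between the positive and
#' negative extremes resolves to the positive one.
#'
#' @param ranked a `ranked_list` (see [ranked_list()]), or a named numeric
#'   vector of statistics already sorted in ranking order.
#' @param gene_set character vector of gene ids; its intersection with the
#'   ranked genes must be nonempty and a proper subset.
#' @param weight_exponent the weight exponent p (default 1; 0 gives the
#'   classic unweighted KS statistic).
#' @return the enrichment score, in [-1, 1].
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  s <- ranked_stats(ranked)
  hit <- names(s) %in% gene_set
  k <- sum(hit)
  if (k == 0L) isr_stop("gene set does not intersect the ranked list",
                        "isrmap_input_error")
  if (k == length(s)) isr_stop("gene set covers the whole ranked list",
                               "isrmap_input_error")
  w <- abs(s)^weight_exponent
  wh <- w[hit]
  incr <- numeric(length(s))
  incr[hit] <- if (sum(wh) > 0) wh / sum(wh) else 1 / k
  incr[!hit] <- -1 / (length(s) - k)
  d <- cumsum(incr)
  maxv <- max(d); minv <- min(d)
  if (maxv >= -minv) maxv else minv
}

ranked_stats <- function(ranked) {
  if (inherits(ranked, "ranked_list") || is.data.frame(ranked)) {
    setNames(ranked$stat, ranked$gene)
  } else {
    if (is.null(names(ranked))) isr_stop("ranked statistics must be named",
                                         "isrmap_input_error")
    ranked
  }
}

# ES evaluated only at the hit positions: between hits the running sum
# decreases linearly, so the positive extreme sits just after a hit (or at
# the final value 0) and the negative extreme just before a hit. `sp` is
# |stat|^p over the whole ranking, `idx` the sorted hit positions. Exactly
# matches enrichment_score() up to floating-point summation order.
es_at_positions <- function(sp, idx, n) {
  k <- length(idx)
  w <- sp[idx]
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
  cw <- cumsum(w)
  miss <- (idx - seq_len(k)) / (n - k)
  after <- cw - miss
  before <- c(0, cw[-k]) - miss
  maxv <- max(after, 0); minv <- min(before)
  if (maxv >= -minv) maxv else minv
}

#' Preranked GSEA with a gene-permutation null
#'
#' For each gene set, the observed enrichment score is compared against the
#' scores of `n_perm` random gene sets of identical size drawn without
#' replacement from the ranked universe. The nominal p-value is the
#' one-sided tail frequency among null scores of matching sign, with a +1
#' pseudo-count; NES is the observed score divided by the mean magnitude of
#' same-sign null scores; q-values are Benjamini-Hochberg across all sets
#' in the call.
#'
#' @param ranked a `ranked_list` or named sorted statistic vector.
#' @param gene_sets named list of gene-id vectors.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param weight_exponent see [enrichment_score()].
#' @return data.frame with columns `set`, `size` (genes in the ranking),
#'   `ES`, `NES`, `p_value`, `q_value`, `n_perm`, `seed`.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1) {
  if (n_perm < 100L) isr_stop("n_perm must be >= 100", "isrmap_config_error")
  s <- ranked_stats(ranked)
  n <- length(s)
  sp <- abs(s)^weight_exponent
  rows <- lapply(names(gene_sets), function(nm) {
    idx <- sort(which(names(s) %in% gene_sets[[nm]]))
    k <- length(idx)
    if (k == 0L || k == n)
      isr_stop(sprintf("gene set '%s' must be a nonempty proper subset of the ranking", nm),
               "isrmap_input_error")
    es <- es_at_positions(sp, idx, n)
    null_es <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      es_at_positions(sp, sort(sample.int(n, k)), n)
    }, numeric(1)))
    if (es == 0) {
      p <- 1; nes <- NA_real_
    } else {
      same <- null_es * sign(es) > 0
      p <- (1 + sum(null_es[same] * sign(es) >= abs(es))) / (1 + sum(same))
      nes <- if (any(same)) es / mean(abs(null_es[same])) else NA_real_
    }
    data.frame(set = nm, size = k, ES = es, NES = nes, p_value = p,
               n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[, c("set", "size", "ES", "NES", "p_value", "q_value", "n_perm", "seed")]
}

#' Per-cluster signature enrichment in two contrast families
#'
#' Family `basal`: for each cluster, reference-genotype (WT) cells of the
#' cluster are contrasted against WT cells of all other clusters, and the
#' resulting ranked list is tested for signature enrichment — which cell
#' types carry the signature at baseline. Family `genotype`: within each
#' cluster, mutant cells are contrasted against WT cells — which cell types
#' elevate the signature in the mutant. Clusters missing a genotype are
#' skipped in the genotype family with a logged warning. Q-values are
#' Benjamini-Hochberg within each family across all (cluster, set) results.
#'
#' @param normalized genes x barcodes normalized matrix.
#' @param assignment a `cluster_assignment` or label vector.
#' @param genotypes vector of genotype labels aligned with the matrix
#'   columns (or named by barcode).
#' @param gene_sets named list of signature gene sets.
#' @param genotype_labels length-2: reference label then mutant label
#'   (default `c("WT", "MUT")`).
#' @param n_perm,seed,weight_exponent passed to [gsea_preranked()].
#' @param families which contrast families to run (default both).
#' @return data.frame with columns `family` (`"basal"` or `"genotype"`),
#'   `cluster`, `set`, `size`, `ES`, `NES`, `p_value`, `q_value`.
#' @export
cluster_signature_analysis <- function(normalized, assignment, genotypes,
                                       gene_sets,
                                       genotype_labels = c("WT", "MUT"),
                                       n_perm = 1000L, seed = 1L,
                                       weight_exponent = 1,
                                       families = c("basal", "genotype")) {
  families <- match.arg(families, several.ok = TRUE)
  barcodes <- colnames(normalized)
  labels <- assignment_labels(assignment, barcodes)
  if (!is.null(names(genotypes))) genotypes <- genotypes[barcodes]
  if (length(genotypes) != length(barcodes))
    isr_stop("genotypes do not align with matrix columns", "isrmap_input_error")
  wt <- genotypes == genotype_labels[1]
  mut <- genotypes == genotype_labels[2]
  if (!any(wt) || !any(mut))
    isr_stop("both genotypes must be present", "isrmap_input_error")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L)
    isr_stop("need >= 2 clusters", "isrmap_input_error")

  run_family <- function(family) {
    rows <- lapply(clusters, function(cl) {
      inside <- labels == cl
      if (family == "basal") {
        a <- which(inside & wt); b <- which(!inside & wt)
        desc <- sprintf("cluster %s WT vs other WT", cl)
      } else {
        a <- which(inside & mut); b <- which(inside & wt)
        desc <- sprintf("cluster %s %s vs %s", cl, genotype_labels[2],
                        genotype_labels[1])
      }
      if (!length(a) || !length(b)) {
        isr_log("warn", sprintf("cluster %s lacks cells for the %s contrast; skipped",
                                cl, family))
        return(NULL)
      }
      rl <- ranked_list(normalized, a, b, descriptor = desc)
      res <- gsea_preranked(rl, gene_sets, n_perm = n_perm, seed = seed,
                            weight_exponent = weight_exponent)
      cbind(family = family, cluster = cl,
            res[, setdiff(names(res), "q_value")],
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$q_value <- p.adjust(out$p_value, method = "BH")
    out
  }
  out <- do.call(rbind, lapply(families, run_family))
  rownames(out) <- NULL
  out[, c("family", "cluster", "set", "size", "ES", "NES", "p_value",
          "q_value", "n_perm", "seed")]
}
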