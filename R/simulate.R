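#' Configuration for the droplet scRNA-seq simulator
#'
#' The generator emulates the structure the downstream analyses assume: a
#' fixed number of transcriptionally distinct cell types, each carrying a
#' set of over-expressed marker genes; one or more "astrocyte-like" types
#' with elevated basal expression of an ISR-like gene signature; two
#' genotypes (`WT`, `MUT`) where the mutant further elevates the signature
#' in designated types; and a large pool of empty droplets sampling the
#' ambient (population-average) expression program at low depth.
#'
#' Per-barcode UMI totals are log10-normal, with separate location/scale for
#' cells and empties; gene counts given a total are multinomial from the
#' cell's normalized expression program, which preserves the UMI-total
#' structure the barcode filter exploits.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type integer vector (recycled) of cells per type;
#'   defaults sum to the expected recovery of 4000 cells.
#' @param n_genes number of genes.
#' @param markers_per_type markers planted per type.
#' @param marker_fold fold elevation of a marker in its own type (>= 1).
#' @param marker_exclusivity fraction of a marker's baseline rate retained
#'   in the other cell types (default 0.1). Real cell-type markers are
#'   close to exclusive; without suppression a probability-normalized
#'   marker score over many types could never clear 0.5.
#' @param n_empty_droplets number of empty droplets.
#' @param cell_umi_logmean,cell_umi_logsd location/scale of log10 UMI totals
#'   for real cells.
#' @param empty_umi_logmean,empty_umi_logsd same for empty droplets; the
#'   empty mode must lie below the cell mode.
#' @param n_signature_genes size of the planted ISR-like signature
#'   (default 95).
#' @param basal_signature_fold basal signature elevation in `basal_types`
#'   (>= 1).
#' @param genotype_signature_fold additional signature elevation in `MUT`
#'   cells of `shifted_types` (>= 1).
#' @param basal_types indices of types with elevated basal signature.
#' @param shifted_types indices of types whose mutant cells elevate the
#'   signature further.
#' @param genotype_labels two labels, reference first.
#' @param seed RNG seed.
#' @return a validated config object (class `cell_sim_config`).
#' @export
cell_sim_config <- function(n_cell_types = 10L,
                            cells_per_type = 400L,
                            n_genes = 10000L,
                            markers_per_type = 50L,
                            marker_fold = 4,
                            marker_exclusivity = 0.1,
                            n_empty_droplets = 20000L,
                            cell_umi_logmean = 3.5, cell_umi_logsd = 0.2,
                            empty_umi_logmean = 1.5, empty_umi_logsd = 0.3,
                            n_signature_genes = 95L,
                            basal_signature_fold = 3,
                            genotype_signature_fold = 2,
                            basal_types = 1L,
                            shifted_types = c(1L, 2L),
                            genotype_labels = c("WT", "MUT"),
                            seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = rep_len(as.integer(cells_per_type), n_cell_types),
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              marker_fold = marker_fold,
              marker_exclusivity = marker_exclusivity,
              n_empty_droplets = as.integer(n_empty_droplets),
              cell_umi_logmean = cell_umi_logmean,
              cell_umi_logsd = cell_umi_logsd,
              empty_umi_logmean = empty_umi_logmean,
              empty_umi_logsd = empty_umi_logsd,
              n_signature_genes = as.integer(n_signature_genes),
              basal_signature_fold = basal_signature_fold,
              genotype_signature_fold = genotype_signature_fold,
              basal_types = as.integer(basal_types),
              shifted_types = as.integer(shifted_types),
              genotype_labels = genotype_labels,
              seed = as.integer(seed))
  class(cfg) <- "cell_sim_config"
  validate_cell_sim_config(cfg)
  cfg
}

validate_cell_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cell_types < 1L || n_genes < 1L || n_empty_droplets < 0L)
      isr_stop("counts must be positive", "isrmap_config_error")
    if (marker_fold < 1 || basal_signature_fold < 1 || genotype_signature_fold < 1)
      isr_stop("fold multipliers must be >= 1", "isrmap_config_error")
    if (marker_exclusivity <= 0 || marker_exclusivity > 1)
      isr_stop("marker_exclusivity must be in (0, 1]", "isrmap_config_error")
    if (n_cell_types * markers_per_type + n_signature_genes > n_genes)
      isr_stop("markers plus signature genes exceed the gene universe",
               "isrmap_config_error")
    if (cell_umi_logmean <= empty_umi_logmean)
      isr_stop("cell UMI mode must exceed empty UMI mode", "isrmap_config_error")
    if (any(basal_types > n_cell_types) || any(shifted_types > n_cell_types))
      isr_stop("designated type index out of range", "isrmap_config_error")
    if (length(genotype_labels) != 2L)
      isr_stop("exactly two genotype labels required", "isrmap_config_error")
  })
  invisible(cfg)
}

#' Simulate a droplet scRNA-seq experiment with ground truth
#'
#' @param config a [cell_sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{counts}{genes x barcodes sparse UMI matrix (cells and empties,
#'       shuffled column order).}
#'     \item{truth}{data.frame with columns `barcode`, `cell_type`
#'       (`"EMPTY"` for empty droplets) and `genotype` (`NA` for empties).}
#'     \item{marker_ref}{planted marker reference (named list per type).}
#'     \item{signature}{planted signature as a one-set gene-set collection
#'       named `ISR_signature`.}
#'     \item{basal_types, shifted_types}{names of the designated types.}
#'   }
#' @export
simulate_droplets <- function(config) {
  validate_cell_sim_config(config)
  with_seed(config$seed, {
    ng <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(ng))
    type_names <- sprintf("type%02d", seq_len(config$n_cell_types))

    base_rate <- rlnorm(ng, meanlog = 0, sdlog = 1)
    special <- sample.int(ng, config$n_cell_types * config$markers_per_type +
                              config$n_signature_genes)
    marker_idx <- matrix(special[seq_len(config$n_cell_types * config$markers_per_type)],
                         nrow = config$markers_per_type)
    sig_idx <- special[-seq_len(config$n_cell_types * config$markers_per_type)]
    # markers and signature genes sit in the moderately-to-highly expressed
    # part of the rate distribution, as curated marker panels do; a shifted
    # broad lognormal keeps them spread over many mean bins downstream
    base_rate[special] <- rlnorm(length(special), meanlog = 1, sdlog = 0.8)

    programs <- matrix(base_rate, nrow = ng, ncol = config$n_cell_types)
    # markers: near-exclusive (suppressed off-type), elevated in their type
    programs[as.vector(marker_idx), ] <-
      programs[as.vector(marker_idx), ] * config$marker_exclusivity
    for (t in seq_len(config$n_cell_types)) {
      programs[marker_idx[, t], t] <- base_rate[marker_idx[, t]] * config$marker_fold
    }
    programs[sig_idx, config$basal_types] <-
      programs[sig_idx, config$basal_types] * config$basal_signature_fold

    n_cells <- sum(config$cells_per_type)
    cell_type <- rep(seq_len(config$n_cell_types), config$cells_per_type)
    # split each type evenly across genotypes
    genotype <- unlist(lapply(config$cells_per_type, function(n) {
      rep(c(1L, 2L), c(ceiling(n / 2), floor(n / 2)))
    }), use.names = FALSE)

    totals_cell <- pmax(1L, round(10^rnorm(n_cells, config$cell_umi_logmean,
                                           config$cell_umi_logsd)))
    totals_empty <- pmax(1L, round(10^rnorm(config$n_empty_droplets,
                                            config$empty_umi_logmean,
                                            config$empty_umi_logsd)))

    # draw gene indices group-wise (same program within a (type, genotype)
    # group), equivalent to per-cell multinomials
    ii <- vector("list", 2L * config$n_cell_types + 1L)
    jj <- vector("list", 2L * config$n_cell_types + 1L)
    k <- 0L
    for (t in seq_len(config$n_cell_types)) {
      for (g in 1:2) {
        cells <- which(cell_type == t & genotype == g)
        if (!length(cells)) next
        prog <- programs[, t]
        if (g == 2L && t %in% config$shifted_types) {
          prog[sig_idx] <- prog[sig_idx] * config$genotype_signature_fold
        }
        tot <- sum(totals_cell[cells])
        k <- k + 1L
        ii[[k]] <- sample.int(ng, tot, replace = TRUE, prob = prog)
        jj[[k]] <- rep.int(cells, totals_cell[cells])
      }
    }
    if (config$n_empty_droplets > 0L) {
      ambient <- programs %*% config$cells_per_type  # population-average program
      k <- k + 1L
      ii[[k]] <- sample.int(ng, sum(totals_empty), replace = TRUE,
                            prob = as.vector(ambient))
      jj[[k]] <- rep.int(n_cells + seq_len(config$n_empty_droplets), totals_empty)
    }
    ii <- unlist(ii[seq_len(k)], use.names = FALSE)
    jj <- unlist(jj[seq_len(k)], use.names = FALSE)

    n_bc <- n_cells + config$n_empty_droplets
    perm <- sample.int(n_bc)  # shuffle droplet order
    counts <- Matrix::sparseMatrix(i = ii, j = perm[jj], x = 1,
                                   dims = c(ng, n_bc))
    barcode_ids <- sprintf("bc%06d", seq_len(n_bc))
    dimnames(counts) <- list(gene_ids, barcode_ids)

    truth <- data.frame(
      barcode = barcode_ids,
      cell_type = c(type_names[cell_type], rep("EMPTY", config$n_empty_droplets))[order(perm)],
      genotype = c(config$genotype_labels[genotype],
                   rep(NA_character_, config$n_empty_droplets))[order(perm)],
      stringsAsFactors = FALSE)

    marker_ref <- lapply(seq_len(config$n_cell_types),
                         function(t) gene_ids[marker_idx[, t]])
    names(marker_ref) <- type_names
    signature <- structure(list(ISR_signature = gene_ids[sig_idx]),
                           description = c(ISR_signature = "planted ISR-like signature"))

    list(counts = counts, truth = truth, marker_ref = marker_ref,
         signature = signature,
         basal_types = type_names[config$basal_types],
         shifted_types = type_names[config$shifted_types])
  })
}

#' Configuration for the bulk expression simulator
#'
#' Two sample groups (reference and mutant) with log-normal expression,
#' a planted class of up-regulated genes (multiplied by `up_fold` in the
#' mutant group) and a planted class of down-regulated genes (divided by
#' `down_fold`); columns are rescaled to sum to 1e6 (TPM convention).
#' Default class sizes follow the 473-up / 600-down split the eigengene
#' analysis is expected to recover.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per group.
#' @param n_up_genes,n_down_genes planted class sizes.
#' @param up_fold,down_fold class fold changes (> 1).
#' @param dispersion sd of per-sample log-normal noise (natural log scale).
#' @param seed RNG seed.
#' @return a validated config (class `bulk_sim_config`).
#' @export
bulk_sim_config <- function(n_genes = 10000L, n_samples_per_group = 3L,
                            n_up_genes = 473L, n_down_genes = 600L,
                            up_fold = 4, down_fold = 4,
                            dispersion = 0.2, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_up_genes = as.integer(n_up_genes),
              n_down_genes = as.integer(n_down_genes),
              up_fold = up_fold, down_fold = down_fold,
              dispersion = dispersion, seed = as.integer(seed))
  class(cfg) <- "bulk_sim_config"
  if (cfg$n_up_genes + cfg$n_down_genes > cfg$n_genes)
    isr_stop("planted classes exceed the gene universe", "isrmap_config_error")
  if (cfg$up_fold < 1 || cfg$down_fold < 1)
    isr_stop("fold changes must be >= 1", "isrmap_config_error")
  if (cfg$n_samples_per_group < 2L)
    isr_stop("need >= 2 samples per group", "isrmap_config_error")
  cfg
}

#' Simulate a bulk genotype-contrast expression matrix
#'
#' @param config a [bulk_sim_config()].
#' @return list with `expr` (genes x samples TPM-like matrix; columns sum to
#'   1e6), `groups` (sample group factor, levels `WT`, `MUT`) and `truth`
#'   (list with `up_genes` and `down_genes` id vectors).
#' @export
simulate_bulk <- function(config) {
  with_seed(config$seed, {
    ng <- config$n_genes
    ns <- 2L * config$n_samples_per_group
    gene_ids <- sprintf("g%05d", seq_len(ng))
    sample_ids <- paste0(rep(c("WT", "MUT"), each = config$n_samples_per_group),
                         seq_len(config$n_samples_per_group))
    groups <- factor(rep(c("WT", "MUT"), each = config$n_samples_per_group),
                     levels = c("WT", "MUT"))

    base <- rlnorm(ng, meanlog = 3, sdlog = 1.5)
    idx <- sample.int(ng, config$n_up_genes + config$n_down_genes)
    up <- idx[seq_len(config$n_up_genes)]
    down <- idx[-seq_len(config$n_up_genes)]

    expr <- matrix(0, ng, ns, dimnames = list(gene_ids, sample_ids))
    for (s in seq_len(ns)) {
      mu <- base
      if (groups[s] == "MUT") {
        mu[up] <- mu[up] * config$up_fold
        mu[down] <- mu[down] / config$down_fold
      }
      expr[, s] <- mu * rlnorm(ng, meanlog = 0, sdlog = config$dispersion)
    }
    expr <- sweep(expr, 2, colSums(expr), "/") * 1e6
    list(expr = expr, groups = groups,
         truth = list(up_genes = gene_ids[up], down_genes = gene_ids[down]))
  })
}
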