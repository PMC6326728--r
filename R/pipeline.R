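#' Pipeline configuration
#'
#' All tunable parameters of the pipeline stages, with the study's printed
#' values as defaults where it states one (UMI floor 2 in log10 units,
#' K cap 750, Jaccard prune cutoff 1/15, resolution range 0.05-1.225,
#' 50 PCs, assignment probability threshold 0.5, marker alpha 0.05) and
#' era-standard workflow defaults elsewhere.
#'
#' @param bin_width,smooth_window,umi_floor see [build_umi_histogram()].
#' @param scale_factor see [normalize_counts()].
#' @param vg_bins,vg_z_cutoff,vg_mean_bounds see [select_variable_genes()].
#' @param n_pcs see [compute_pca()].
#' @param k_cap,prune_cutoff see [build_knn()], [build_snn_jaccard()].
#' @param res_min,res_max,res_step resolution grid bounds and step.
#' @param min_cells minimum sub-cluster size in [iterative_subcluster()].
#' @param de_min_frac,de_adjust,alpha,sigma_min see [markers_for_cluster()].
#' @param prob_threshold see [score_cluster()].
#' @param n_perm,weight_exponent see [gsea_preranked()].
#' @param seed RNG seed for all stochastic stages.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return validated list of class `pipeline_config`, with a derived
#'   `resolution_grid` element.
#' @export
pipeline_config <- function(bin_width = 0.05, smooth_window = 3L,
                            umi_floor = 2.0, scale_factor = 1e4,
                            vg_bins = 20L, vg_z_cutoff = 1,
                            vg_mean_bounds = c(0.0125, 3),
                            n_pcs = 50L, k_cap = 750L,
                            prune_cutoff = 1 / 15,
                            res_min = 0.05, res_max = 1.225,
                            res_step = 0.025, min_cells = 10L,
                            de_min_frac = 0.1,
                            de_adjust = "bonferroni", alpha = 0.05,
                            sigma_min = 1e-3,
                            prob_threshold = 0.5, n_perm = 1000L,
                            weight_exponent = 1, seed = 1L,
                            log_level = "info") {
  cfg <- list(bin_width = bin_width, smooth_window = as.integer(smooth_window),
              umi_floor = umi_floor, scale_factor = scale_factor,
              vg_bins = as.integer(vg_bins), vg_z_cutoff = vg_z_cutoff,
              vg_mean_bounds = as.numeric(vg_mean_bounds),
              n_pcs = as.integer(n_pcs), k_cap = as.integer(k_cap),
              prune_cutoff = prune_cutoff,
              res_min = res_min, res_max = res_max, res_step = res_step,
              min_cells = as.integer(min_cells),
              de_min_frac = de_min_frac, de_adjust = de_adjust,
              alpha = alpha, sigma_min = sigma_min,
              prob_threshold = prob_threshold, n_perm = as.integer(n_perm),
              weight_exponent = weight_exponent, seed = as.integer(seed),
              log_level = log_level)
  cfg$resolution_grid <- seq(cfg$res_min, cfg$res_max, by = cfg$res_step)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) isr_stop(paste0("config: ", what),
                                              "isrmap_config_error")
  chk(cfg$bin_width > 0, "bin_width must be > 0")
  chk(cfg$smooth_window >= 1L && cfg$smooth_window %% 2L == 1L,
      "smooth_window must be odd and >= 1")
  chk(cfg$scale_factor > 0, "scale_factor must be > 0")
  chk(cfg$vg_bins >= 1L, "vg_bins must be >= 1")
  chk(length(cfg$vg_mean_bounds) == 2L &&
        cfg$vg_mean_bounds[1] <= cfg$vg_mean_bounds[2],
      "vg_mean_bounds must be an ordered pair")
  chk(cfg$n_pcs >= 1L, "n_pcs must be >= 1")
  chk(cfg$k_cap >= 1L, "k_cap must be >= 1")
  chk(cfg$prune_cutoff >= 0 && cfg$prune_cutoff <= 1,
      "prune_cutoff must be in [0, 1]")
  chk(cfg$res_min > 0 && cfg$res_max >= cfg$res_min && cfg$res_step > 0,
      "resolution grid must be positive and increasing")
  chk(cfg$min_cells >= 1L, "min_cells must be >= 1")
  chk(cfg$de_min_frac >= 0 && cfg$de_min_frac <= 1,
      "de_min_frac must be in [0, 1]")
  chk(cfg$de_adjust %in% c("bonferroni", "BH"),
      "de_adjust must be 'bonferroni' or 'BH'")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$prob_threshold >= 0 && cfg$prob_threshold < 1,
      "prob_threshold must be in [0, 1)")
  chk(cfg$n_perm >= 100L, "n_perm must be >= 100")
  chk(cfg$weight_exponent >= 0, "weight_exponent must be >= 0")
  chk(cfg$log_level %in% names(.log_levels), "unknown log_level")
  invisible(cfg)
}

#' Read/write a pipeline configuration as YAML
#'
#' Round-trips losslessly (numbers are serialized at full double
#' precision).
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a validated `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  fields <- unclass(cfg)
  fields$resolution_grid <- NULL  # derived
  writeLines(yaml::as.yaml(fields, precision = 17L), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  fields <- yaml::read_yaml(path)
  do.call(pipeline_config, fields)
}

#' Run the full single-cell pipeline
#'
#' Executes QC (barcode filtering), embedding (normalization,
#' variable-gene selection, PCA), clustering (SNN graph, resolution search,
#' iterative sub-clustering), marker calling, cell-type assignment and
#' signature enrichment, in that order, writing per-stage TSV/JSON outputs
#' plus a JSON log of every effective parameter. A run is a pure function
#' of (inputs, config): repeated runs with the same seed produce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param counts genes x barcodes count matrix, or a directory containing a
#'   10x triple (`matrix.mtx`, `barcodes.tsv`, `features.tsv`).
#' @param out_dir output directory.
#' @param marker_ref marker reference (named list, or TSV path); required
#'   for the `celltype` stage.
#' @param gene_sets signature collection (named list, or GMT path);
#'   required for the `enrich` stage.
#' @param genotypes data.frame with columns `barcode`, `genotype` (or a
#'   TSV path); required for the `enrich` stage.
#' @param genotype_labels reference and mutant labels.
#' @param stages stages to run, in pipeline order.
#' @return invisibly, a list with the in-memory stage results (`threshold`,
#'   `filtered`, `normalized`, `embedding`, `clusters`, `markers`,
#'   `celltype`, `enrichment`) and `paths` of written files.
#' @export
run_pipeline <- function(config, counts, out_dir,
                         marker_ref = NULL, gene_sets = NULL,
                         genotypes = NULL,
                         genotype_labels = c("WT", "MUT"),
                         stages = c("qc", "embed", "cluster", "markers",
                                    "celltype", "enrich")) {
  validate_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  old <- options(isrmap.log_level = config$log_level)
  on.exit(options(old))

  # resolve all inputs up front so a missing one aborts before any stage
  if (is.character(counts) && length(counts) == 1L) {
    counts <- read_counts_10x(file.path(counts, "matrix.mtx"),
                              file.path(counts, "barcodes.tsv"),
                              file.path(counts, "features.tsv"))
  }
  counts <- validate_count_matrix(counts)
  if ("celltype" %in% stages) {
    if (is.null(marker_ref)) isr_stop("celltype stage requires marker_ref",
                                      "isrmap_config_error")
    if (is.character(marker_ref)) marker_ref <- read_marker_reference(marker_ref)
    marker_ref <- validate_marker_reference(marker_ref)
  }
  if ("enrich" %in% stages) {
    if (is.null(gene_sets) || is.null(genotypes))
      isr_stop("enrich stage requires gene_sets and genotypes",
               "isrmap_config_error")
    if (is.character(gene_sets)) gene_sets <- read_gene_sets_gmt(gene_sets)
    if (is.character(genotypes))
      genotypes <- read.table(genotypes, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    isr_stop(sprintf("cannot create '%s'", out_dir), "isrmap_io_error")

  res <- list(paths = list())
  stage <- function(name, expr) {
    isr_log("info", "stage ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    res$paths[[name]] <<- path
    path
  }

  res$filtered <- counts
  if ("qc" %in% stages) {
    res$filtered <- stage("qc", {
      h <- build_umi_histogram(counts, bin_width = config$bin_width,
                               smooth_window = config$smooth_window,
                               floor = config$umi_floor)
      thr <- find_umi_threshold(h)
      isr_log("info", sprintf("qc: bin_width=%g smooth_window=%d floor=%g threshold=%g",
                              config$bin_width, config$smooth_window,
                              config$umi_floor, thr))
      res$threshold <- thr
      f <- filter_barcodes(counts, thr)
      emit("qc.json", function(p) jsonlite::write_json(
        list(threshold_log10_umi = thr, barcodes_in = ncol(counts),
             barcodes_retained = ncol(f)), p, auto_unbox = TRUE, digits = NA))
      f
    })
  }

  if (any(c("embed", "cluster", "markers", "celltype", "enrich") %in% stages)) {
    stage("embed", {
      res$normalized <- normalize_counts(res$filtered,
                                          scale_factor = config$scale_factor)
      vg <- select_variable_genes(res$normalized, n_bins = config$vg_bins,
                                  z_cutoff = config$vg_z_cutoff,
                                  mean_bounds = config$vg_mean_bounds)
      isr_log("info", sprintf("embed: scale=%g bins=%d z>=%g -> %d variable genes",
                              config$scale_factor, config$vg_bins,
                              config$vg_z_cutoff, length(vg)))
      res$embedding <- compute_pca(res$normalized, vg, n_pcs = config$n_pcs)
      emit("variable_genes.tsv", function(p) writeLines(vg, p))
      emit("embedding.tsv", function(p) write_tsv(
        data.frame(barcode = res$embedding$barcode_ids,
                   res$embedding$coordinates, check.names = FALSE), p))
    })
  }

  if (any(c("cluster", "markers", "celltype", "enrich") %in% stages)) {
    stage("cluster", {
      knn <- build_knn(res$embedding, K_cap = config$k_cap)
      snn <- build_snn_jaccard(knn, prune_cutoff = config$prune_cutoff)
      isr_log("info", sprintf("cluster: K=%d prune=%g grid=[%g,%g] step %g",
                              knn$K, config$prune_cutoff, config$res_min,
                              config$res_max, config$res_step))
      scan <- resolution_search(snn, grid = config$resolution_grid,
                                seed = config$seed)
      res$clusters <- iterative_subcluster(res$normalized, scan, snn, config)
      emit("clusters.tsv", function(p) write_tsv(as.data.frame(res$clusters), p))
      emit("resolution_scan.json", function(p) jsonlite::write_json(
        list(grid = scan$grid, metric = scan$metric,
             selected_resolution = scan$resolution,
             n_communities = scan$partition$n_communities,
             n_leaves = length(unique(res$clusters$cluster))),
        p, auto_unbox = TRUE, digits = NA))
    })
  }

  if ("markers" %in% stages) {
    stage("markers", {
      tabs <- lapply(sort(unique(res$clusters$cluster)), function(cl) {
        m <- markers_for_cluster(res$normalized, res$clusters, cl,
                                 min_frac = config$de_min_frac,
                                 alpha = config$alpha,
                                 adjust = config$de_adjust,
                                 sigma_min = config$sigma_min)
        cbind(cluster = cl, m[m$is_marker, , drop = FALSE])
      })
      res$markers <- do.call(rbind, tabs)
      emit("markers.tsv", function(p) write_tsv(res$markers, p))
    })
  }

  if ("celltype" %in% stages) {
    stage("celltype", {
      res$celltype <- assign_all(res$normalized, res$clusters, marker_ref,
                                  threshold = config$prob_threshold)
      emit("celltype.tsv", function(p) write_tsv(res$celltype, p))
      emit("celltype_calls.tsv", function(p) write_tsv(celltype_calls(res$celltype), p))
    })
  }

  if ("enrich" %in% stages) {
    stage("enrich", {
      geno <- setNames(genotypes$genotype, genotypes$barcode)
      res$enrichment <- cluster_signature_analysis(
        res$normalized, res$clusters, geno, gene_sets,
        genotype_labels = genotype_labels, n_perm = config$n_perm,
        seed = config$seed, weight_exponent = config$weight_exponent)
      emit("enrichment.tsv", function(p) write_tsv(res$enrichment, p))
    })
  }

  emit("params.json", function(p) {
    fields <- unclass(config)
    fields$resolution_grid <- NULL
    jsonlite::write_json(fields, p, auto_unbox = TRUE, digits = NA)
  })
  invisible(res)
}
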