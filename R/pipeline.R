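#' Build a run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]:
#' either a synthetic-generator block or paths to expression tables, the
#' analysis thresholds (all defaulting to the conventional values:
#' microarray detection 200, FPKM bins 5/200, 95% detection CI, FPKM > 5
#' stringent filter, B = 1000 bootstrap replicates, alpha = 0.01,
#' connectivity tau = 2), a mandatory seed, and stage toggles.
#'
#' @param synthetic a [synthetic_config()] (or argument list for one),
#'   or `NULL` when reading input tables.
#' @param inputs list with `rnaseq`, `microarray` (TSV paths) and
#'   optionally `paralogs` (pair TSV); ignored when `synthetic` is
#'   given.
#' @param ma_threshold,ci_level,fpkm_bins,fpkm_min,alpha,tau,boot_reps
#'   analysis thresholds.
#' @param seed global seed for every stochastic stage.
#' @param outdir output directory; `NULL` to skip writing artifacts.
#' @param stages character vector of enabled stages, a subset of
#'   `c("concordance", "entropy", "paralogs", "network", "ec")`.
#' @param pca_k gene-cluster count for the ordination stage.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       ma_threshold = 200, ci_level = 0.95,
                       fpkm_bins = c(5, 200), fpkm_min = 5,
                       alpha = 0.01, tau = 2.0, boot_reps = 1000,
                       seed = 1, outdir = NULL,
                       stages = c("concordance", "entropy", "paralogs",
                                  "network", "ec"),
                       pca_k = 1000) {
  if (is.null(synthetic) && is.null(inputs)) {
    stop("provide either a synthetic block or input paths")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, synthetic)
  }
  stopifnot(ma_threshold >= 0, ci_level > 0, ci_level < 1,
            length(fpkm_bins) == 2L, fpkm_min >= 0,
            alpha > 0, alpha < 1, boot_reps >= 1, is.numeric(seed))
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(synthetic = synthetic, inputs = inputs,
                 ma_threshold = ma_threshold, ci_level = ci_level,
                 fpkm_bins = fpkm_bins, fpkm_min = fpkm_min,
                 alpha = alpha, tau = tau, boot_reps = boot_reps,
                 seed = seed, outdir = outdir, stages = stages,
                 pca_k = pca_k),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full cross-platform comparison pipeline
#'
#' Executes, in dependency order: data acquisition (synthetic simulation
#' or table ingestion), replicate collapsing, detection on both
#' platforms, gene alignment, and then the enabled stages -- concordance
#' (replicate QC, per-tissue cross-platform correlations, tissue
#' clustering, k-means/PCA ordination, top expressed genes), entropy
#' (tissue specificity with a cross-platform rank-sum comparison),
#' paralogs (pair correlations against the random-pair null on both
#' platforms), network (transforms, co-expression networks, similarity,
#' stringent-filter variant, mixed-platform bootstrap), and ec
#' (expression-conservation fit, divergence classification, low-
#' expression diagnostic, and -- for synthetic data -- recovery of the
#' injected divergent genes with an enrichment test).
#'
#' A stage failure aborts with an error naming the stage; when an output
#' directory is configured, artifacts written so far are retained along
#' with a `FAILED` marker. Rerunning with an identical configuration
#' reproduces the report.
#'
#' @param config a [run_config()] (or a YAML path).
#' @return A report list (also written as `report.json` when `outdir`
#'   is set) with one element per executed stage plus `parameters`,
#'   `attrition` (gene counts after each filter) and `warnings`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  report <- list(parameters = config_summary(config),
                 warnings = character(0), attrition = list())
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) {
        writeLines(paste("stage", name, "failed:", conditionMessage(e)),
                   file.path(outdir, "FAILED"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (config$boot_reps < 100) {
    report$warnings <- c(report$warnings,
                         sprintf("boot_reps = %d: p-value resolution 1/%d is coarser than alpha = %g",
                                 config$boot_reps, config$boot_reps + 1,
                                 config$alpha))
  }

  ## -- data -----------------------------------------------------------
  truth <- NULL
  stage("data", {
    if (!is.null(config$synthetic)) {
      truth <- generate_truth(config$synthetic)
      rnaseq <- simulate_rnaseq(truth)
      microarray <- simulate_microarray(truth)
      pairs <- truth$paralog_pairs
    } else {
      rnaseq <- read_expression_table(config$inputs$rnaseq, "rnaseq")
      microarray <- read_expression_table(config$inputs$microarray, "microarray")
      pairs <- if (!is.null(config$inputs$paralogs)) {
        utils::read.delim(config$inputs$paralogs, stringsAsFactors = FALSE)
      } else NULL
    }
    rs_coll <- collapse_replicates(rnaseq)
    ma_coll <- if (is_collapsed(microarray)) microarray else
      collapse_replicates(microarray)
  })
  note("data: %d RNA-Seq genes, %d microarray genes",
       nrow(rs_coll$values), nrow(ma_coll$values))

  ## -- detection and alignment ---------------------------------------
  stage("detection", {
    det_rs <- detect_expressed_rnaseq(rnaseq, config$ci_level,
                                       config$fpkm_bins)
    det_ma <- detect_expressed_microarray(ma_coll, config$ma_threshold,
                                           bins = config$fpkm_bins)
    aligned_all <- align_common_genes(rs_coll, ma_coll, "all_common")
    aligned_expr <- align_common_genes(rs_coll, ma_coll, "expressed_both",
                                        detections = list(det_rs, det_ma))
  })
  report$detection <- list(
    rnaseq_expressed = sum(det_rs$expressed),
    rnaseq_fraction = mean(det_rs$expressed),
    microarray_expressed = sum(det_ma$expressed),
    microarray_fraction = mean(det_ma$expressed))
  report$attrition$common_genes <- nrow(aligned_all$a$values)
  report$attrition$expressed_both <- nrow(aligned_expr$a$values)
  note("detection: %d genes expressed (RNA-Seq), %d (microarray); %d common, %d expressed on both",
       sum(det_rs$expressed), sum(det_ma$expressed),
       nrow(aligned_all$a$values), nrow(aligned_expr$a$values))
  if (!is.null(outdir)) {
    write_detection(det_rs, file.path(outdir, "detection_rnaseq.tsv"))
    write_detection(det_ma, file.path(outdir, "detection_microarray.tsv"))
  }

  ## -- concordance ----------------------------------------------------
  if ("concordance" %in% config$stages) stage("concordance", {
    repqc <- replicate_correlations(rnaseq)
    xcorr_all <- cross_platform_correlations(aligned_all$a, aligned_all$b)
    xcorr_expr <- cross_platform_correlations(aligned_expr$a, aligned_expr$b)
    dend <- cluster_tissues(rs_coll)
    pca <- pca_tissues(rs_coll, k = min(config$pca_k, nrow(rs_coll$values)),
                       seed = config$seed)
    top <- top_expressed_genes(rs_coll)
    report$concordance <- list(
      replicate_mean_r = repqc$mean_r, replicate_sd_r = repqc$sd_r,
      replicate_fraction_above = repqc$fraction_above,
      cross_platform_all = list(mean_r = xcorr_all$mean_r,
                                per_tissue = xcorr_all$per_tissue),
      cross_platform_expressed = list(mean_r = xcorr_expr$mean_r,
                                      per_tissue = xcorr_expr$per_tissue),
      pca_explained = pca$explained_variance[1:2],
      top_genes = lapply(top, function(d) d$gene_id))
    if (!is.null(outdir)) {
      utils::write.table(xcorr_expr$per_tissue,
                         file.path(outdir, "cross_platform_r.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_dendrogram_newick(dend, file.path(outdir, "tissue_dendrogram.nwk"))
      utils::write.table(data.frame(tissue = rownames(pca$scores),
                                    pca$scores[, 1:2]),
                         file.path(outdir, "pca_tissues.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  ## -- entropy --------------------------------------------------------
  if ("entropy" %in% config$stages) stage("entropy", {
    ent_rs <- entropy_profile(aligned_expr$a)
    ent_ma <- entropy_profile(aligned_expr$b)
    cmp <- compare_entropy_distributions(ent_rs, ent_ma)
    report$entropy <- list(
      rnaseq_median = stats::median(ent_rs$per_gene_entropy),
      microarray_median = stats::median(ent_ma$per_gene_entropy),
      U = cmp$U, p_value = cmp$p_value, more_specific = cmp$more_specific,
      excluded_rnaseq = length(ent_rs$excluded),
      excluded_microarray = length(ent_ma$excluded))
  })

  ## -- paralogs -------------------------------------------------------
  if ("paralogs" %in% config$stages && !is.null(pairs) && nrow(pairs) > 0)
    stage("paralogs", {
      t_rs <- transform_asinh(aligned_expr$a)
      t_ma <- transform_log2_floor(aligned_expr$b)
      rep_rs <- paralog_correlations(t_rs, pairs)
      rep_ma <- paralog_correlations(t_ma, pairs)
      n_null <- max(100L, 10L * nrow(pairs))
      rep_rs <- set_paralog_null(rep_rs, random_pair_null(
        t_rs, n_null, config$seed, exclude_pairs = pairs))
      rep_ma <- set_paralog_null(rep_ma, random_pair_null(
        t_ma, n_null, config$seed, exclude_pairs = pairs))
      report$paralogs <- list(
        n_pairs = nrow(rep_rs$pair_r),
        fraction_high_rnaseq = fraction_highly_correlated(rep_rs),
        fraction_high_microarray = fraction_highly_correlated(rep_ma))
    })

  ## -- network + ec ---------------------------------------------------
  net_genes <- NULL
  if (any(c("network", "ec") %in% config$stages)) stage("network", {
    keep <- network_gene_filter(rs_coll, ma_coll, det_ma)
    report$attrition$network_genes <- length(keep)
    t_rs <- transform_asinh(subset_genes(rs_coll, keep))
    t_ma <- transform_log2_floor(subset_genes(ma_coll, keep))
    net_genes <- keep
  })
  if ("network" %in% config$stages) stage("network", {
    nr <- fisher_normalize(build_network(t_rs, max_genes = Inf))
    nm <- fisher_normalize(build_network(t_ma, max_genes = Inf))
    sim <- network_similarity(nr, nm)
    filt <- stringent_expression_filter(
      expression_matrix(rs_coll$values[net_genes, , drop = FALSE],
                        rs_coll$tissues, NULL, "rnaseq"),
      config$fpkm_min)
    sim_filtered <- NA_real_
    if (length(filt$retained) >= 4) {
      sim_filtered <- network_similarity(
        fisher_normalize(build_network(subset_genes(t_rs, filt$retained),
                                       max_genes = Inf)),
        fisher_normalize(build_network(subset_genes(t_ma, filt$retained),
                                       max_genes = Inf)))
    }
    boot <- mixed_bootstrap(t_rs, t_ma, B = config$boot_reps,
                            seed = config$seed)
    report$network <- list(
      n_genes = length(net_genes),
      similarity = sim, similarity_fpkm_filtered = sim_filtered,
      removed_by_fpkm_filter = length(filt$removed),
      bootstrap_observed = boot$observed_similarity,
      bootstrap_percentile = boot$percentile_of_observed,
      bootstrap_null_quantiles = stats::quantile(boot$null_similarities,
                                                 c(.025, .5, .975)))
  })
  if ("ec" %in% config$stages) stage("ec", {
    fit <- ec_significance(t_ma, t_rs, B = config$boot_reps,
                           alpha = config$alpha, tau = config$tau,
                           seed = config$seed)
    div <- classify_divergent(fit,
                              microarray = sub_collapsed(ma_coll, net_genes),
                              rnaseq = sub_collapsed(rs_coll, net_genes))
    ec_report <- list(
      n_genes = nrow(fit$genes),
      n_flagged = sum(fit$genes$flagged),
      fraction_conserved = mean(!fit$genes$flagged),
      divergence_classes = as.list(div$counts),
      expression_clusters = as.list(div$cluster_counts))
    if (!is.null(truth)) {
      divergent_truth <- intersect(truth$divergent_genes, net_genes)
      flagged <- fit$genes$gene_id[fit$genes$flagged]
      enr <- enrichment_test(flagged, divergent_truth, net_genes)
      ec_report$truth_recovery <- list(
        n_divergent_in_network = length(divergent_truth),
        sensitivity = if (length(divergent_truth))
          mean(divergent_truth %in% flagged) else NA_real_,
        false_flag_rate = mean(setdiff(net_genes, truth$divergent_genes)
                               %in% flagged),
        enrichment_p = enr$p_value)
    }
    flagged <- fit$genes$gene_id[fit$genes$flagged]
    if (length(flagged) > 0 && length(flagged) < length(net_genes)) {
      lo <- low_expression_diagnostic(flagged,
                                      sub_collapsed(rs_coll, net_genes))
      ec_report$low_expression_p <- lo$p_value
    }
    report$ec <- ec_report
    if (!is.null(outdir)) {
      utils::write.table(div$genes, file.path(outdir, "ec_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  invisible(report)
}

sub_collapsed <- function(m, g) {
  expression_matrix(m$values[g, , drop = FALSE], m$tissues, NULL,
                    m$platform, m$units, m$transform)
}

config_summary <- function(config) {
  out <- unclass(config)
  out$synthetic <- if (!is.null(config$synthetic)) {
    s <- unclass(config$synthetic)
    s$tissue_groups <- lapply(s$tissue_groups, as.integer)
    s
  }
  out
}
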