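#' Configuration for the paired-platform synthetic generator
#'
#' Describes a study of `n_tissues` tissues (default 18) profiled in
#' `n_replicates` biological replicates (default 3) on two platforms that
#' observe the same latent transcriptome: negative-binomial RNA-Seq counts
#' converted to FPKM, and microarray intensities with a background floor,
#' a saturation ceiling and paralog cross-hybridization.
#'
#' Tissues are organized in groups (default: three consecutive groups,
#' emulating leaf-, seed- and endosperm-like clusters); tissues within a
#' group share all latent factor values, so they co-cluster. Latent
#' co-expression modules are blocks of genes loading on a shared tissue
#' factor. Three artifact classes provide ground-truth platform-divergent
#' genes: saturated genes whose true signal exceeds the microarray
#' ceiling in one tissue group, low-count genes whose RNA-Seq means are
#' scaled down until most tissues yield zero counts, and paralog pairs
#' whose probes bleed a fraction of the partner's signal into the
#' microarray measurement (by probe-mismatch class: 2-3 mismatches bleed
#' strongly, 5+ not at all).
#'
#' @param n_genes,n_tissues,n_replicates dimensions of the study.
#' @param n_modules number of latent co-expression modules.
#' @param tissue_groups list of integer vectors partitioning
#'   `1:n_tissues`; `NULL` for three near-equal consecutive groups.
#' @param module_size_range inclusive range of module sizes (genes).
#' @param paralog_fraction fraction of genes belonging to a paralog pair.
#' @param paralog_bleed named vector of bleed coefficients per mismatch
#'   class (default `c(mm2_3 = 0.3, mm5plus = 0)`).
#' @param frac_saturated fraction of genes with true expression above the
#'   microarray ceiling in one tissue group.
#' @param saturation_ceiling,background_floor,intensity_scale microarray
#'   response parameters (intensity units).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param depth_per_tissue sequencing depth in fragments; scalar or one
#'   value per tissue.
#' @param noise_sd log-scale SD of biological tissue noise; also the SD of
#'   the microarray multiplicative log-normal replicate noise.
#' @param frac_low_expressed fraction of genes in the low-count artifact
#'   class.
#' @param low_count_mu per-replicate expected read count for low-count
#'   genes.
#' @param length_range_kb transcript lengths are drawn log-uniform on this
#'   range (kb); short transcripts yield fewer fragments at equal molar
#'   abundance.
#' @param seed global seed; each operation derives its own sub-stream.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_tissues = 18, n_replicates = 3,
                             n_modules = 20, tissue_groups = NULL,
                             module_size_range = c(5, 20),
                             paralog_fraction = 0.05,
                             paralog_bleed = c(mm2_3 = 0.3, mm5plus = 0),
                             frac_saturated = 0.05,
                             saturation_ceiling = 65535,
                             background_floor = 50,
                             intensity_scale = 20,
                             nb_dispersion = 0.1,
                             depth_per_tissue = NULL,
                             noise_sd = 0.25,
                             frac_low_expressed = 0.05,
                             low_count_mu = 0.015,
                             length_range_kb = c(0.5, 5),
                             seed = 1) {
  if (is.null(depth_per_tissue)) {
    # sequencing depths span 5-28 million fragments; interleaved so that
    # depth does not align with the tissue-group structure
    d <- exp(seq(log(5e6), log(2.8e7), length.out = n_tissues))
    half <- ceiling(n_tissues / 2)
    ord <- as.vector(rbind(seq_len(half), n_tissues - seq_len(half) + 1L))
    depth_per_tissue <- d[order(ord[seq_len(n_tissues)])]
  }
  cfg <- list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
              n_replicates = as.integer(n_replicates),
              n_modules = as.integer(n_modules),
              tissue_groups = tissue_groups,
              module_size_range = as.integer(module_size_range),
              paralog_fraction = paralog_fraction,
              paralog_bleed = paralog_bleed,
              frac_saturated = frac_saturated,
              saturation_ceiling = saturation_ceiling,
              background_floor = background_floor,
              intensity_scale = intensity_scale,
              nb_dispersion = nb_dispersion,
              depth_per_tissue = rep_len(depth_per_tissue, n_tissues),
              noise_sd = noise_sd,
              frac_low_expressed = frac_low_expressed,
              low_count_mu = low_count_mu,
              length_range_kb = length_range_kb,
              seed = seed)
  if (is.null(cfg$tissue_groups)) {
    cfg$tissue_groups <- unname(split(seq_len(cfg$n_tissues),
                                      cut(seq_len(cfg$n_tissues), 3,
                                          labels = FALSE)))
  }
  with(cfg, {
    stopifnot(n_genes >= 1, n_tissues >= 1, n_replicates >= 1, n_modules >= 0,
              all(module_size_range >= 1),
              module_size_range[1] <= module_size_range[2],
              paralog_fraction >= 0, paralog_fraction <= 1,
              all(paralog_bleed >= 0), all(paralog_bleed < 1),
              frac_saturated >= 0, frac_saturated <= 1,
              frac_low_expressed >= 0, frac_low_expressed <= 1,
              saturation_ceiling > background_floor, background_floor > 0,
              nb_dispersion > 0, noise_sd >= 0,
              all(depth_per_tissue > 0))
  })
  if (!setequal(unlist(cfg$tissue_groups), seq_len(cfg$n_tissues))) {
    stop("tissue_groups must partition 1:n_tissues")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Configuration for an exchangeable-platform null study
#'
#' A [synthetic_config()] with every platform artifact disabled (no
#' saturation, no low-count genes, no paralog bleed), a negligible
#' microarray background floor and a negative-binomial dispersion whose
#' count-noise coefficient of variation matches the microarray's
#' log-normal replicate noise. Under this configuration the two
#' platforms are observations of the same truth with comparable noise,
#' the setting in which expression-conservation p-values should be
#' calibrated and the observed network similarity should fall inside
#' the mixed-platform null.
#'
#' @param n_genes,seed,... passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
exchangeable_config <- function(n_genes = 500, seed = 1, ...) {
  synthetic_config(n_genes = n_genes, seed = seed,
                   frac_saturated = 0, frac_low_expressed = 0,
                   paralog_fraction = 0,
                   background_floor = 1e-3, nb_dispersion = 0.0625, ...)
}

#' Generate the latent ground truth for a synthetic study
#'
#' Builds the gene x tissue latent log-expression surface as a gene
#' baseline plus module loading times tissue factor (factors shared by all
#' tissues of a group), assigns module memberships, paralog pairs with
#' contrasting tissue-group specificity, saturated genes and low-count
#' genes, and records the ground-truth set of platform-divergent genes
#' (genes carrying a saturation, low-count or probe-bleed artifact).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_truth` with elements
#'   `latent_log_expression` (gene x tissue, natural-log scale),
#'   `lengths_kb`, `module_of_gene`, `paralog_pairs` (data frame with
#'   `gene1`, `gene2`, `mismatch_class`), `saturated_genes`,
#'   `low_count_genes`, `divergent_genes`, `tissue_groups`, `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "truth"))
  G <- config$n_genes
  T <- config$n_tissues
  genes <- sprintf("g%05d", seq_len(G))
  tissues <- sprintf("tissue%02d", seq_len(T))
  grp_of <- integer(T)
  for (i in seq_along(config$tissue_groups)) {
    grp_of[config$tissue_groups[[i]]] <- i
  }
  ngrp <- length(config$tissue_groups)

  lengths_kb <- exp(stats::runif(G, log(config$length_range_kb[1]),
                                 log(config$length_range_kb[2])))
  baseline <- stats::rnorm(G, mean = log(30), sd = 1.2)

  # module memberships: consecutive blocks of sampled size
  size_choices <- seq(config$module_size_range[1], config$module_size_range[2])
  sizes <- if (length(size_choices) == 1L) {
    rep(size_choices, config$n_modules)
  } else {
    sample(size_choices, config$n_modules, replace = TRUE)
  }
  if (sum(sizes) > G) {
    stop("module sizes (", sum(sizes), " genes) exceed n_genes (", G, ")")
  }
  module_of_gene <- rep(NA_integer_, G)
  if (config$n_modules > 0) {
    module_of_gene[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  }

  # tissue factors: one value per (module, group), expanded to tissues
  mod_factor <- matrix(stats::rnorm(max(config$n_modules, 1) * ngrp), ncol = ngrp)
  loading <- stats::runif(G, 0.8, 1.2)
  # idiosyncratic gene profile for non-module genes, also group-structured
  own_factor <- matrix(stats::rnorm(G * ngrp), ncol = ngrp)

  latent <- matrix(baseline, G, T)
  for (t in seq_len(T)) {
    g <- grp_of[t]
    inmod <- !is.na(module_of_gene)
    latent[inmod, t] <- latent[inmod, t] +
      loading[inmod] * mod_factor[module_of_gene[inmod], g]
    latent[!inmod, t] <- latent[!inmod, t] + own_factor[!inmod, g]
  }

  free <- which(is.na(module_of_gene))  # artifacts live outside modules

  # paralog pairs: asymmetric donor/receiver with contrasting tissue-group
  # specificity. The donor (gene1) is strongly expressed in its group; the
  # receiver (gene2) is ~12-fold weaker, so mismatch-dependent probe bleed
  # from the donor dominates the receiver's microarray profile (the
  # cross-hybridization scenario in which the lowly expressed member of a
  # pair picks up its partner's tissue pattern)
  n_pairs <- floor(config$paralog_fraction * G / 2)
  paralog_pairs <- data.frame(gene1 = character(), gene2 = character(),
                              mismatch_class = character(),
                              stringsAsFactors = FALSE)
  par_idx <- integer(0)
  if (n_pairs > 0) {
    if (length(free) < 2 * n_pairs) stop("not enough non-module genes for paralog pairs")
    par_idx <- sample(free, 2 * n_pairs)
    free <- setdiff(free, par_idx)
    p1 <- par_idx[seq_len(n_pairs)]
    p2 <- par_idx[n_pairs + seq_len(n_pairs)]
    classes <- rep_len(names(config$paralog_bleed), n_pairs)
    for (i in seq_len(n_pairs)) {
      gA <- sample.int(ngrp, 1L)
      gB <- if (ngrp > 1) sample(setdiff(seq_len(ngrp), gA), 1L) else gA
      bd <- stats::rnorm(1, log(30) + 1.5, 0.8)
      latent[p1[i], ] <- bd + ifelse(grp_of == gA, 2.5, -2.5)
      latent[p2[i], ] <- (bd - 2.5) + ifelse(grp_of == gB, 2.5, -2.5)
    }
    paralog_pairs <- data.frame(gene1 = genes[p1], gene2 = genes[p2],
                                mismatch_class = classes,
                                stringsAsFactors = FALSE)
  }

  # saturated genes: expressed above the microarray ceiling in every
  # tissue, with a strong one-group RNA-Seq gradient (3.5 e-folds) that
  # the ceiling erases; the microarray reports a flat pinned profile
  n_sat <- floor(config$frac_saturated * G)
  sat_idx <- integer(0)
  if (n_sat > 0) {
    if (length(free) < n_sat) stop("not enough non-module genes for saturated set")
    sat_idx <- sample(free, n_sat)
    free <- setdiff(free, sat_idx)
    top <- log((config$saturation_ceiling - config$background_floor) /
                 config$intensity_scale)
    for (g in sat_idx) {
      gpk <- sample.int(ngrp, 1L)
      latent[g, ] <- top + 1 + ifelse(grp_of == gpk, 3.5, 0)
    }
  }

  # low-count genes: a real, strongly tissue-group-specific profile that
  # the microarray measures faithfully; the RNA-Seq simulation replaces
  # their NB means by a depth-scaled near-zero value, so their counts are
  # mostly zero with occasional one-read spikes in the deeper libraries
  n_low <- floor(config$frac_low_expressed * G)
  low_idx <- integer(0)
  if (n_low > 0) {
    if (length(free) < n_low) stop("not enough non-module genes for low-count set")
    low_idx <- sample(free, n_low)
    for (g in low_idx) {
      gpk <- sample.int(ngrp, 1L)
      latent[g, ] <- stats::rnorm(1, log(30), 1.2) +
        ifelse(grp_of == gpk, 2.5, -2.5)
    }
  }

  # biological tissue noise, shared by both platforms
  if (config$noise_sd > 0) {
    latent <- latent + matrix(stats::rnorm(G * T, 0, config$noise_sd), G, T)
  }
  dimnames(latent) <- list(genes, tissues)

  # ground-truth platform-divergent genes: saturation and low-count
  # victims plus the bleed-affected receivers (donors keep their own
  # dominant signal and stay essentially clean)
  bleed_classes <- names(config$paralog_bleed)[config$paralog_bleed > 0]
  bleed_genes <- paralog_pairs$gene2[paralog_pairs$mismatch_class %in%
                                       bleed_classes]
  divergent <- sort(unique(c(genes[sat_idx], genes[low_idx], bleed_genes)))

  structure(
    list(latent_log_expression = latent, lengths_kb = stats::setNames(lengths_kb, genes),
         module_of_gene = stats::setNames(module_of_gene, genes),
         paralog_pairs = paralog_pairs,
         saturated_genes = genes[sat_idx], low_count_genes = genes[low_idx],
         divergent_genes = divergent, tissue_groups = config$tissue_groups,
         tissue_group_of = grp_of, config = config),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes x %d tissues\n",
              nrow(x$latent_log_expression), ncol(x$latent_log_expression)))
  cat(sprintf("  modules: %d; paralog pairs: %d; saturated: %d; low-count: %d; divergent: %d\n",
              length(unique(stats::na.omit(x$module_of_gene))),
              nrow(x$paralog_pairs), length(x$saturated_genes),
              length(x$low_count_genes), length(x$divergent_genes)))
  invisible(x)
}

#' Simulate RNA-Seq FPKM replicates from a latent truth
#'
#' Per tissue and replicate, fragment counts are drawn negative-binomial
#' with mean `depth * p`, where `p` is the gene's share of
#' `exp(latent) * length_kb` (molar abundance times length). Low-count
#' genes have their means replaced by `low_count_mu` scaled by the
#' tissue's relative depth (depth-dependent dropout), so most tissues
#' yield zero counts while preserving count noise. FPKM uses an
#' upper-quartile library size, `1e6 * count / (n_genes *
#' upper-quartile count * length_kb)`, which keeps a handful of
#' extremely abundant transcripts from compressing everyone else's
#' values (`quartile_normalize = FALSE` divides by the raw total
#' instead).
#'
#' @param truth a [generate_truth()] result.
#' @param config the matching [synthetic_config()].
#' @param quartile_normalize upper-quartile library normalization
#'   (default TRUE).
#' @return An RNA-Seq `expr_matrix` with replicate columns.
#' @export
simulate_rnaseq <- function(truth, config = truth$config,
                            quartile_normalize = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(substream_seed(config$seed, "rnaseq"))
  lat <- truth$latent_log_expression
  G <- nrow(lat); T <- ncol(lat); R <- config$n_replicates
  len <- truth$lengths_kb
  low <- gene_ids_in(truth$low_count_genes, rownames(lat))
  vals <- matrix(0, G, T * R)
  tissues <- rep(colnames(lat), each = R)
  reps <- rep(seq_len(R), times = T)
  col <- 0L
  size <- 1 / config$nb_dispersion
  rel_depth <- config$depth_per_tissue / mean(config$depth_per_tissue)
  for (t in seq_len(T)) {
    w <- exp(lat[, t]) * len
    p <- w / sum(w)
    for (k in seq_len(R)) {
      mu <- config$depth_per_tissue[t] * p
      mu[low] <- config$low_count_mu * rel_depth[t]
      counts <- if (size > 1e8) stats::rpois(G, mu) else
        stats::rnbinom(G, mu = mu, size = size)
      lib <- if (quartile_normalize) {
        G * stats::quantile(counts, 0.75, names = FALSE)
      } else {
        sum(counts)
      }
      col <- col + 1L
      vals[, col] <- if (lib > 0) 1e6 * counts / (lib * len) else 0
    }
  }
  rownames(vals) <- rownames(lat)
  expression_matrix(vals, tissues, reps, "rnaseq")
}

gene_ids_in <- function(ids, universe) which(universe %in% ids)

#' Simulate microarray intensity replicates from a latent truth
#'
#' The noise-free intensity is
#' `min(ceiling, floor + scale * exp(latent) + sum of bleed * exp(partner latent))`,
#' where the bleed term adds, for each paralog partner, a
#' mismatch-class-dependent fraction of the partner's signal
#' (cross-hybridization). Each replicate multiplies this by log-normal
#' noise with log-scale SD `noise_sd`.
#'
#' @inheritParams simulate_rnaseq
#' @return A microarray `expr_matrix` with replicate columns.
#' @export
simulate_microarray <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(substream_seed(config$seed, "microarray"))
  lat <- truth$latent_log_expression
  G <- nrow(lat); T <- ncol(lat); R <- config$n_replicates
  E <- exp(lat)
  bleed <- matrix(0, G, T)
  pp <- truth$paralog_pairs
  if (nrow(pp) > 0) {
    for (i in seq_len(nrow(pp))) {
      b <- config$paralog_bleed[[pp$mismatch_class[i]]]
      if (b > 0) {
        i1 <- match(pp$gene1[i], rownames(lat))
        i2 <- match(pp$gene2[i], rownames(lat))
        bleed[i1, ] <- bleed[i1, ] + b * E[i2, ]
        bleed[i2, ] <- bleed[i2, ] + b * E[i1, ]
      }
    }
  }
  base <- pmin(config$background_floor + config$intensity_scale * E + bleed,
               config$saturation_ceiling)
  vals <- matrix(0, G, T * R)
  tissues <- rep(colnames(lat), each = R)
  reps <- rep(seq_len(R), times = T)
  col <- 0L
  for (t in seq_len(T)) {
    for (k in seq_len(R)) {
      col <- col + 1L
      noise <- if (config$noise_sd > 0)
        exp(stats::rnorm(G, 0, config$noise_sd)) else 1
      vals[, col] <- base[, t] * noise
    }
  }
  rownames(vals) <- rownames(lat)
  expression_matrix(vals, tissues, reps, "microarray")
}

#' Noise-free microarray response for a latent truth
#'
#' Exposes the deterministic part of [simulate_microarray()] (floor,
#' bleed, ceiling; no replicate noise), useful for verifying the response
#' model directly.
#'
#' @inheritParams simulate_rnaseq
#' @return gene x tissue intensity matrix.
#' @export
microarray_response <- function(truth, config = truth$config) {
  cfg0 <- config
  cfg0$noise_sd <- 0
  m <- simulate_microarray(truth, cfg0)
  collapse_replicates(m)$values
}

#' Write a synthetic dataset to disk
#'
#' One tab-delimited expression table per platform
#' (`rnaseq.tsv`, `microarray.tsv`, columns `<tissue>__rep<k>`), a
#' two-plus-one-column paralog-pair table (`paralogs.tsv`) and a JSON
#' truth sidecar (`truth.json`) with module memberships, artifact sets
#' and generator parameters.
#'
#' @param truth a [generate_truth()] result.
#' @param dir output directory (created if missing).
#' @param config the matching config.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir, config = truth$config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(simulate_rnaseq(truth, config),
                         file.path(dir, "rnaseq.tsv"))
  write_expression_table(simulate_microarray(truth, config),
                         file.path(dir, "microarray.tsv"))
  utils::write.table(truth$paralog_pairs, file.path(dir, "paralogs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    latent_log_expression = truth$latent_log_expression,
    lengths_kb = truth$lengths_kb,
    module_of_gene = truth$module_of_gene,
    saturated_genes = truth$saturated_genes,
    low_count_genes = truth$low_count_genes,
    divergent_genes = truth$divergent_genes,
    tissue_groups = truth$tissue_groups,
    config = unclass(config)
  )
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
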