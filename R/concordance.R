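correlation_report <- function(per_tissue, mean_r, sd_r, fraction_above,
                               excluded = character(0)) {
  structure(list(per_tissue = per_tissue, mean_r = mean_r, sd_r = sd_r,
                 fraction_above = fraction_above, excluded = excluded),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d correlations: mean r = %.3f (sd %.3f)\n",
              nrow(x$per_tissue), x$mean_r, x$sd_r))
  for (th in names(x$fraction_above)) {
    cat(sprintf("  fraction of r > %s: %.1f%%\n", th,
                100 * x$fraction_above[[th]]))
  }
  if (length(x$excluded)) {
    cat("  excluded (undefined r):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Replicate quality control correlations
#'
#' All pairwise Pearson correlations between replicates of each tissue,
#' computed on floored log2 values, with a summary (mean, SD, fraction of
#' correlations above a cutoff). Pairs involving a constant replicate
#' column have undefined r; they are reported and excluded from the
#' summary.
#'
#' @param m `expr_matrix` with at least 2 replicates per tissue.
#' @param cutoff threshold for the `fraction_above` summary (default
#'   0.95).
#' @return A `correlation_report`; `per_tissue` holds one row per
#'   replicate pair.
#' @export
replicate_correlations <- function(m, cutoff = 0.95) {
  if (is_collapsed(m)) stop("replicate columns required")
  v <- if (m$transform == "none") log2(pmax(m$values, 1)) else m$values
  rows <- list()
  excluded <- character(0)
  for (t in unique(m$tissues)) {
    idx <- which(m$tissues == t)
    if (length(idx) < 2L) next
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq((i + 1L), length(idx))) {
        a <- v[, idx[i]]; b <- v[, idx[j]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
          excluded <- c(excluded, sprintf("%s (rep %d vs %d)", t,
                                          m$replicates[idx[i]],
                                          m$replicates[idx[j]]))
          r <- NA_real_
        } else {
          r <- stats::cor(a, b)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(tissue = t, rep1 = m$replicates[idx[i]],
                     rep2 = m$replicates[idx[j]], r = r,
                     stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  ok <- df$r[!is.na(df$r)]
  if (length(excluded)) {
    message("correlation undefined (constant column) for: ",
            paste(excluded, collapse = "; "))
  }
  correlation_report(df, mean(ok), stats::sd(ok),
                     stats::setNames(list(mean(ok > cutoff)),
                                     as.character(cutoff)),
                     excluded)
}

#' Per-tissue cross-platform correlations
#'
#' Pearson correlation, per tissue, between the two platforms' floored
#' log2 expression values over the shared genes. Matrices must be aligned
#' with [align_common_genes()] and replicate-collapsed; untransformed
#' input is log2-floored internally.
#'
#' @param a,b aligned, replicate-collapsed `expr_matrix` objects with
#'   identical tissue sets.
#' @param cutoff threshold for the `fraction_above` summary (default
#'   0.7).
#' @return A `correlation_report`; `per_tissue` holds one row per tissue.
#' @export
cross_platform_correlations <- function(a, b, cutoff = 0.7) {
  stopifnot(is_collapsed(a), is_collapsed(b))
  if (!identical(gene_ids(a), gene_ids(b))) {
    stop("matrices must be aligned on the same genes (align_common_genes)")
  }
  if (nrow(a$values) < 3L) stop("need at least 3 genes")
  tis <- intersect(a$tissues, b$tissues)
  if (length(tis) == 0L) stop("no shared tissues")
  va <- if (a$transform == "none") log2(pmax(a$values, 1)) else a$values
  vb <- if (b$transform == "none") log2(pmax(b$values, 1)) else b$values
  r <- vapply(tis, function(t) stats::cor(va[, t], vb[, t]), numeric(1))
  df <- data.frame(tissue = tis, r = r, stringsAsFactors = FALSE)
  correlation_report(df, mean(r), stats::sd(r),
                     stats::setNames(list(mean(r > cutoff)),
                                     as.character(cutoff)))
}

#' Hierarchical clustering of tissues
#'
#' Complete-linkage agglomeration on the distance 1 - Pearson r between
#' tissue expression columns. Columns are ordered lexicographically by
#' tissue label before clustering so merges are reproducible regardless
#' of input column order.
#'
#' @param m replicate-collapsed `expr_matrix`, log2-floored values
#'   recommended (untransformed input is log2-floored internally).
#' @return An `hclust` object (n - 1 merges, non-decreasing heights).
#' @export
cluster_tissues <- function(m) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  if (ncol(m$values) < 2L) stop("need at least 2 tissues")
  v <- if (m$transform == "none") log2(pmax(m$values, 1)) else m$values
  v <- v[, order(colnames(v)), drop = FALSE]
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant tissue column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "complete")
}

#' Write a tissue dendrogram in Newick format
#'
#' @param hc an `hclust` from [cluster_tissues()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Tissue ordination by k-means then PCA
#'
#' Genes are first grouped into `k` clusters by k-means (fixed seed, 10
#' restarts, best within-cluster sum of squares); PCA is then run on the
#' tissues x cluster-centroid matrix after centering (optionally
#' scaling). This compresses the gene dimension before ordination of the
#' tissues.
#'
#' @param m replicate-collapsed `expr_matrix` (log2-floored values
#'   recommended; untransformed input is log2-floored internally).
#' @param k number of gene clusters (default 1000; reduced to the gene
#'   count with a warning when larger).
#' @param seed RNG seed for k-means restarts.
#' @param scale. scale centroid variables to unit variance before PCA.
#' @param nstart k-means restarts.
#' @return List of class `tissue_pca`: `scores` (tissue x PC
#'   coordinates), `explained_variance` (fractions, decreasing, summing
#'   to 1), `k`.
#' @export
pca_tissues <- function(m, k = 1000, seed = 1, scale. = FALSE, nstart = 10) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  v <- if (m$transform == "none") log2(pmax(m$values, 1)) else m$values
  uniq <- unique(v)
  n_distinct <- nrow(uniq)
  if (k >= n_distinct) {
    if (k > n_distinct) {
      warning("k (", k, ") exceeds the number of distinct gene profiles (",
              n_distinct, "); reducing")
    }
    # every distinct profile is its own cluster: skip k-means
    k <- n_distinct
    centers <- uniq
    key <- apply(v, 1L, paste, collapse = "\r")
    ukey <- apply(uniq, 1L, paste, collapse = "\r")
    sizes <- as.vector(table(factor(key, levels = ukey)))
  } else {
    set.seed(substream_seed(seed, "kmeans"))
    km <- suppressWarnings(stats::kmeans(v, centers = k, nstart = nstart,
                                         iter.max = 100))
    centers <- km$centers
    sizes <- km$size
  }
  pr <- stats::prcomp(t(centers), center = TRUE, scale. = scale.)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, explained_variance = ev, k = k,
                 cluster_sizes = sizes),
            class = "tissue_pca")
}

#' @export
print.tissue_pca <- function(x, ...) {
  cat(sprintf("<tissue_pca> %d tissues, %d gene clusters\n",
              nrow(x$scores), x$k))
  ev <- x$explained_variance
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * ev[1], 100 * ev[min(2, length(ev))]))
  invisible(x)
}

#' Top expressed genes per tissue
#'
#' The `n` genes with the highest expression in each tissue, descending,
#' ties broken by lexicographically smaller gene id.
#'
#' @param m replicate-collapsed `expr_matrix`.
#' @param n number of genes per tissue (default 10; capped at the gene
#'   count with a warning).
#' @return Named list of data frames (`gene_id`, `value`), one per
#'   tissue.
#' @export
top_expressed_genes <- function(m, n = 10) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  if (n > nrow(m$values)) {
    warning("n exceeds gene count; returning the full ranking")
    n <- nrow(m$values)
  }
  ids <- gene_ids(m)
  out <- lapply(m$tissues, function(t) {
    v <- m$values[, t]
    ord <- order(-v, ids)[seq_len(n)]
    data.frame(gene_id = ids[ord], value = v[ord],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  stats::setNames(out, m$tissues)
}
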