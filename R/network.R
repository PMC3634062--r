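#' Select genes for co-expression network analysis
#'
#' The network gene set: genes detected as expressed on the microarray,
#' with nonzero mean FPKM in at least one tissue, present on both
#' platforms and with a nonconstant profile on both (constant profiles
#' have undefined correlations).
#'
#' @param rnaseq,microarray replicate-collapsed, untransformed
#'   `expr_matrix` objects.
#' @param detection_ma a [detect_expressed_microarray()] result.
#' @return Character vector of gene ids.
#' @export
network_gene_filter <- function(rnaseq, microarray, detection_ma) {
  rs_ok <- gene_ids(rnaseq)[apply(rnaseq$values, 1L, max) > 0]
  ma_ok <- names(detection_ma$expressed)[detection_ma$expressed]
  keep <- intersect(intersect(rs_ok, ma_ok),
                    intersect(gene_ids(rnaseq), gene_ids(microarray)))
  nonconst <- apply(rnaseq$values[keep, , drop = FALSE], 1L, stats::sd) > 0 &
    apply(microarray$values[keep, , drop = FALSE], 1L, stats::sd) > 0
  keep[nonconst]
}

coexpr_network <- function(edges, stage, source) {
  structure(list(gene_ids = rownames(edges), edges = edges, stage = stage,
                 source = source),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("<coexpr_network> %d genes, stage %s (source: %s)\n",
              length(x$gene_ids), x$stage, x$source))
  w <- upper_tri_values(x$edges)
  cat(sprintf("  edge weights: mean %.3f, sd %.3f\n", mean(w), stats::sd(w)))
  invisible(x)
}

# internal: correlation network from a genes x tissues value matrix
cor_network_values <- function(v) stats::cor(t(v))

#' Build a co-expression network
#'
#' Edge weight between two genes is the Pearson correlation of their
#' expression profiles across tissues. Input must be replicate-collapsed
#' and already transformed (log2 floor for microarray, asinh for
#' RNA-Seq); constant gene profiles have undefined correlations and are
#' rejected by name.
#'
#' @param m transformed, replicate-collapsed `expr_matrix` with at least
#'   4 tissues.
#' @param max_genes guard against accidental quadratic blow-up (default
#'   5000).
#' @return A `coexpr_network` at stage `raw_r` (symmetric gene x gene
#'   matrix; the diagonal is excluded from all downstream statistics).
#' @export
build_network <- function(m, max_genes = 5000) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is_collapsed(m)) stop("collapse replicates before building a network")
  if (ncol(m$values) < 4L) stop("need at least 4 tissues")
  if (nrow(m$values) > max_genes) {
    stop("gene count ", nrow(m$values), " exceeds max_genes = ", max_genes)
  }
  sds <- apply(m$values, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene profile(s): ",
         paste(utils::head(gene_ids(m)[sds == 0], 10), collapse = ", "))
  }
  coexpr_network(cor_network_values(m$values), "raw_r", m$platform)
}

# internal: Fisher z + upper-triangle z-score standardization on a plain
# edge matrix; diagonal set to NA
fisher_normalize_values <- function(edges, eps = 1e-7, method = "zscore") {
  z <- atanh(pmin(pmax(edges, -1 + eps), 1 - eps))
  diag(z) <- NA_real_
  u <- upper_tri_values(z)
  if (method == "zscore") {
    (z - mean(u)) / stats::sd(u)
  } else {  # minmax
    (z - min(u)) / (max(u) - min(u))
  }
}

#' Fisher-transform and normalize network edges
#'
#' Applies the variance-stabilizing Fisher transform z = atanh(r) (r
#' clamped to within `eps` of +/-1) and then standardizes the edge
#' weights to mean 0, SD 1 over the upper triangle (`method = "minmax"`
#' rescales to [0, 1] instead). The transform is strictly monotone, so
#' edge ranking is preserved.
#'
#' @param net a `coexpr_network` at stage `raw_r`.
#' @param eps clamp distance from |r| = 1 (default 1e-7).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return A `coexpr_network` at stage `normalized` (diagonal `NA`).
#' @export
fisher_normalize <- function(net, eps = 1e-7, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "coexpr_network"))
  if (net$stage != "raw_r") stop("expected a stage 'raw_r' network")
  if (length(net$gene_ids) < 3L) stop("need at least 2 edges")
  coexpr_network(fisher_normalize_values(net$edges, eps, method),
                 "normalized", net$source)
}

#' Global similarity of two networks
#'
#' Pearson correlation between the upper-triangle edge-weight vectors of
#' two normalized networks over the same genes.
#'
#' @param a,b `coexpr_network` objects at stage `normalized`, identical
#'   gene ids and order.
#' @return Pearson R.
#' @export
network_similarity <- function(a, b) {
  if (!identical(a$gene_ids, b$gene_ids)) {
    stop("networks must share the same genes in the same order")
  }
  if (a$stage != "normalized" || b$stage != "normalized") {
    stop("normalize both networks first (fisher_normalize)")
  }
  stats::cor(upper_tri_values(a$edges), upper_tri_values(b$edges))
}

# internal driver shared by mixed_bootstrap and ec_significance: prepares
# the two value matrices (per-tissue standardization), computes observed
# normalized networks, and iterates complementary platform-mixed network
# pairs, invoking `collect(b, n1, n2)` with the normalized edge matrices.
# mixing = "coin": a fair coin per tissue decides which platform enters
# pseudo-dataset 1. mixing = "balanced": exactly floor(T/2) tissues are
# assigned platform A, so both pseudo-datasets are genuine mixtures and
# near-pure assignments are excluded from the null family.
mixed_platform_engine <- function(tA, tB, B, seed, standardize = TRUE,
                                  complementary = TRUE,
                                  mixing = c("coin", "balanced"), collect) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(tA, "expr_matrix"), inherits(tB, "expr_matrix"))
  if (!is_collapsed(tA) || !is_collapsed(tB)) {
    stop("collapse replicates before mixing")
  }
  if (!identical(gene_ids(tA), gene_ids(tB))) {
    stop("matrices must be aligned on the same genes")
  }
  if (!setequal(tA$tissues, tB$tissues)) stop("tissue sets differ")
  va <- tA$values[, tA$tissues, drop = FALSE]
  vb <- tB$values[, match(tA$tissues, tB$tissues), drop = FALSE]
  sda <- apply(va, 1L, stats::sd)
  sdb <- apply(vb, 1L, stats::sd)
  bad <- sda == 0 | sdb == 0
  if (any(bad)) {
    stop("constant gene profile(s): ",
         paste(utils::head(rownames(va)[bad], 10), collapse = ", "))
  }
  if (standardize) {
    va <- standardize_columns(va)
    vb <- standardize_columns(vb)
  }
  nT <- ncol(va)
  n1_obs <- fisher_normalize_values(cor_network_values(va))
  n2_obs <- fisher_normalize_values(cor_network_values(vb))
  assignments <- matrix(NA, B, nT, dimnames = list(NULL, tA$tissues))
  set.seed(substream_seed(seed, "mixed_bootstrap"))
  for (b in seq_len(B)) {
    coin <- if (mixing == "coin") {
      stats::runif(nT) < 0.5
    } else {
      x <- rep(FALSE, nT)
      x[sample.int(nT, nT %/% 2L)] <- TRUE
      x
    }
    m1 <- va
    m1[, !coin] <- vb[, !coin]
    if (complementary) {
      m2 <- vb
      m2[, !coin] <- va[, !coin]
    } else {
      coin2 <- stats::runif(nT) < 0.5
      m2 <- va
      m2[, !coin2] <- vb[, !coin2]
    }
    assignments[b, ] <- coin
    collect(b,
            fisher_normalize_values(cor_network_values(m1)),
            fisher_normalize_values(cor_network_values(m2)))
  }
  list(n1_obs = n1_obs, n2_obs = n2_obs, assignments = assignments,
       gene_ids = rownames(va))
}

#' Mixed-platform bootstrap null for network similarity
#'
#' Builds `B` random pairs of co-expression networks, each pair obtained
#' by assigning, per tissue and independently across replicates, one
#' platform's profile to the first pseudo-dataset and the other
#' platform's to the second (a fair coin per tissue; the two
#' pseudo-datasets are complementary by default). Each pseudo-network is
#' Fisher-transformed and normalized, the pair's similarity recorded,
#' and the observed similarity of the unmixed pair located within the
#' null.
#'
#' Before mixing, every tissue column of each transformed matrix is
#' standardized over genes (mean 0, SD 1) so mixed profiles are not
#' dominated by platform scale; the observed value uses the same
#' standardization (`standardize = FALSE` disables both).
#'
#' @param tA,tB transformed, replicate-collapsed, gene-aligned
#'   `expr_matrix` objects over the same tissues.
#' @param B bootstrap replicates (default 1000; below 100 a warning is
#'   issued).
#' @param seed RNG seed.
#' @param standardize per-tissue column standardization (default TRUE).
#' @param complementary complementary platform assignment (default TRUE;
#'   FALSE draws the second pseudo-dataset's coins independently).
#' @param mixing `"coin"` (default; a fair coin per tissue) or
#'   `"balanced"` (exactly half the tissues from each platform per
#'   pseudo-dataset).
#' @return List of class `mixed_bootstrap`: `observed_similarity`,
#'   `null_similarities` (length B), `B`, `percentile_of_observed`
#'   (fraction of null values at or below the observed), `assignments`
#'   (B x tissue logical matrix; TRUE = platform A enters pseudo-dataset
#'   1).
#' @export
mixed_bootstrap <- function(tA, tB, B = 1000, seed = 1, standardize = TRUE,
                            complementary = TRUE,
                            mixing = c("coin", "balanced")) {
  mixing <- match.arg(mixing)
  if (B < 100) warning("B < 100 gives a coarse null; interpret with care")
  sims <- numeric(B)
  eng <- mixed_platform_engine(tA, tB, B, seed, standardize, complementary,
                               mixing = mixing,
                               collect = function(b, n1, n2) {
                                 sims[b] <<- stats::cor(upper_tri_values(n1),
                                                        upper_tri_values(n2))
                               })
  obs <- stats::cor(upper_tri_values(eng$n1_obs), upper_tri_values(eng$n2_obs))
  structure(list(observed_similarity = obs, null_similarities = sims, B = B,
                 percentile_of_observed = mean(sims <= obs),
                 assignments = eng$assignments, seed = seed),
            class = "mixed_bootstrap")
}

#' @export
print.mixed_bootstrap <- function(x, ...) {
  q <- stats::quantile(x$null_similarities, c(0.025, 0.975))
  cat(sprintf("<mixed_bootstrap> B = %d\n", x$B))
  cat(sprintf("  observed similarity: %.4f (null central 95%%: %.4f-%.4f)\n",
              x$observed_similarity, q[1], q[2]))
  cat(sprintf("  percentile of observed: %.3f\n", x$percentile_of_observed))
  invisible(x)
}

#' @export
plot.mixed_bootstrap <- function(x, ...) {
  graphics::hist(x$null_similarities, breaks = 30,
                 main = "Mixed-platform null", xlab = "network similarity R",
                 xlim = range(c(x$null_similarities, x$observed_similarity)),
                 ...)
  graphics::abline(v = x$observed_similarity, col = "red", lwd = 2)
  invisible(x)
}
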