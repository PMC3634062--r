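#' Per-gene expression-conservation scores
#'
#' The EC score of a gene is the Pearson correlation between its
#' co-expression profiles (edge-weight row vectors) in two networks,
#' excluding the self-edge from both vectors. A low EC means the gene
#' has different neighbors in the two networks.
#'
#' @param a,b `coexpr_network` objects at stage `normalized`, same genes
#'   and order.
#' @return Named numeric vector of EC scores in [-1, 1]; `NA` where a
#'   gene's profile is constant in either network.
#' @export
ec_scores <- function(a, b) {
  if (!identical(a$gene_ids, b$gene_ids)) {
    stop("networks must share the same genes in the same order")
  }
  if (a$stage != "normalized" || b$stage != "normalized") {
    stop("normalize both networks first (fisher_normalize)")
  }
  r <- row_cors_excluding_diag(a$edges, b$edges)
  stats::setNames(r, a$gene_ids)
}

#' Network connectivity (degree) above a weight threshold
#'
#' Degree of a gene = number of off-diagonal edges in its row with
#' normalized weight at or above `tau` (inclusive).
#'
#' @param net `coexpr_network` at stage `normalized`.
#' @param tau normalized-weight threshold (default 2.0, i.e. edges about
#'   2 SD above the mean edge weight).
#' @return Named integer vector of degrees.
#' @export
connectivity <- function(net, tau = 2.0) {
  if (net$stage != "normalized") stop("normalize the network first")
  e <- net$edges
  diag(e) <- NA_real_
  stats::setNames(rowSums(e >= tau, na.rm = TRUE), net$gene_ids)
}

#' Fit per-gene expression conservation with a mixed-platform null
#'
#' The central model fit of the package. Given the two platforms'
#' transformed expression matrices for the same genes and tissues, it
#' (i) builds and normalizes both co-expression networks, (ii) computes
#' each gene's observed EC score between them, (iii) generates `B`
#' platform-mixed network pairs (see [mixed_bootstrap()]; balanced
#' mixing by default, so every pseudo-network is a genuine mixture) and
#' recomputes every gene's EC under each, and (iv) tests each observed
#' EC against the gene's null expectation. Low EC means
#' platform-divergent co-expression; genes with p < `alpha` are
#' flagged. Degrees in both observed networks (edges at or above `tau`)
#' and the similarity null are recorded as well.
#'
#' With the default `p_method = "moderated"`, the per-gene p-value is
#' the lower normal tail of a moderated z-statistic,
#' z = (EC_obs - mean(EC_null)) / sqrt(sd(EC_null)^2 + tau0^2),
#' where tau0 is the 75th percentile of the per-gene null SDs. The
#' moderation keeps genes with near-degenerate (tiny-SD) nulls from
#' being flagged on trivial deviations, in the spirit of moderated
#' t-statistics. `p_method = "empirical"` instead uses the
#' add-one-corrected empirical tail p = (1 + #\{null EC <= observed\}) /
#' (B + 1); at common choices of `B` its resolution is too coarse to
#' clear a small `alpha` unless the observed EC falls below essentially
#' the entire null sample.
#'
#' @inheritParams mixed_bootstrap
#' @param alpha significance level for flagging (default 0.01).
#' @param tau connectivity threshold on normalized edge weights.
#' @param p_method `"moderated"` (default) or `"empirical"`; see
#'   Details.
#' @param two_sided use 2 * min(lower, upper) tail probabilities instead
#'   of the lower tail only.
#' @return An object of class `ec_fit`; see [summary.ec_fit()]. Key
#'   elements: `genes` (data frame with `ec`, `null_mean`, `null_sd`,
#'   `p`, `flagged`, `degree_a`, `degree_b`), `observed_similarity`,
#'   `null_similarities`, `B`, `alpha`, `tau`, `seed`.
#' @export
ec_significance <- function(tA, tB, B = 1000, alpha = 0.01, tau = 2.0,
                            seed = 1, standardize = TRUE,
                            complementary = TRUE,
                            mixing = c("balanced", "coin"),
                            p_method = c("moderated", "empirical"),
                            two_sided = FALSE) {
  mixing <- match.arg(mixing)
  p_method <- match.arg(p_method)
  if (B < 100) {
    warning("B = ", B, " gives p-value resolution 1/", B + 1,
            "; too coarse for alpha = ", alpha)
  }
  G <- nrow(tA$values)
  count_le <- numeric(G)
  count_ge <- numeric(G)
  sum1 <- numeric(G)
  sum2 <- numeric(G)
  sims <- numeric(B)
  ec_obs <- NULL
  collect <- function(b, n1, n2) {
    ecb <- row_cors_excluding_diag(n1, n2)
    count_le <<- count_le + (ecb <= ec_obs)
    count_ge <<- count_ge + (ecb >= ec_obs)
    sum1 <<- sum1 + ecb
    sum2 <<- sum2 + ecb^2
    sims[b] <<- stats::cor(upper_tri_values(n1), upper_tri_values(n2))
  }
  # observed EC must exist before the engine starts collecting, so run
  # the observed-network computation first via a two-phase call
  eng_pre <- mixed_platform_engine(tA, tB, B = 0, seed = seed,
                                   standardize = standardize,
                                   complementary = complementary,
                                   mixing = mixing,
                                   collect = function(...) NULL)
  ec_obs <- row_cors_excluding_diag(eng_pre$n1_obs, eng_pre$n2_obs)
  eng <- mixed_platform_engine(tA, tB, B = B, seed = seed,
                               standardize = standardize,
                               complementary = complementary,
                               mixing = mixing,
                               collect = collect)
  null_mean <- sum1 / B
  null_sd <- sqrt(pmax(0, (sum2 - B * null_mean^2) / (B - 1)))
  if (p_method == "moderated") {
    tau0 <- stats::quantile(null_sd, 0.75, names = FALSE, na.rm = TRUE)
    denom <- sqrt(null_sd^2 + tau0^2)
    z <- (ec_obs - null_mean) / denom
    # degenerate null (e.g. identical inputs): no evidence unless the
    # observed EC falls strictly below the point-mass null
    zero <- !is.na(denom) & denom == 0
    z[zero] <- ifelse(ec_obs[zero] < null_mean[zero], -Inf, Inf)
    p_low <- stats::pnorm(z)
    p_high <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    p_low <- (1 + count_le) / (B + 1)
    p_high <- (1 + count_ge) / (B + 1)
  }
  p <- if (two_sided) pmin(1, 2 * pmin(p_low, p_high)) else p_low
  net_a <- coexpr_network(eng$n1_obs, "normalized", tA$platform)
  net_b <- coexpr_network(eng$n2_obs, "normalized", tB$platform)
  deg_a <- connectivity(net_a, tau)
  deg_b <- connectivity(net_b, tau)
  genes <- data.frame(gene_id = eng$gene_ids, ec = ec_obs,
                      null_mean = null_mean, null_sd = null_sd, p = p,
                      flagged = p < alpha, degree_a = as.integer(deg_a),
                      degree_b = as.integer(deg_b),
                      stringsAsFactors = FALSE, row.names = NULL)
  obs_sim <- stats::cor(upper_tri_values(eng$n1_obs),
                        upper_tri_values(eng$n2_obs))
  structure(list(genes = genes, network_a = net_a, network_b = net_b,
                 observed_similarity = obs_sim, null_similarities = sims,
                 assignments = eng$assignments,
                 B = B, alpha = alpha, tau = tau, seed = seed,
                 platform_a = tA$platform, platform_b = tB$platform,
                 mixing = mixing, p_method = p_method,
                 two_sided = two_sided,
                 call = match.call()),
            class = "ec_fit")
}

#' @export
print.ec_fit <- function(x, ...) {
  cat(sprintf("<ec_fit> %d genes, %s vs %s, B = %d\n",
              nrow(x$genes), x$platform_a, x$platform_b, x$B))
  cat(sprintf("  conserved (p >= %g): %d (%.1f%%); divergent: %d\n",
              x$alpha, sum(!x$genes$flagged),
              100 * mean(!x$genes$flagged), sum(x$genes$flagged)))
  cat(sprintf("  network similarity R = %.3f (null central 95%%: %.3f-%.3f)\n",
              x$observed_similarity,
              stats::quantile(x$null_similarities, 0.025),
              stats::quantile(x$null_similarities, 0.975)))
  invisible(x)
}

#' Summarize an expression-conservation fit
#'
#' @param object an `ec_fit`.
#' @param ... unused.
#' @return List with counts of conserved/divergent genes, EC score
#'   quantiles, the observed network similarity and the null summary.
#' @export
summary.ec_fit <- function(object, ...) {
  g <- object$genes
  out <- list(
    n_genes = nrow(g),
    n_flagged = sum(g$flagged),
    fraction_conserved = mean(!g$flagged),
    ec_quantiles = stats::quantile(g$ec, c(0, .25, .5, .75, 1), na.rm = TRUE),
    observed_similarity = object$observed_similarity,
    null_similarity_range = range(object$null_similarities),
    B = object$B, alpha = object$alpha, tau = object$tau
  )
  class(out) <- "summary.ec_fit"
  out
}

#' @export
print.summary.ec_fit <- function(x, ...) {
  cat(sprintf("Expression conservation: %d genes, %d divergent (%.1f%% conserved)\n",
              x$n_genes, x$n_flagged, 100 * x$fraction_conserved))
  cat("EC quantiles:\n")
  print(round(x$ec_quantiles, 4))
  cat(sprintf("Network similarity R = %.4f; null range %.4f-%.4f (B = %d)\n",
              x$observed_similarity, x$null_similarity_range[1],
              x$null_similarity_range[2], x$B))
  invisible(x)
}

#' @export
coef.ec_fit <- function(object, ...) {
  stats::setNames(object$genes$ec, object$genes$gene_id)
}

#' @export
plot.ec_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$genes$ec, breaks = 40, main = "EC scores",
                 xlab = "EC (per-gene network-profile correlation)")
  graphics::abline(v = stats::quantile(x$genes$ec[x$genes$flagged], 1,
                                       na.rm = TRUE),
                   col = "red", lty = 2)
  graphics::plot(x$genes$degree_a, x$genes$degree_b,
                 col = ifelse(x$genes$flagged, "red", "grey50"),
                 xlab = paste("degree,", x$platform_a),
                 ylab = paste("degree,", x$platform_b),
                 main = "Connectivity")
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Classify divergent genes by connectivity and expression pattern
#'
#' Flagged genes are classed `more_in_a` when their degree in network A
#' is at least `2 * degree_b + margin` (symmetrically `more_in_b`), else
#' `similar`. Two expression-defined clusters of divergent genes are
#' also reported: cluster (i), genes high on both platforms with mean
#' microarray intensity at or above the saturation quantile (signal
#' clipped at the platform ceiling); and cluster (ii), genes with an
#' exactly zero median RNA-Seq FPKM but a range of microarray values
#' (low-count genes whose RNA-Seq correlations are count noise).
#'
#' @param fit an `ec_fit` (network A conventionally the microarray).
#' @param microarray replicate-collapsed, untransformed microarray
#'   `expr_matrix`.
#' @param rnaseq replicate-collapsed, untransformed RNA-Seq
#'   `expr_matrix` (FPKM).
#' @param margin additive margin of the degree-dominance rule (default
#'   5).
#' @param sat_quantile saturation quantile of the mean microarray
#'   intensity (default 0.99).
#' @return List of class `divergence_report`: `genes` (data frame with
#'   `divergence_class`, `cluster`), `counts` (per class), plus the rule
#'   parameters.
#' @export
classify_divergent <- function(fit, microarray, rnaseq, margin = 5,
                               sat_quantile = 0.99) {
  stopifnot(inherits(fit, "ec_fit"))
  g <- fit$genes
  cls <- rep("similar", nrow(g))
  cls[g$degree_a >= 2 * g$degree_b + margin] <- "more_in_a"
  cls[g$degree_b >= 2 * g$degree_a + margin] <- "more_in_b"
  cls[!g$flagged] <- NA_character_

  ma_mean <- rowMeans(microarray$values)[g$gene_id]
  rs_med <- apply(rnaseq$values, 1L, stats::median)[g$gene_id]
  rs_mean <- rowMeans(rnaseq$values)[g$gene_id]
  sat_cut <- stats::quantile(ma_mean, sat_quantile, na.rm = TRUE)
  cluster <- rep(NA_character_, nrow(g))
  cluster[g$flagged & ma_mean >= sat_cut &
            rs_mean >= stats::median(rs_mean, na.rm = TRUE)] <- "saturated_high"
  cluster[g$flagged & rs_med == 0] <- "rnaseq_near_zero"
  out <- data.frame(g, divergence_class = cls, cluster = cluster,
                    stringsAsFactors = FALSE)
  structure(list(genes = out,
                 counts = table(factor(cls[g$flagged],
                                       c("more_in_a", "more_in_b", "similar"))),
                 cluster_counts = table(factor(cluster[g$flagged],
                                               c("saturated_high",
                                                 "rnaseq_near_zero"))),
                 margin = margin, sat_quantile = sat_quantile,
                 sat_cut = unname(sat_cut)),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report> flagged-gene connectivity classes:\n")
  print(x$counts)
  cat("expression clusters among flagged genes:\n")
  print(x$cluster_counts)
  invisible(x)
}

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a flagged gene set and an annotated gene set drawn from a
#' common universe.
#'
#' @param flagged,annotated,universe character vectors of gene ids;
#'   `flagged` and `annotated` must be subsets of `universe`.
#' @return List: `overlap`, `expected`, `p_value`.
#' @export
enrichment_test <- function(flagged, annotated, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(flagged %in% universe) || !all(annotated %in% universe)) {
    stop("flagged and annotated must be subsets of the universe")
  }
  flagged <- unique(flagged); annotated <- unique(annotated)
  k <- length(intersect(flagged, annotated))
  p <- stats::phyper(k - 1, length(annotated),
                     length(universe) - length(annotated),
                     length(flagged), lower.tail = FALSE)
  list(overlap = k,
       expected = length(flagged) * length(annotated) / length(universe),
       p_value = p)
}

#' Are these genes expressed lower than the rest of the genome?
#'
#' One-sided Mann-Whitney U test that the mean expression of a gene set
#' is lower than that of the remaining genes, as used to diagnose
#' spurious co-expression driven by low-count genes.
#'
#' @param genes character vector, a strict nonempty subset of the
#'   matrix's genes.
#' @param m replicate-collapsed RNA-Seq `expr_matrix` (untransformed).
#' @return List: `p_value` (one-sided, "less"), `median_set`,
#'   `median_rest`, `n_set`, `n_rest`.
#' @export
low_expression_diagnostic <- function(genes, m) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  all_ids <- gene_ids(m)
  genes <- intersect(genes, all_ids)
  rest <- setdiff(all_ids, genes)
  if (length(genes) == 0) stop("empty gene set")
  if (length(rest) == 0) stop("gene set equals the whole universe")
  mu <- rowMeans(m$values)
  wt <- suppressWarnings(stats::wilcox.test(mu[genes], mu[rest],
                                            alternative = "less"))
  list(p_value = wt$p.value, median_set = stats::median(mu[genes]),
       median_rest = stats::median(mu[rest]),
       n_set = length(genes), n_rest = length(rest))
}
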