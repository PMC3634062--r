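#' Shannon entropy of a tissue expression profile
#'
#' H = -sum p_t log2 p_t with p_t = x_t / sum(x), the standard
#' tissue-specificity index: 0 bits for expression confined to a single
#' tissue, log2(T) bits for a uniform profile. Computed on the linear
#' expression scale.
#'
#' @param profile nonnegative expression vector (one value per tissue)
#'   with at least one positive entry.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(profile) {
  if (any(profile < 0)) stop("negative expression value")
  s <- sum(profile)
  if (s == 0) stop("all-zero profile: entropy undefined")
  p <- profile / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-gene tissue-specificity entropy for a platform
#'
#' Applies [shannon_entropy()] to every gene of a replicate-collapsed
#' matrix; all-zero genes are excluded and reported. Entropy is computed
#' on the linear scale by default (`log_scale = TRUE` uses the values as
#' given).
#'
#' @param m replicate-collapsed `expr_matrix` (untransformed).
#' @param genes optional subset of gene ids (e.g. the expressed set).
#' @return List of class `entropy_result`: `per_gene_entropy` (named,
#'   bits), `platform`, `excluded` (all-zero gene ids).
#' @export
entropy_profile <- function(m, genes = NULL) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  v <- m$values
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  tot <- rowSums(v)
  excluded <- rownames(v)[tot == 0]
  v <- v[tot > 0, , drop = FALSE]
  h <- apply(v, 1L, shannon_entropy)
  structure(list(per_gene_entropy = h, platform = m$platform,
                 n_tissues = ncol(v), excluded = excluded),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> %s: %d genes, median H = %.3f bits (max %.3f)\n",
              x$platform, length(x$per_gene_entropy),
              stats::median(x$per_gene_entropy), log2(x$n_tissues)))
  if (length(x$excluded)) cat("  excluded all-zero genes:", length(x$excluded), "\n")
  invisible(x)
}

#' Compare two entropy distributions
#'
#' Mann-Whitney U (Wilcoxon rank-sum) test on the per-gene entropies of
#' two platforms over their shared gene universe: exact null when the
#' combined sample size is at most 20 (and no ties), normal
#' approximation with tie correction otherwise. Reports which platform
#' has the lower median entropy, i.e. the more tissue-specific profiles.
#'
#' @param a,b `entropy_result` objects, or plain numeric entropy
#'   samples.
#' @param shared restrict to the gene-id intersection (default TRUE;
#'   FALSE compares the full samples).
#' @return List: `U`, `p_value` (two-sided), `more_specific` (platform
#'   tag with lower median entropy, or `"tie"`), `median_a`, `median_b`,
#'   `n_a`, `n_b`.
#' @export
compare_entropy_distributions <- function(a, b, shared = TRUE) {
  if (is.numeric(a)) a <- list(per_gene_entropy = a, platform = "a")
  if (is.numeric(b)) b <- list(per_gene_entropy = b, platform = "b")
  ha <- a$per_gene_entropy
  hb <- b$per_gene_entropy
  if (shared && !is.null(names(ha)) && !is.null(names(hb))) {
    common <- intersect(names(ha), names(hb))
    if (length(common) >= 2L) {
      ha <- ha[common]
      hb <- hb[common]
    }
  }
  if (length(ha) < 2L || length(hb) < 2L) {
    stop("need at least 2 entropy values per platform")
  }
  exact <- (length(ha) + length(hb)) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(ha, hb, exact = exact,
                                            correct = !exact))
  med_a <- stats::median(ha)
  med_b <- stats::median(hb)
  more <- if (med_a < med_b) a$platform else if (med_b < med_a) b$platform else "tie"
  list(U = unname(wt$statistic), p_value = wt$p.value, more_specific = more,
       median_a = med_a, median_b = med_b,
       n_a = length(ha), n_b = length(hb))
}

#' Within-platform correlation of paralog pairs
#'
#' Pearson correlation across tissues between the expression profiles of
#' the two members of each paralog pair. Pairs with a missing or
#' constant-profile member are skipped and reported.
#'
#' @param m replicate-collapsed `expr_matrix`, platform-appropriate
#'   transform applied (log2 for microarray, asinh for RNA-Seq).
#' @param pairs data frame with columns `gene1`, `gene2` (optionally
#'   `mismatch_class`).
#' @return List of class `paralog_report`: `pair_r` (data frame with the
#'   pair columns plus `r`), `skipped` (row indices), plus null summary
#'   slots filled by [random_pair_null()] / the caller.
#' @export
paralog_correlations <- function(m, pairs) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  v <- m$values
  keep <- logical(nrow(pairs))
  r <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    if (!(g1 %in% rownames(v)) || !(g2 %in% rownames(v))) next
    x <- v[g1, ]; y <- v[g2, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r[i] <- stats::cor(x, y)
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no usable paralog pairs")
  if (any(!keep)) {
    message(sum(!keep), " pair(s) skipped (missing or constant member)")
  }
  out <- pairs[keep, , drop = FALSE]
  out$r <- r[keep]
  structure(list(pair_r = out, skipped = which(!keep), platform = m$platform,
                 null_mean = NULL, null_sd = NULL, null_n = NULL),
            class = "paralog_report")
}

#' Random gene-pair correlation null
#'
#' Samples unordered gene pairs uniformly (no self-pairs; listed paralog
#' pairs excluded) and computes the same across-tissue Pearson
#' correlation, summarizing the null by its mean and SD.
#'
#' @inheritParams paralog_correlations
#' @param n_pairs number of random pairs (>= 100).
#' @param seed RNG seed.
#' @param exclude_pairs data frame of pairs to exclude (`gene1`,
#'   `gene2`), e.g. the paralog list.
#' @return List: `null_mean`, `null_sd`, `null_n`, `sample` (data frame
#'   `gene1`, `gene2`, `r`).
#' @export
random_pair_null <- function(m, n_pairs, seed = 1, exclude_pairs = NULL) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  v <- m$values
  usable <- rownames(v)[apply(v, 1L, stats::sd) > 0]
  if (length(usable) < 20L) stop("need a gene universe of at least 20")
  if (n_pairs < 100L) stop("n_pairs must be at least 100")
  banned <- character(0)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs) > 0) {
    banned <- c(paste(exclude_pairs$gene1, exclude_pairs$gene2, sep = "\r"),
                paste(exclude_pairs$gene2, exclude_pairs$gene1, sep = "\r"))
  }
  set.seed(substream_seed(seed, "random_pairs"))
  g1 <- character(n_pairs); g2 <- character(n_pairs)
  n_done <- 0L
  while (n_done < n_pairs) {
    pick <- sample(usable, 2L)
    if (paste(pick[1L], pick[2L], sep = "\r") %in% banned) next
    n_done <- n_done + 1L
    g1[n_done] <- pick[1L]; g2[n_done] <- pick[2L]
  }
  r <- vapply(seq_len(n_pairs),
              function(i) stats::cor(v[g1[i], ], v[g2[i], ]), numeric(1))
  list(null_mean = mean(r), null_sd = stats::sd(r), null_n = n_pairs,
       sample = data.frame(gene1 = g1, gene2 = g2, r = r,
                           stringsAsFactors = FALSE))
}

#' Attach a random-pair null to a paralog report
#'
#' @param report a `paralog_report`.
#' @param null a [random_pair_null()] result.
#' @return The report with `null_mean`, `null_sd`, `null_n` filled in.
#' @export
set_paralog_null <- function(report, null) {
  report$null_mean <- null$null_mean
  report$null_sd <- null$null_sd
  report$null_n <- null$null_n
  report
}

#' Fraction of paralog pairs above the 2-SD rule
#'
#' Proportion of pairs whose correlation exceeds the random-pair null
#' mean by more than `k` null standard deviations (default 2).
#'
#' @param report a `paralog_report` with the null summary attached.
#' @param k number of null SDs (default 2).
#' @return Proportion in [0, 1].
#' @export
fraction_highly_correlated <- function(report, k = 2) {
  if (is.null(report$null_mean) || is.null(report$null_sd)) {
    stop("attach a random-pair null first (set_paralog_null)")
  }
  mean(report$pair_r$r > report$null_mean + k * report$null_sd)
}

#' @export
print.paralog_report <- function(x, ...) {
  cat(sprintf("<paralog_report> %s: %d pairs, median r = %.3f\n",
              x$platform, nrow(x$pair_r), stats::median(x$pair_r$r)))
  if (!is.null(x$null_mean)) {
    cat(sprintf("  null: %.3f +/- %.3f (n = %d); fraction > mean + 2 SD: %.1f%%\n",
                x$null_mean, x$null_sd, x$null_n,
                100 * fraction_highly_correlated(x)))
  }
  invisible(x)
}
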