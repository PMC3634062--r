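detection_result <- function(expressed, level_by_tissue, criterion) {
  structure(list(expressed = expressed, level_by_tissue = level_by_tissue,
                 criterion = criterion),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d genes, %d expressed (%.1f%%)\n",
              length(x$expressed), sum(x$expressed),
              100 * mean(x$expressed)))
  cat("  criterion:", x$criterion, "\n")
  invisible(x)
}

#' Detect expressed genes from RNA-Seq replicates
#'
#' A gene is called expressed in a tissue when the lower bound of the
#' two-sided t confidence interval for its mean FPKM across replicates is
#' strictly greater than zero, and expressed overall when that holds in at
#' least one tissue. With identical positive replicates the standard
#' deviation is zero and the lower bound equals the mean, so the gene is
#' expressed; an all-zero tissue has lower bound zero and is not.
#'
#' Per-tissue expression levels are binned with
#' [classify_expression_level()] on the replicate-mean FPKM, with tissues
#' failing the confidence criterion set to `none`.
#'
#' @param m RNA-Seq `expr_matrix` with at least 2 replicates per tissue.
#' @param confidence confidence level of the interval (default 0.95).
#' @param bins passed to [classify_expression_level()].
#' @return A `detection_result` with `expressed` (named logical),
#'   `level_by_tissue` (gene x tissue character matrix) and a criterion
#'   descriptor.
#' @export
detect_expressed_rnaseq <- function(m, confidence = 0.95, bins = c(5, 200)) {
  if (is_collapsed(m)) {
    stop("replicate columns required; supply a precomputed lower bound ",
         "for replicate-collapsed input")
  }
  tis <- unique(m$tissues)
  nrep <- table(m$tissues)
  if (any(nrep < 2L)) {
    stop("at least 2 replicates per tissue are required; supply a ",
         "precomputed lower bound instead for: ",
         paste(names(nrep)[nrep < 2L], collapse = ", "))
  }
  G <- nrow(m$values)
  lower <- means <- matrix(0, G, length(tis), dimnames = list(gene_ids(m), tis))
  for (t in tis) {
    v <- m$values[, m$tissues == t, drop = FALSE]
    n <- ncol(v)
    mu <- rowMeans(v)
    sdv <- sqrt(rowSums((v - mu)^2) / (n - 1L))
    tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 1L)
    lower[, t] <- mu - tq * sdv / sqrt(n)
    means[, t] <- mu
  }
  detected <- lower > 0
  levels_mat <- matrix("none", G, length(tis), dimnames = list(gene_ids(m), tis))
  lv <- as.character(classify_expression_level(means[detected], bins))
  levels_mat[detected] <- lv
  expressed <- apply(detected, 1L, any)
  detection_result(expressed, levels_mat,
                   sprintf("FPKM %g%% CI lower bound > 0 in >= 1 tissue",
                           100 * confidence))
}

#' Detect expressed genes from microarray intensities
#'
#' A gene is expressed when its mean intensity strictly exceeds
#' `threshold` (default 200) in at least one tissue; with
#' `strict = FALSE`, at-threshold values count as expressed.
#'
#' Per-tissue levels reuse the FPKM bin rule on the intensity scale, with
#' tissues at or below the detection threshold set to `none` (only
#' `medium`/`high` are reachable above an intensity threshold of 200).
#'
#' @param m replicate-collapsed microarray `expr_matrix`.
#' @param threshold intensity detection threshold.
#' @param strict use strict `>` (default) or `>=`.
#' @param bins passed to [classify_expression_level()].
#' @return A `detection_result`.
#' @export
detect_expressed_microarray <- function(m, threshold = 200, strict = TRUE,
                                        bins = c(5, 200)) {
  if (!is_collapsed(m)) m <- collapse_replicates(m)
  v <- m$values
  detected <- if (strict) v > threshold else v >= threshold
  levels_mat <- matrix("none", nrow(v), ncol(v),
                       dimnames = list(gene_ids(m), m$tissues))
  levels_mat[detected] <-
    as.character(classify_expression_level(v[detected], bins))
  expressed <- apply(detected, 1L, any)
  detection_result(expressed, levels_mat,
                   sprintf("mean intensity %s %g in >= 1 tissue",
                           if (strict) ">" else ">=", threshold))
}

#' Write a detection result as TSV
#'
#' One row per gene: expressed flag followed by the per-tissue level bins.
#'
#' @param d a `detection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detection <- function(d, path) {
  df <- data.frame(gene_id = names(d$expressed), expressed = d$expressed,
                   d$level_by_tissue, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
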