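#' Floored log2 transform
#'
#' Replaces every value below 1 by 1 before taking log2, so that weakly
#' expressed genes map to 0 rather than to large negative values. This is
#' the conventional transform for microarray intensities and for FPKM in
#' correlation work.
#'
#' @param m an `expr_matrix` with `transform == "none"`.
#' @return The transformed `expr_matrix`, tagged `"log2"`.
#' @export
transform_log2_floor <- function(m) {
  if (m$transform != "none") {
    stop("matrix already transformed ('", m$transform, "'); refusing to re-transform")
  }
  v <- log2(pmax(m$values, 1))
  expression_matrix(v, m$tissues, m$replicates, m$platform,
                    units = "log2", transform = "log2")
}

#' Inverse hyperbolic sine transform
#'
#' asinh(x) = ln(x + sqrt(x^2 + 1)) compresses large values more strongly
#' than small ones and is well behaved below 1, which suits the wide
#' dynamic range of RNA-Seq FPKM.
#'
#' @inheritParams transform_log2_floor
#' @return The transformed `expr_matrix`, tagged `"asinh"`.
#' @export
transform_asinh <- function(m) {
  if (m$transform != "none") {
    stop("matrix already transformed ('", m$transform, "'); refusing to re-transform")
  }
  expression_matrix(asinh(m$values), m$tissues, m$replicates, m$platform,
                    units = "asinh", transform = "asinh")
}

#' Bin an FPKM value by expression magnitude
#'
#' Bins partition the nonnegative reals: 0 is `none`, (0, 5] `low`,
#' (5, 200] `medium`, (200, Inf) `high`. Boundaries are strict on the
#' upper side of each bin.
#'
#' @param fpkm numeric vector of nonnegative values.
#' @param bins numeric length-2 vector of bin boundaries (low/medium and
#'   medium/high).
#' @return Factor with levels `none`, `low`, `medium`, `high`.
#' @export
classify_expression_level <- function(fpkm, bins = c(5, 200)) {
  if (any(fpkm < 0)) stop("negative expression value")
  stopifnot(length(bins) == 2L, bins[1] < bins[2])
  lev <- c("none", "low", "medium", "high")
  out <- lev[findInterval(fpkm, c(0, bins), left.open = TRUE) + 1L]
  factor(out, levels = lev)
}

#' Stringent maximum-expression filter
#'
#' Retains genes whose maximum tissue FPKM strictly exceeds `cutoff`
#' (default 5). Removing genes that never rise above a few FPKM guards
#' co-expression analysis against spurious correlations among low-count
#' genes.
#'
#' @param m replicate-collapsed RNA-Seq `expr_matrix` (untransformed FPKM).
#' @param cutoff FPKM threshold, strict.
#' @return List with `retained` and `removed` gene-id vectors.
#' @export
stringent_expression_filter <- function(m, cutoff = 5) {
  mx <- apply(m$values, 1L, max)
  keep <- mx > cutoff
  list(retained = gene_ids(m)[keep], removed = gene_ids(m)[!keep])
}
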