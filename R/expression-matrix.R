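#' Expression matrix container
#'
#' Holds a genes x (tissue, replicate) table of nonnegative expression
#' values together with platform and unit metadata. RNA-Seq values are FPKM
#' (fragments per kilobase of exon model per million mapped fragments);
#' microarray values are normalized hybridization intensities, stored
#' pre-log. Columns are either one per tissue (replicate-collapsed) or one
#' per (tissue, replicate) pair, named `<tissue>__rep<k>`.
#'
#' @param values numeric matrix, genes in rows. Row names are gene ids.
#' @param tissues character vector, one entry per column: the tissue each
#'   column belongs to.
#' @param replicates optional integer vector, one entry per column; `NULL`
#'   for a replicate-collapsed matrix.
#' @param platform `"rnaseq"` or `"microarray"`.
#' @param units `"FPKM"` or `"intensity"` (or `"log2"`/`"asinh"` after a
#'   transform).
#' @param transform transform already applied: `"none"`, `"log2"` or
#'   `"asinh"`. Transform functions refuse to double-transform.
#' @return An object of class `expr_matrix`.
#' @seealso [read_expression_table()], [collapse_replicates()],
#'   [transform_log2_floor()], [transform_asinh()]
#' @export
expression_matrix <- function(values, tissues, replicates = NULL,
                              platform = c("rnaseq", "microarray"),
                              units = NULL, transform = "none") {
  platform <- match.arg(platform)
  if (is.null(units)) units <- if (platform == "rnaseq") "FPKM" else "intensity"
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values must carry gene ids as row names")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(values)) stop("missing values are not allowed in expression input")
  if (any(values < 0)) stop("negative expression values are not allowed")
  if (length(tissues) != ncol(values)) {
    stop("tissues must have one entry per column")
  }
  if (!is.null(replicates)) {
    if (length(replicates) != ncol(values)) {
      stop("replicates must have one entry per column")
    }
    replicates <- as.integer(replicates)
    colnames(values) <- paste0(tissues, "__rep", replicates)
  } else {
    colnames(values) <- tissues
  }
  structure(
    list(values = values, tissues = as.character(tissues),
         replicates = replicates, platform = platform,
         units = units, transform = transform),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d columns (%s, %s%s)\n",
              nrow(x$values), ncol(x$values), x$platform, x$units,
              if (x$transform != "none") paste0(", ", x$transform) else ""))
  nt <- length(unique(x$tissues))
  if (is.null(x$replicates)) {
    cat(sprintf("  %d tissues, replicate-collapsed\n", nt))
  } else {
    cat(sprintf("  %d tissues x up to %d replicates\n", nt,
                max(x$replicates)))
  }
  invisible(x)
}

gene_ids <- function(m) rownames(m$values)

tissue_ids <- function(m) unique(m$tissues)

is_collapsed <- function(m) is.null(m$replicates)

#' Read a tab-delimited expression table
#'
#' First column holds gene ids; remaining column headers are either bare
#' tissue names or `<tissue>__rep<k>`. Fails fast on duplicate gene ids,
#' negative values and ragged rows.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return An `expr_matrix`.
#' @export
read_expression_table <- function(path, platform = c("rnaseq", "microarray")) {
  platform <- match.arg(platform)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) stop("parse error: ragged rows in ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("parse error: duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("parse error: non-numeric expression values")
  rownames(vals) <- ids
  hdr <- colnames(vals)
  has_rep <- grepl("__rep[0-9]+$", hdr)
  if (any(has_rep) && !all(has_rep)) {
    stop("parse error: mixed replicate and collapsed column headers")
  }
  if (all(has_rep)) {
    tissues <- sub("__rep[0-9]+$", "", hdr)
    reps <- as.integer(sub("^.*__rep", "", hdr))
    expression_matrix(vals, tissues, reps, platform)
  } else {
    expression_matrix(vals, hdr, NULL, platform)
  }
}

#' Write an expression matrix as a tab-delimited table
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(gene_id = gene_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicates within each tissue
#'
#' Per-tissue arithmetic mean across replicate columns, mirroring the
#' convention of averaging the replicate FPKM values before any downstream
#' analysis. Tissues with a missing replicate are averaged over the
#' replicates present (a message reports them).
#'
#' @param m an `expr_matrix` with replicate columns.
#' @return A replicate-collapsed `expr_matrix` in the tissue order of first
#'   appearance.
#' @export
collapse_replicates <- function(m) {
  if (is_collapsed(m)) stop("matrix has no replicate structure to collapse")
  tis <- unique(m$tissues)
  counts <- table(m$tissues)
  if (length(unique(counts)) > 1L) {
    message("uneven replicate counts; averaging available replicates for: ",
            paste(names(counts)[counts < max(counts)], collapse = ", "))
  }
  out <- vapply(tis, function(t) {
    rowMeans(m$values[, m$tissues == t, drop = FALSE])
  }, numeric(nrow(m$values)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m$values))
  rownames(out) <- gene_ids(m)
  expression_matrix(out, tis, NULL, m$platform, m$units, m$transform)
}

#' Subset an expression matrix to a gene set
#'
#' @param m an `expr_matrix`.
#' @param genes character vector of gene ids (order preserved).
#' @return The subsetted `expr_matrix`.
#' @export
subset_genes <- function(m, genes) {
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing)) {
    stop("gene(s) not present: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  expression_matrix(m$values[genes, , drop = FALSE], m$tissues,
                    m$replicates, m$platform, m$units, m$transform)
}

#' Restrict two expression matrices to shared genes
#'
#' Intersects the gene sets of two platforms (optionally further restricted
#' to genes detected as expressed on both) and returns both matrices with
#' identical gene order.
#'
#' @param a,b `expr_matrix` objects.
#' @param mode `"all_common"` or `"expressed_both"`.
#' @param detections for `expressed_both`, a list of two
#'   [detection_result] objects, in the order `(a, b)`.
#' @return A list with elements `a` and `b`.
#' @export
align_common_genes <- function(a, b, mode = c("all_common", "expressed_both"),
                               detections = NULL) {
  mode <- match.arg(mode)
  common <- intersect(gene_ids(a), gene_ids(b))
  if (mode == "expressed_both") {
    if (is.null(detections) || length(detections) != 2L) {
      stop("mode 'expressed_both' requires detections for both platforms")
    }
    ea <- names(detections[[1L]]$expressed)[detections[[1L]]$expressed]
    eb <- names(detections[[2L]]$expressed)[detections[[2L]]$expressed]
    common <- intersect(intersect(common, ea), eb)
  }
  if (length(common) == 0L) stop("no genes shared between the two matrices")
  take <- function(m) {
    expression_matrix(m$values[common, , drop = FALSE], m$tissues,
                      m$replicates, m$platform, m$units, m$transform)
  }
  list(a = take(a), b = take(b))
}
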