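# Internal helpers shared across modules.

# Derive a deterministic sub-stream seed from a global seed and an operation
# tag, so that independent stages draw from independent but reproducible
# streams. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) + 1009 * h) %% 2147483647L)
}

# Upper-triangle (diagonal excluded) of a symmetric matrix as a vector.
upper_tri_values <- function(m) m[upper.tri(m, diag = FALSE)]

# Standardize each column to mean 0, sd 1 (over rows). Columns with zero
# variance trigger an error naming the offender: downstream correlation
# statistics are undefined for them.
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  if (any(sd == 0)) {
    stop("constant column(s): ", paste(colnames(x)[sd == 0], collapse = ", "))
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
}

# Row-wise Pearson correlation between two matrices with matching shape,
# excluding the diagonal entry of each row (used for EC scores on gene
# co-expression profiles, where the self-edge is dropped from both vectors).
row_cors_excluding_diag <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)), nrow(a) == ncol(a))
  diag(a) <- NA_real_
  diag(b) <- NA_real_
  n <- ncol(a) - 1L
  am <- rowSums(a, na.rm = TRUE) / n
  bm <- rowSums(b, na.rm = TRUE) / n
  ac <- a - am
  bc <- b - bm
  num <- rowSums(ac * bc, na.rm = TRUE)
  den <- sqrt(rowSums(ac^2, na.rm = TRUE) * rowSums(bc^2, na.rm = TRUE))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
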