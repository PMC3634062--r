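# Small in-code fixtures shared across test files.

# genes x (tissue, replicate) matrix from a plain numeric matrix
em <- function(values, tissues, replicates = NULL, platform = "rnaseq",
               genes = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  rownames(values) <- genes
  expression_matrix(values, tissues, replicates, platform)
}

# replicate-collapsed 4-tissue matrix with hand-picked profiles
toy_collapsed <- function(platform = "rnaseq") {
  v <- rbind(c(1, 2, 3, 4),
             c(2, 4, 6, 8),
             c(5, 1, 4, 2),
             c(10, 10, 2, 2),
             c(0.5, 8, 1, 3))
  em(v, paste0("t", 1:4), platform = platform)
}

# small synthetic study shared by slower tests
small_study <- function(seed = 11, n_genes = 300, ...) {
  cfg <- synthetic_config(n_genes = n_genes, seed = seed, n_modules = 10,
                          module_size_range = c(4, 10), ...)
  truth <- generate_truth(cfg)
  list(cfg = cfg, truth = truth,
       rnaseq = simulate_rnaseq(truth),
       microarray = simulate_microarray(truth))
}

# transformed, gene-aligned platform pair ready for network analysis
network_pair <- function(truth, rnaseq, microarray) {
  rsc <- collapse_replicates(rnaseq)
  mac <- collapse_replicates(microarray)
  keep <- network_gene_filter(rsc, mac, detect_expressed_microarray(mac))
  list(keep = keep,
       rsc = rsc, mac = mac,
       rs = transform_asinh(subset_genes(rsc, keep)),
       ma = transform_log2_floor(subset_genes(mac, keep)))
}

# brute-force complete-linkage agglomeration on a distance matrix;
# returns the sorted merge heights
complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); besth <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1), length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < besth) { besth <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, besth)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
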