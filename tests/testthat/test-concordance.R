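test_that("replicate correlations match direct Pearson evaluation", {
  # identical replicates
  v <- matrix(c(1, 5, 9, 2, 1, 5, 9, 2), 4)
  m <- em(v, c("t1", "t1"), replicates = 1:2)
  rep1 <- replicate_correlations(m)
  expect_equal(rep1$per_tissue$r, 1)
  expect_equal(rep1$fraction_above[["0.95"]], 1)

  # hand-specified 4-gene, 3-replicate tissue: compare to cor() on the
  # log2-floored values pair by pair
  v3 <- cbind(c(2, 8, 32, 4), c(4, 16, 16, 8), c(2, 2, 64, 16))
  m3 <- em(v3, rep("t1", 3), replicates = 1:3)
  rep3 <- replicate_correlations(m3)
  lg <- log2(v3)
  expect_equal(rep3$per_tissue$r,
               c(stats::cor(lg[, 1], lg[, 2]), stats::cor(lg[, 1], lg[, 3]),
                 stats::cor(lg[, 2], lg[, 3])))

  # anti-correlated replicate pair (flip deviations about the mean on the
  # log scale)
  a <- c(1, 2, 3, 6)
  b <- mean(a) - (a - mean(a))
  m2 <- em(2^cbind(a, b), c("t1", "t1"), replicates = 1:2)
  expect_equal(replicate_correlations(m2)$per_tissue$r, -1)
})

test_that("constant replicate columns are excluded from correlation summaries", {
  v <- cbind(c(1, 1, 1, 1), c(2, 8, 4, 16), c(4, 16, 8, 32))
  m <- em(v, rep("t1", 3), replicates = 1:3)
  expect_message(rep1 <- replicate_correlations(m), "constant")
  expect_equal(sum(is.na(rep1$per_tissue$r)), 2)
  expect_equal(rep1$mean_r, 1)  # only the (2,3) pair survives, r = 1
})

test_that("cross-platform correlations are affine-invariant and match direct formula", {
  a <- em(rbind(c(2, 4, 8, 3), c(16, 2, 4, 32), c(5, 9, 2, 7),
                c(11, 3, 6, 2), c(4, 4, 9, 1)) + 1, paste0("t", 1:4))
  b <- em(2 * a$values, a$tissues, platform = "microarray")
  rep_ab <- cross_platform_correlations(a, b)
  # log2(2x) = log2 x + 1 (all values above the floor): r = 1 per tissue
  expect_true(all(abs(rep_ab$per_tissue$r - 1) < 1e-12))

  set.seed(42)
  noise <- em(matrix(stats::rexp(5 * 4, 1 / 5), 5), paste0("t", 1:4),
              platform = "microarray", genes = gene_ids(a))
  r_noise <- cross_platform_correlations(a, noise)$per_tissue$r
  expect_true(all(abs(r_noise) < 1))

  # toy 4-gene hand check on one tissue
  x <- c(1, 2, 4, 16); y <- c(2, 2, 8, 4)
  mx <- em(cbind(x, x), c("t1", "t2"))
  my <- em(cbind(y, y), c("t1", "t2"), platform = "microarray")
  got <- cross_platform_correlations(mx, my)$per_tissue$r[1]
  lx <- log2(x); ly <- log2(y)
  byhand <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(got, byhand)
})

test_that("tissue clustering is complete linkage on 1 - r with sane merges", {
  # two identical tissues among four merge first at height 0
  v <- cbind(c(1, 2, 3, 5), c(1, 2, 3, 5), c(5, 3, 2, 1), c(2, 7, 3, 4))
  m <- em(2^v, paste0("t", 1:4))
  hc <- cluster_tissues(m)
  expect_equal(length(hc$height), 3)
  expect_false(is.unsorted(hc$height))
  expect_lt(hc$height[1], 1e-12)
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("t1", "t2"))

  # heights equal an independent brute-force complete-linkage agglomeration
  d <- 1 - stats::cor(v)
  expect_equal(sort(hc$height), sort(complete_linkage_heights(stats::as.dist(d))),
               tolerance = 1e-12)

  const <- em(cbind(c(1, 1, 1, 1), c(1, 2, 3, 4)), c("flat", "ok"))
  expect_error(cluster_tissues(const), "flat")
})

test_that("tissue clustering recovers synthetic groups exactly at zero noise", {
  cfg <- synthetic_config(n_genes = 120, seed = 6, noise_sd = 0,
                          tissue_groups = list(1:9, 10:18),
                          n_modules = 6, module_size_range = c(4, 6),
                          paralog_fraction = 0, frac_saturated = 0,
                          frac_low_expressed = 0)
  tr <- generate_truth(cfg)
  m <- em(exp(tr$latent_log_expression),
          colnames(tr$latent_log_expression),
          genes = rownames(tr$latent_log_expression))
  hc <- cluster_tissues(m)
  cut2 <- stats::cutree(hc, 2)
  grp <- tr$tissue_group_of[match(names(cut2),
                                  colnames(tr$latent_log_expression))]
  expect_equal(length(unique(paste(cut2, grp))), 2)
})

test_that("pca_tissues orders components, sums variance to 1, and separates groups", {
  cfg <- synthetic_config(n_genes = 120, seed = 6, noise_sd = 0,
                          tissue_groups = list(1:9, 10:18),
                          n_modules = 6, module_size_range = c(4, 6),
                          paralog_fraction = 0, frac_saturated = 0,
                          frac_low_expressed = 0)
  tr <- generate_truth(cfg)
  m <- em(exp(tr$latent_log_expression),
          colnames(tr$latent_log_expression),
          genes = rownames(tr$latent_log_expression))
  pc <- pca_tissues(m, k = 30, seed = 1)
  ev <- pc$explained_variance
  expect_false(is.unsorted(rev(ev)))
  expect_equal(sum(ev), 1, tolerance = 1e-9)
  grp <- tr$tissue_group_of
  pc1 <- pc$scores[, 1]
  expect_true(max(pc1[grp == 1]) < min(pc1[grp == 2]) ||
                max(pc1[grp == 2]) < min(pc1[grp == 1]))

  # duplicated tissues land on identical coordinates
  v <- m$values[, c(1, 1, 5, 10, 14)]
  colnames(v) <- paste0("c", 1:5)
  dup <- em(v, colnames(v), genes = gene_ids(m))
  pc2 <- pca_tissues(dup, k = 20, seed = 1)
  expect_equal(unname(pc2$scores[1, ]), unname(pc2$scores[2, ]),
               tolerance = 1e-9)

  expect_warning(pca_tissues(m, k = 1e5, seed = 1), "reducing")
})

test_that("top_expressed_genes ranks like a full sort and breaks ties by id", {
  v <- rbind(c(5, 1), c(9, 2), c(9, 3), c(1, 4), c(3, 10))
  m <- em(v, c("t1", "t2"))
  top <- top_expressed_genes(m, 3)
  expect_equal(top$t1$gene_id, c("g02", "g03", "g01"))
  expect_equal(top$t2$gene_id, c("g05", "g04", "g03"))
  # n = 1 is the argmax
  expect_equal(top_expressed_genes(m, 1)$t2$gene_id, "g05")
  # brute-force oracle on the full ranking
  expect_warning(full <- top_expressed_genes(m, 10), "full ranking")
  ord <- order(-v[, 1], gene_ids(m))
  expect_equal(full$t1$gene_id, gene_ids(m)[ord])
})
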