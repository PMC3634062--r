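norm_net <- function(edges, genes) {
  dimnames(edges) <- list(genes, genes)
  structure(list(gene_ids = genes, edges = edges, stage = "normalized",
                 source = "test"),
            class = "coexpr_network")
}

test_that("ec_scores correlates co-expression profiles excluding the self-edge", {
  g <- c("a", "b", "c", "d")
  e1 <- rbind(c(NA, 0.9, 0.1, 0.2),
              c(0.9, NA, 0.3, 0.4),
              c(0.1, 0.3, NA, 0.5),
              c(0.2, 0.4, 0.5, NA))
  dimnames(e1) <- list(g, g)
  ec_same <- ec_scores(norm_net(e1, g), norm_net(e1, g))
  expect_true(all(ec_same == 1))

  # row a swapped between two neighbors: direct Pearson on the 3-vectors
  e2 <- e1
  e2["a", c("b", "c")] <- c(0.1, 0.9)
  e2[c("b", "c"), "a"] <- c(0.1, 0.9)
  ec <- ec_scores(norm_net(e1, g), norm_net(e2, g))
  expect_equal(unname(ec["a"]), stats::cor(c(0.9, 0.1, 0.2), c(0.1, 0.9, 0.2)))
  expect_equal(unname(ec["a"]), -0.6842105, tolerance = 1e-6)

  # symmetry in the two networks
  ec_rev <- ec_scores(norm_net(e2, g), norm_net(e1, g))
  expect_equal(ec, ec_rev)
})

test_that("replacing one gene's edges with noise lowers its EC only", {
  set.seed(10)
  G <- 30
  base <- stats::cor(matrix(stats::rnorm(G * 12), ncol = G))
  diag(base) <- NA
  genes <- sprintf("g%02d", 1:G)
  dimnames(base) <- list(genes, genes)
  pert <- base
  noise <- stats::runif(G - 1, -0.5, 0.5)
  pert["g01", -1] <- noise
  pert[-1, "g01"] <- noise
  ec <- ec_scores(norm_net(base, genes), norm_net(pert, genes))
  expect_lt(abs(ec[["g01"]]), 0.6)
  expect_true(all(ec[-1] > 0.7))
  expect_gt(mean(ec[-1]), 0.9)
})

test_that("connectivity counts edges at or above tau inclusively", {
  g <- c("a", "b", "c", "d")
  e <- matrix(0, 4, 4)
  e[1, 2] <- e[2, 1] <- 2.0   # exactly tau: counted for both endpoints
  e[3, 4] <- e[4, 3] <- 3.5
  e[1, 3] <- e[3, 1] <- 1.9
  net <- norm_net(e, g)
  expect_equal(unname(connectivity(net, tau = 2)), c(1, 1, 1, 1))
  expect_equal(unname(connectivity(net, tau = 5)), c(0, 0, 0, 0))
  expect_equal(unname(connectivity(net, tau = 1.9)), c(2, 1, 2, 1))
})

test_that("ec_significance degenerates to p = 1 when platforms are identical", {
  m <- transform_asinh(toy_collapsed())
  fit <- suppressWarnings(ec_significance(m, m, B = 120, seed = 2))
  expect_true(all(fit$genes$ec == 1))
  expect_true(all(!fit$genes$flagged))
  expect_true(all(fit$genes$p > 0.5))
  expect_equal(fit$observed_similarity, 1)
})

test_that("ec_significance p-values are reproducible and bounded", {
  s <- small_study(seed = 91, n_genes = 150)
  np <- network_pair(s$truth, s$rnaseq, s$microarray)
  fit1 <- ec_significance(np$ma, np$rs, B = 100, seed = 6)
  fit2 <- ec_significance(np$ma, np$rs, B = 100, seed = 6)
  expect_identical(fit1$genes, fit2$genes)
  expect_true(all(fit1$genes$p >= 0 & fit1$genes$p <= 1))
  # empirical variant respects the add-one floor
  fit3 <- ec_significance(np$ma, np$rs, B = 100, seed = 6,
                          p_method = "empirical")
  expect_true(all(fit3$genes$p >= 1 / 101))
  expect_warning(ec_significance(np$ma, np$rs, B = 50, seed = 6),
                 "resolution")
})

test_that("ec_fit methods expose scores, summaries and plots", {
  s <- small_study(seed = 92, n_genes = 120)
  np <- network_pair(s$truth, s$rnaseq, s$microarray)
  fit <- ec_significance(np$ma, np$rs, B = 100, seed = 1)
  expect_s3_class(fit, "ec_fit")
  cf <- coef(fit)
  expect_equal(length(cf), nrow(fit$genes))
  expect_named(cf)
  sm <- summary(fit)
  expect_equal(sm$n_genes, nrow(fit$genes))
  expect_output(print(fit), "conserved")
  expect_output(print(sm), "Expression conservation")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("divergence classification applies the degree-dominance rule and clusters", {
  s <- small_study(seed = 93, n_genes = 300)
  np <- network_pair(s$truth, s$rnaseq, s$microarray)
  fit <- ec_significance(np$ma, np$rs, B = 150, seed = 3)
  div <- classify_divergent(fit, microarray = subset_genes(np$mac, np$keep),
                            rnaseq = subset_genes(np$rsc, np$keep))
  g <- div$genes
  flagged <- g[g$flagged, ]
  # rule check against a hand evaluation
  expect_equal(flagged$divergence_class,
               ifelse(flagged$degree_a >= 2 * flagged$degree_b + 5, "more_in_a",
                      ifelse(flagged$degree_b >= 2 * flagged$degree_a + 5,
                             "more_in_b", "similar")))
  expect_true(all(is.na(g$divergence_class[!g$flagged])))
  # low-count genes flagged land in the RNA-Seq-near-zero cluster
  lows <- intersect(s$truth$low_count_genes, flagged$gene_id)
  if (length(lows)) {
    expect_true(all(g$cluster[g$gene_id %in% lows] == "rnaseq_near_zero"))
  }
})

test_that("degree rule boundary: 20 vs 2 is more_in_a, equal degrees are similar", {
  fit <- structure(list(genes = data.frame(
    gene_id = c("a", "b"), ec = c(0.1, 0.2),
    null_mean = 0.8, null_sd = 0.1,
    p = c(0.001, 0.002), flagged = TRUE,
    degree_a = c(20L, 7L), degree_b = c(2L, 7L))), class = "ec_fit")
  ma <- em(matrix(c(100, 100, 200, 200), 2), c("t1", "t2"),
           platform = "microarray", genes = c("a", "b"))
  rs <- em(matrix(c(1, 0, 2, 0), 2), c("t1", "t2"), genes = c("a", "b"))
  div <- classify_divergent(fit, ma, rs)
  expect_equal(div$genes$divergence_class, c("more_in_a", "similar"))
})

test_that("hypergeometric enrichment matches brute-force tail summation", {
  expect_equal(enrichment_test("g1", letters, c("g1", letters))$p_value, 1,
               tolerance = 1e-12)
  # universe 4, annotated 2, flagged 2, overlap 2 -> 1/6
  uni <- c("a", "b", "c", "d")
  expect_equal(enrichment_test(c("a", "b"), c("a", "b"), uni)$p_value, 1 / 6,
               tolerance = 1e-12)

  # brute-force: enumerate all draws of size 10 is infeasible; sum the
  # hypergeometric pmf directly instead
  brute_tail <- function(k, K, N, n) {
    sum(vapply(k:min(K, n), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }, numeric(1)))
  }
  uni100 <- sprintf("u%03d", 1:100)
  ann <- uni100[1:10]
  flg <- c(uni100[1:5], uni100[50:54])
  got <- enrichment_test(flg, ann, uni100)
  expect_equal(got$overlap, 5)
  expect_equal(got$p_value, brute_tail(5, 10, 100, 10), tolerance = 1e-12)
  expect_error(enrichment_test("x", "y", character(0)), "empty")
})

test_that("low-expression diagnostic matches exact enumeration and finds low sets", {
  # exact two-group enumeration at tiny n
  v <- c(3, 1, 4, 1.5, 9, 2.6)
  m <- em(matrix(rep(v, 2), 6), c("t1", "t2"))
  res <- low_expression_diagnostic(c("g01", "g02"), m)
  brute_less <- function(set_vals, rest_vals) {
    pooled <- c(set_vals, rest_vals); n1 <- length(set_vals)
    combos <- utils::combn(length(pooled), n1)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    mean(apply(combos, 2, function(i) sum(r[i])) <= w_obs)
  }
  expect_equal(res$p_value, brute_less(v[1:2], v[3:6]), tolerance = 1e-12)

  # bottom decile by mean is detected overwhelmingly
  set.seed(12)
  big <- matrix(stats::rexp(2000 * 2, 1 / 20), 2000)
  mb <- em(big, c("t1", "t2"))
  mu <- rowMeans(big)
  bottom <- gene_ids(mb)[order(mu)][1:200]
  expect_lt(low_expression_diagnostic(bottom, mb)$p_value, 1e-10)
  expect_error(low_expression_diagnostic(gene_ids(mb), mb), "universe")
})

test_that("flagged-set p-values are calibrated when the gene set is random", {
  set.seed(33)
  v <- matrix(stats::rexp(200 * 4, 1 / 10), 200)
  m <- em(v, paste0("t", 1:4))
  ps <- vapply(1:60, function(i) {
    low_expression_diagnostic(sample(gene_ids(m), 40), m)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
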