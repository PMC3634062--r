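test_that("generation is deterministic given config and seed", {
  s1 <- small_study(seed = 3)
  s2 <- small_study(seed = 3)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$rnaseq$values, s2$rnaseq$values)
  expect_identical(s1$microarray$values, s2$microarray$values)
  s3 <- small_study(seed = 4)
  expect_false(identical(s1$truth$latent_log_expression,
                         s3$truth$latent_log_expression))
})

test_that("module genes share their tissue factor exactly at zero noise", {
  cfg <- synthetic_config(n_genes = 60, seed = 2, n_modules = 3,
                          module_size_range = c(4, 6), noise_sd = 0,
                          paralog_fraction = 0, frac_saturated = 0,
                          frac_low_expressed = 0)
  tr <- generate_truth(cfg)
  mods <- tr$module_of_gene
  pair <- names(mods)[which(mods == 1)][1:2]
  r <- stats::cor(tr$latent_log_expression[pair[1], ],
                  tr$latent_log_expression[pair[2], ])
  expect_equal(r, 1)
})

test_that("latent correlation is higher within tissue groups than between", {
  cfg <- synthetic_config(n_genes = 100, seed = 5, noise_sd = 0,
                          tissue_groups = list(1:9, 10:18),
                          n_modules = 5, module_size_range = c(4, 6),
                          paralog_fraction = 0, frac_saturated = 0,
                          frac_low_expressed = 0)
  tr <- generate_truth(cfg)
  lat <- tr$latent_log_expression
  cors <- stats::cor(lat)
  within <- c(upper_tri <- cors[1:9, 1:9][upper.tri(diag(9))],
              cors[10:18, 10:18][upper.tri(diag(9))])
  between <- as.vector(cors[1:9, 10:18])
  expect_gt(mean(within), mean(between))
  # zero noise: tissues within a group are identical columns
  expect_equal(unname(lat[, 1]), unname(lat[, 9]))
})

test_that("module sizes beyond n_genes raise a sizing error", {
  cfg <- synthetic_config(n_genes = 10, seed = 1, n_modules = 5,
                          module_size_range = c(4, 4))
  expect_error(generate_truth(cfg), "exceed")
})

test_that("RNA-Seq log-FPKM tracks the latent surface in the deep, low-dispersion limit", {
  cfg <- synthetic_config(n_genes = 150, seed = 8, n_modules = 5,
                          module_size_range = c(4, 6),
                          depth_per_tissue = 1e8, nb_dispersion = 1e-6,
                          frac_low_expressed = 0, frac_saturated = 0,
                          paralog_fraction = 0)
  tr <- generate_truth(cfg)
  m <- collapse_replicates(simulate_rnaseq(tr))
  for (t in c(1, 9, 18)) {
    r <- stats::cor(log(m$values[, t]), tr$latent_log_expression[, t])
    expect_gt(r, 0.99)
  }
})

test_that("low-count genes have zero median FPKM and are removed by the FPKM filter", {
  s <- small_study(seed = 13)
  m <- collapse_replicates(s$rnaseq)
  lows <- s$truth$low_count_genes
  expect_gt(length(lows), 0)
  med <- apply(m$values[lows, , drop = FALSE], 1, stats::median)
  expect_true(all(med == 0))
  f <- stringent_expression_filter(m)
  expect_gte(mean(lows %in% f$removed), 0.9)
})

test_that("microarray response is monotone in the latent signal without artifacts", {
  cfg <- synthetic_config(n_genes = 80, seed = 9, noise_sd = 0,
                          n_modules = 4, module_size_range = c(4, 6),
                          paralog_fraction = 0, frac_saturated = 0,
                          frac_low_expressed = 0)
  tr <- generate_truth(cfg)
  resp <- microarray_response(tr)
  for (t in c(1, 10)) {
    expect_equal(stats::cor(resp[, t], exp(tr$latent_log_expression[, t]),
                            method = "spearman"), 1)
  }
})

test_that("probe bleed lifts the receiver's intensity in the donor's tissues", {
  cfg <- synthetic_config(n_genes = 80, seed = 21, noise_sd = 0,
                          n_modules = 0, paralog_fraction = 0.1,
                          frac_saturated = 0, frac_low_expressed = 0)
  tr <- generate_truth(cfg)
  pp <- tr$paralog_pairs[tr$paralog_pairs$mismatch_class == "mm2_3", ]
  expect_gt(nrow(pp), 0)
  resp <- microarray_response(tr)
  cfg0 <- cfg; cfg0$paralog_bleed[] <- 0
  resp0 <- microarray_response(tr, cfg0)
  lat <- tr$latent_log_expression
  for (i in seq_len(nrow(pp))) {
    donor <- pp$gene1[i]; recv <- pp$gene2[i]
    donor_tissues <- which(lat[donor, ] == max(lat[donor, ]))
    # with bleed the receiver picks up signal where the donor peaks;
    # evaluate the stated intensity formula against the bleed-free response
    lift <- resp[recv, donor_tissues] - resp0[recv, donor_tissues]
    expected <- cfg$paralog_bleed[["mm2_3"]] * exp(lat[donor, donor_tissues])
    expect_equal(unname(lift), unname(expected), tolerance = 1e-8)
  }
})

test_that("saturated genes sit at the ceiling in at least 3 tissues before noise", {
  s <- small_study(seed = 17)
  resp <- microarray_response(s$truth)
  sat <- s$truth$saturated_genes
  expect_gt(length(sat), 0)
  at_ceiling <- rowSums(resp[sat, , drop = FALSE] ==
                          s$cfg$saturation_ceiling)
  expect_true(all(at_ceiling >= 3))
})

test_that("transformed platforms are near-exchangeable without artifacts at depth", {
  cfg <- synthetic_config(n_genes = 200, seed = 31, noise_sd = 0,
                          n_modules = 8, module_size_range = c(4, 6),
                          paralog_fraction = 0, frac_saturated = 0,
                          frac_low_expressed = 0,
                          background_floor = 1e-6, depth_per_tissue = 1e8,
                          nb_dispersion = 1e-6)
  tr <- generate_truth(cfg)
  rs <- transform_asinh(collapse_replicates(simulate_rnaseq(tr)))
  ma <- transform_log2_floor(collapse_replicates(simulate_microarray(tr)))
  for (t in c(1, 18)) {
    expect_gt(stats::cor(rs$values[, t], ma$values[, t]), 0.99)
  }
})

test_that("a written dataset reads back consistently with its truth sidecar", {
  s <- small_study(seed = 23, n_genes = 150)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(s$truth, dir)
  rs <- read_expression_table(file.path(dir, "rnaseq.tsv"), "rnaseq")
  expect_equal(rs$values, s$rnaseq$values, tolerance = 1e-6)
  side <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_equal(sort(side$divergent_genes), sort(s$truth$divergent_genes))
  pairs <- utils::read.delim(file.path(dir, "paralogs.tsv"))
  expect_equal(nrow(pairs), nrow(s$truth$paralog_pairs))
})
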