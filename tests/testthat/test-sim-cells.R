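# Single-cell count simulator: shapes, determinism, planted moments.

test_that("config validation enforces the stated invariants", {
  expect_error(sim_cells_config(n_clusters = 1), "n_clusters")
  expect_error(sim_cells_config(target_peak_cluster = 7), "target_peak_cluster")
  expect_error(sim_cells_config(rbp_profile = rep(-1, 7)), "nonnegative")
  expect_error(sim_cells_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_cells_config(n_genes = 10, n_targets = 10), "exceed")
  expect_error(sim_cells_config(rbp_profile = c(1, 2)), "length")
})

test_that("all-zero means give all-zero matrices", {
  cfg <- sim_cells_config(n_clusters = 2, cells_per_cluster = 5,
                          n_genes = 10, n_targets = 2,
                          rbp_profile = c(0, 0), target_peak_cluster = 0,
                          target_unspliced_profile = c(0, 0),
                          background_mean = 0, seed = 1)
  sim <- simulate_cell_counts(cfg)
  expect_equal(sum(sim$counts$spliced), 0)
  expect_equal(sum(sim$counts$unspliced), 0)
})

test_that("identical seeds give bit-identical output; shapes are consistent", {
  cfg <- sim_cells_config(n_clusters = 3, cells_per_cluster = 50,
                          n_genes = 40, n_targets = 5,
                          target_peak_cluster = 1, seed = 1)
  s1 <- simulate_cell_counts(cfg)
  s2 <- simulate_cell_counts(cfg)
  expect_identical(as.matrix(s1$counts$spliced), as.matrix(s2$counts$spliced))
  expect_identical(as.matrix(s1$counts$unspliced),
                   as.matrix(s2$counts$unspliced))
  expect_identical(s1$truth, s2$truth)
  expect_equal(dim(s1$counts), c(40L, 150L))
  expect_length(s1$counts$cluster_labels, 150L)
  expect_equal(sort(unique(s1$counts$cluster_labels)), 0:2)
  # different seed differs
  s3 <- simulate_cell_counts(sim_cells_config(n_clusters = 3,
                                              cells_per_cluster = 50,
                                              n_genes = 40, n_targets = 5,
                                              target_peak_cluster = 1,
                                              seed = 2))
  expect_false(identical(as.matrix(s1$counts$spliced),
                         as.matrix(s3$counts$spliced)))
  # truth is consistent with the config
  expect_length(s1$truth$target_gene_ids, 5L)
  expect_false(s1$truth$rbp_gene_id %in% s1$truth$target_gene_ids)
})

test_that("target unspliced counts hit the planted cluster mean (Monte Carlo)", {
  # K=4, profile (1,1,20,1): 10,000 draws in cluster 2 (0-based), no
  # library-size spread so draws are independent and E[factor] = 1
  cfg <- sim_cells_config(n_clusters = 4, cells_per_cluster = 250,
                          n_genes = 50, n_targets = 40,
                          target_peak_cluster = 2,
                          target_unspliced_profile = c(1, 1, 20, 1),
                          libsize_sigma = 0, seed = 8)
  sim <- simulate_cell_counts(cfg)
  in_k <- sim$counts$cluster_labels == 2L
  x <- as.matrix(sim$counts$unspliced[sim$truth$target_gene_ids, in_k])
  expect_equal(length(x), 10000L)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 20), 3 * se)
})

test_that("library factors scale both matrices of a cell jointly", {
  # huge sigma: per-cell totals of the two matrices must correlate strongly
  cfg <- sim_cells_config(n_clusters = 2, cells_per_cluster = 150,
                          n_genes = 80, n_targets = 10,
                          target_peak_cluster = 0, background_mean = 5,
                          libsize_sigma = 0.8, nb_dispersion = Inf, seed = 3)
  sim <- simulate_cell_counts(cfg)
  ts <- Matrix::colSums(sim$counts$spliced)
  tu <- Matrix::colSums(sim$counts$unspliced)
  expect_gt(cor(log1p(ts), log1p(tu)), 0.8)
})

test_that("truth round-trips through JSON serialization unchanged", {
  sim <- small_sim(seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, path)
  back <- read_sim_truth(path)
  expect_identical(back$rbp_gene_id, sim$truth$rbp_gene_id)
  expect_identical(back$target_gene_ids, sim$truth$target_gene_ids)
  expect_identical(as.integer(back$target_peak_cluster),
                   as.integer(sim$truth$target_peak_cluster))
  expect_equal(back$expected_cluster_scores,
               sim$truth$expected_cluster_scores)
})
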