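# Engagement scoring: per-cell score, cluster summaries, ranking.

make_counts <- function(spliced, unspliced, genes, clusters = NULL) {
  n <- ncol(spliced)
  cell_counts(spliced, unspliced, genes, paste0("c", seq_len(n)),
              clusters %||% rep(0L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hand-computed per-cell scores match (trivial and derived cases)", {
  genes <- c("Rbp", "g1", "g2")
  # zero numerator, r_c = 7 -> 0
  s <- matrix(c(7, 10, 10), 3, 1); u <- matrix(c(0, 0, 0), 3, 1)
  cc <- make_counts(s, u, genes)
  res <- engagement_score_cell(cc, target_set("Rbp", c("g1", "g2")), 1)
  expect_identical(res$score, 0)
  expect_false(res$excluded)

  # one target, u = 5, r = 5, N = 100 -> 1 (normalizations cancel)
  s <- matrix(c(5, 60, 20), 3, 1); u <- matrix(c(5, 5, 5), 3, 1)
  cc <- make_counts(s, u, genes)
  expect_equal(engagement_score_cell(cc, target_set("Rbp", "g1"), 1)$score, 1)

  # two targets u = {2, 3}, r = 4, N = 200 -> 1.25, against the naive oracle
  s <- matrix(c(4, 90, 90), 3, 1); u <- matrix(c(6, 2, 3), 3, 1)
  cc <- make_counts(s, u, genes)
  got <- engagement_score_cell(cc, target_set("Rbp", c("g1", "g2")), 1)$score
  expect_equal(got, 1.25)
  expect_equal(got, oracle_scores(s, u, genes, "Rbp", c("g1", "g2"))[1])
})

test_that("score_cells equals the naive oracle on random seeded matrices", {
  set.seed(421)
  for (rep_i in 1:5) {
    n_g <- sample(5:20, 1); n_c <- sample(5:30, 1)
    genes <- c("Rbp", sprintf("g%02d", seq_len(n_g - 1L)))
    s <- matrix(rpois(n_g * n_c, 4), n_g, n_c)
    u <- matrix(rpois(n_g * n_c, 2), n_g, n_c)
    targets <- sample(genes[-1], max(2, n_g %/% 3))
    cc <- make_counts(s, u, genes)
    got <- score_cells(cc, target_set("Rbp", targets))
    expect_identical(got$score, oracle_scores(s, u, genes, "Rbp", targets))
    expect_identical(got$excluded, s[1, ] == 0)
  }
})

test_that("scores are library-scale and gene-order invariant", {
  set.seed(7)
  genes <- c("Rbp", sprintf("g%d", 1:9))
  s <- matrix(rpois(10 * 6, 5) + 1, 10, 6)
  u <- matrix(rpois(10 * 6, 2), 10, 6)
  ts <- target_set("Rbp", c("g2", "g5", "g7"))
  base <- score_cells(make_counts(s, u, genes), ts)$score

  # doubling every count of cell 3 leaves its score unchanged
  s2 <- s; u2 <- u; s2[, 3] <- 2 * s[, 3]; u2[, 3] <- 2 * u[, 3]
  expect_equal(score_cells(make_counts(s2, u2, genes), ts)$score, base)

  # permuting genes leaves all scores unchanged
  p <- sample(10)
  expect_equal(score_cells(make_counts(s[p, ], u[p, ], genes[p]), ts)$score,
               base)

  # two identical cells score identically
  s3 <- cbind(s, s[, 1]); u3 <- cbind(u, u[, 1])
  sc3 <- score_cells(make_counts(s3, u3, genes), ts)$score
  expect_identical(sc3[1], sc3[7])
})

test_that("normalized form reduces to sum(u)/r to <= 1e-12 relative error", {
  set.seed(11)
  genes <- c("Rbp", sprintf("g%d", 1:7))
  s <- matrix(rpois(8 * 20, 6) + 1, 8, 20)
  u <- matrix(rpois(8 * 20, 3), 8, 20)
  ts <- target_set("Rbp", c("g1", "g4"))
  for (total in c("spliced+unspliced", "spliced")) {
    got <- score_cells(make_counts(s, u, genes), ts, total = total)$score
    reduced <- (u[2, ] + u[5, ]) / s[1, ]
    expect_lt(max(abs(got - reduced) / pmax(reduced, 1e-300)), 1e-12)
  }
})

test_that("monotonicity: raising a target's unspliced count never lowers a score", {
  set.seed(13)
  genes <- c("Rbp", "g1", "g2", "g3")
  s <- matrix(rpois(4 * 10, 5) + 1, 4, 10)
  u <- matrix(rpois(4 * 10, 2), 4, 10)
  ts <- target_set("Rbp", c("g1", "g3"))
  base <- score_cells(make_counts(s, u, genes), ts)$score
  for (i in 1:10) {
    u2 <- u
    row <- sample(c(2, 4), 1)      # a target gene's row
    u2[row, i] <- u2[row, i] + sample(1:5, 1)
    bumped <- score_cells(make_counts(s, u2, genes), ts)$score
    expect_gte(bumped[i], base[i])
  }
})

test_that("error and exclusion contracts hold", {
  genes <- c("Rbp", "g1", "g2")
  s <- matrix(c(0, 5, 5, 3, 5, 5), 3, 2)
  u <- matrix(1, 3, 2)
  cc <- make_counts(s, u, genes)
  ts <- target_set("Rbp", c("g1", "g2"))
  expect_error(score_cells(cc, target_set("Nope", "g1")), "not found")
  expect_error(score_cells(cc, target_set("Rbp", c("x1", "x2"))),
               "none of the")
  expect_message(res <- score_cells(cc, target_set("Rbp", c("g1", "zz"))),
                 "1 of 2")
  expect_equal(attr(res, "n_targets_dropped"), 1L)
  # r_c = 0 -> excluded with NA score; pseudocount rescues it
  full <- score_cells(cc, ts)
  expect_true(full$excluded[1])
  expect_true(is.na(full$score[1]))
  ps <- score_cells(cc, ts, pseudocount = 1)
  expect_false(any(ps$excluded))
  expect_equal(ps$score[1], 2 / 1)
})

test_that("cluster summaries: degenerate, odd-median and bootstrap oracle", {
  pc <- data.frame(cluster = rep(0L, 4), score = rep(2, 4), excluded = FALSE)
  s0 <- summarize_clusters(pc, n_boot = 50, seed = 1)
  expect_equal(s0$median_score, 2)
  expect_equal(s0$ci_low, 2)
  expect_equal(s0$ci_high, 2)

  pc <- data.frame(cluster = 0L, score = c(1, 2, 3), excluded = FALSE)
  expect_equal(summarize_clusters(pc, n_boot = 10, seed = 1)$median_score, 2)

  x <- c(0.5, 1.0, 1.5, 4.0)
  pc <- data.frame(cluster = 0L, score = x, excluded = FALSE)
  got <- summarize_clusters(pc, n_boot = 1000, seed = 7)
  ci <- oracle_boot_ci(x, 1000, 7)
  expect_equal(got$ci_low, ci[1])
  expect_equal(got$ci_high, ci[2])

  expect_error(summarize_clusters(pc[0, ]), "empty")
})

test_that("excluded cells stay out of summaries; all-excluded cluster warns", {
  pc <- data.frame(cluster = c(0, 0, 0, 1, 1),
                   score = c(1, 100, NA, NA, NA),
                   excluded = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_warning(s <- summarize_clusters(pc, n_boot = 20, seed = 2),
                 "all cells excluded")
  expect_equal(s$n_cells_used, c(2L, 0L))
  expect_equal(s$n_excluded, c(1L, 2L))
  expect_equal(s$median_score[1], 50.5)
  expect_true(is.na(s$median_score[2]))
})

test_that("rank_clusters orders by median with documented tie-break", {
  pcl <- data.frame(cluster = c(0, 1), median_score = c(0.1, 0.9))
  expect_identical(rank_clusters(pcl), c(1, 0))
  pcl <- data.frame(cluster = c(2, 1), median_score = c(0.5, 0.5))
  expect_message(rk <- rank_clusters(pcl), "tie")
  expect_identical(rk, c(1, 2))
  expect_error(rank_clusters(pcl[0, ]), "empty")
})

test_that("planted peak cluster is recovered on simulated data", {
  sim <- small_sim(seed = 101, k_star = 2L)
  ts <- target_set(sim$truth$rbp_gene_id, sim$truth$target_gene_ids)
  pc <- score_cells(sim$counts, ts)
  su <- summarize_clusters(pc, n_boot = 100, seed = 11)
  expect_identical(rank_clusters(su)[1], 2L)
})

test_that("per-target mode returns one row per target gene", {
  genes <- c("Rbp", "g1", "g2")
  s <- matrix(c(4, 1, 1, 2, 1, 1), 3, 2)
  u <- matrix(c(0, 2, 6, 0, 1, 3), 3, 2)
  cc <- make_counts(s, u, genes)
  res <- score_cells(cc, target_set("Rbp", c("g1", "g2")), per_target = TRUE)
  pt <- attr(res, "per_target")
  expect_equal(dim(pt), c(2L, 2L))
  expect_equal(unname(colSums(pt)), res$score)
  expect_equal(pt["g1", 1], 2 / 4)
})
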