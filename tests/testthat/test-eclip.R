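# eCLIP enrichment: fold enrichment, Fisher test, significance rule,
# target derivation.

test_that("fold enrichment: ratio, sentinels, errors", {
  expect_equal(fold_enrichment(5, 1, 100, 100), 5)
  expect_equal(fold_enrichment(3, 3, 1000, 1000), 1)
  expect_true(is.nan(fold_enrichment(0, 0, 100, 100)))
  expect_identical(fold_enrichment(4, 0, 100, 100), Inf)
  # FE uses library fractions, not raw counts
  expect_equal(fold_enrichment(10, 10, 100, 1000), 10)
  expect_error(fold_enrichment(101, 1, 100, 100), "exceed")
})

test_that("fisher_peak_test: trivial symmetries", {
  expect_equal(fisher_peak_test(5, 5, 100, 100), 1)
  expect_equal(fisher_peak_test(0, 0, 50, 70), 1)
  # two-sided p is invariant under swapping the IP and input rows
  p1 <- fisher_peak_test(9, 2, 500, 400)
  p2 <- fisher_peak_test(2, 9, 400, 500)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("fisher_peak_test equals enumeration and stats::fisher.test", {
  expect_equal(fisher_peak_test(5, 1, 100, 100), oracle_fisher(5, 1, 100, 100),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    ip_total <- sample(20:200, 1); input_total <- sample(20:200, 1)
    a <- sample(0:min(15, ip_total), 1); b <- sample(0:min(15, input_total), 1)
    got <- fisher_peak_test(a, b, ip_total, input_total)
    exp_enum <- oracle_fisher(a, b, ip_total, input_total)
    expect_equal(got, exp_enum, tolerance = 1e-12)
    ref <- stats::fisher.test(matrix(c(a, ip_total - a, b, input_total - b),
                                     2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-9)
  }
  # one-sided option agrees with fisher.test alternative = "greater"
  got1 <- fisher_peak_test(12, 2, 300, 300, sided = "greater")
  ref1 <- stats::fisher.test(matrix(c(12, 288, 2, 298), 2, byrow = TRUE),
                             alternative = "greater")$p.value
  expect_equal(got1, ref1, tolerance = 1e-9)
})

test_that("call_significant applies direction filter and Bonferroni", {
  mk <- function(ip, input, n = length(ip)) {
    peak_set(data.frame(peak_id = sprintf("p%d", seq_len(n)), chrom = "chr1",
                        start = (seq_len(n) - 1L) * 100L,
                        end = seq_len(n) * 100L, strand = "+",
                        ip_reads = ip, input_reads = input),
             ip_total = 1e6, input_total = 1e6)
  }
  # single strongly enriched peak at m = 1: significant
  one <- call_significant(mk(80, 2))
  expect_lt(one$peaks$p_raw, 1e-8)
  expect_true(one$peaks$significant)
  expect_equal(one$peaks$p_bonf, one$peaks$p_raw)

  # same counts swapped: tiny p but direction filter blocks the call
  swapped <- call_significant(mk(2, 80))
  expect_lt(swapped$peaks$p_bonf, 1e-8)
  expect_false(swapped$peaks$significant)

  # Bonferroni arithmetic: m identical peaks multiply p by m
  m10 <- call_significant(mk(rep(80, 10), rep(2, 10)))
  expect_equal(m10$peaks$p_bonf, pmin(1, m10$peaks$p_raw * 10))

  # borderline peak significant alone but not after correction over m = 10
  p1 <- fisher_peak_test(36, 2, 1e6, 1e6)
  expect_true(p1 < 1e-8 && p1 * 10 > 1e-8)   # chosen to straddle alpha
  alone <- call_significant(mk(36, 2))
  expect_true(alone$peaks$significant)
  crowd <- call_significant(mk(rep(36, 10), rep(2, 10)))
  expect_false(any(crowd$peaks$significant))

  # monotone: larger alpha can only add calls
  strict <- call_significant(mk(rep(80, 10), rep(2, 10)), alpha = 1e-30)
  expect_true(all(which(strict$peaks$significant) %in%
                    which(m10$peaks$significant)))
})

test_that("peak_set validates intervals and counts", {
  df <- data.frame(peak_id = "p1", chrom = "chr1", start = 10, end = 5,
                   strand = "+", ip_reads = 1, input_reads = 1)
  expect_error(peak_set(df, 100, 100), "start < end")
  df$end <- 20; df$ip_reads <- 200
  expect_error(peak_set(df, 100, 100), "exceed")
})

test_that("derive_target_set: de-duplication, strand rule, RBP removal", {
  ann <- toy_annotation()
  mk <- function(chrom, start, end, strand) {
    n <- length(start)
    ps <- peak_set(data.frame(peak_id = sprintf("q%d", seq_len(n)),
                              chrom = chrom, start = start, end = end,
                              strand = strand,
                              ip_reads = 80L, input_reads = 1L),
                   ip_total = 1e6, input_total = 1e6)
    call_significant(ps)
  }
  # three peaks in one gene -> one target
  ts <- derive_target_set(mk("chr1", c(1100, 2500, 9500),
                             c(1150, 2550, 9550), "+"), ann, "someRBP")
  expect_identical(ts$target_gene_ids, "gA")

  # antisense peak is not a target
  expect_error(derive_target_set(mk("chr1", 2500, 2550, "-"), ann, "x"),
               "no gene")

  # the RBP's own gene is removed from the target set
  both <- mk("chr1", c(2500, 21500), c(2550, 21550), c("+", "-"))
  ts2 <- derive_target_set(both, ann, "gA")
  expect_identical(ts2$target_gene_ids, "gB")

  # no significant peaks is an error with guidance
  null_ps <- peak_set(data.frame(peak_id = "p", chrom = "chr1", start = 2500,
                                 end = 2550, strand = "+", ip_reads = 3L,
                                 input_reads = 3L), 1e6, 1e6)
  expect_error(derive_target_set(call_significant(null_ps), ann, "x"),
               "no significant peaks")
})

test_that("planted eCLIP targets are recovered with high precision/recall", {
  cfg <- sim_eclip_config(n_genes = 20, n_true_sites = 20,
                          enrichment_lambda = 10, background_rate = 20,
                          seed = 5)
  sim <- simulate_eclip(cfg)
  called <- call_significant(sim$peaks)
  ts <- derive_target_set(called, sim$annotation, "Rbp1")
  truth_genes <- unique(sim$truth$gene_id)
  recall <- length(intersect(ts$target_gene_ids, truth_genes)) /
    length(truth_genes)
  precision <- length(intersect(ts$target_gene_ids, truth_genes)) /
    length(ts$target_gene_ids)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
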