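# Peak-to-feature assignment and metagene profiles.

test_that("assignment honors containment, the proximal rule and priority", {
  ann <- toy_annotation()
  pk <- function(chrom, start, end, strand = "+") {
    data.frame(chrom = chrom, start = start, end = end, strand = strand)
  }
  # wholly inside gA's 3'UTR [10000, 11000)
  expect_identical(assign_peak_feature(pk("chr1", 10100, 10200), ann), "3UTR")
  # centered 300 nt into the intron from the splice site at 3000
  expect_identical(assign_peak_feature(pk("chr1", 3280, 3320), ann),
                   "proximal_intron")
  # deep intron
  expect_identical(assign_peak_feature(pk("chr1", 3900, 4100), ann),
                   "distal_intron")
  # no same-strand overlap
  expect_identical(assign_peak_feature(pk("chr1", 10100, 10200, "-"), ann),
                   "other")
  expect_identical(assign_peak_feature(pk("chr3", 100, 200), ann), "other")
  # tie: equal CDS and 3'UTR overlap around 10000 -> priority picks 3'UTR
  expect_identical(assign_peak_feature(pk("chr1", 9900, 10100), ann), "3UTR")
  expect_error(assign_peak_feature(pk("chr1", 50, 10), ann), "malformed")
})

test_that("assignment equals the per-base brute-force counter", {
  ann <- toy_annotation()
  set.seed(77)
  peaks <- random_peaks(120, ann, width_range = c(10, 300))
  got <- assign_peak_feature(peaks, ann)
  want <- vapply(seq_len(nrow(peaks)), function(i) {
    oracle_assign_feature(peaks[i, ], ann$genes)
  }, character(1))
  expect_identical(got, want)
})

test_that("feature_distribution normalizes and recovers planted bias", {
  ann <- toy_annotation()
  one <- data.frame(chrom = "chr1", start = c(10100, 10300),
                    end = c(10200, 10400), strand = "+")
  fd <- feature_distribution(one, ann)
  expect_equal(sum(fd$fraction), 1)
  expect_equal(fd$fraction[fd$category == "3UTR"], 1)
  expect_error(feature_distribution(one[0, ], ann), "empty")

  # Monte-Carlo recovery of the planted placement probability
  cfg <- sim_eclip_config(n_genes = 60, n_true_sites = 150,
                          enrichment_lambda = 10,
                          feature_bias = c("5UTR" = 1, "CDS" = 1,
                                           "proximal_intron" = 1,
                                           "distal_intron" = 1, "3UTR" = 4),
                          seed = 21)
  sim <- simulate_eclip(cfg)
  called <- call_significant(sim$peaks)
  sig <- called$peaks[called$peaks$significant, ]
  fd <- feature_distribution(sig, sim$annotation)
  p <- attr(sim$truth, "placement_prob")[["3UTR"]]
  se <- sqrt(p * (1 - p) / nrow(sig))
  expect_lt(abs(fd$fraction[fd$category == "3UTR"] - p), 3 * se + 0.02)
  expect_equal(sum(fd$fraction), 1)
})

test_that("metagene: uniform coverage, strand orientation, normalization", {
  ann <- toy_annotation()
  # one interval covering all of gA, 10 bins -> 0.1 each
  full <- data.frame(chrom = "chr1", start = 1000, end = 11000, strand = "+")
  expect_equal(metagene_profile(full, ann, n_bins = 10), rep(0.1, 10))
  # 5'-most 1% of minus-strand gB (genomic right end) -> mass in bin 1
  tip <- data.frame(chrom = "chr1", start = 29950, end = 30000, strand = "-")
  prof <- metagene_profile(tip, ann, n_bins = 100)
  expect_equal(prof[1], 1)
  expect_equal(sum(prof), 1)
  # profile sums to 1 for arbitrary input
  set.seed(5)
  pks <- random_peaks(50, ann)
  expect_equal(sum(metagene_profile(pks, ann, 100)), 1)
})

test_that("metagene equals the per-base histogram oracle", {
  ann <- toy_annotation()   # gene lengths are multiples of 10 and 100
  set.seed(19)
  for (n_bins in c(10, 100)) {
    pks <- random_peaks(40, ann)
    expect_equal(metagene_profile(pks, ann, n_bins),
                 oracle_metagene(pks, ann$genes, n_bins), tolerance = 1e-12)
  }
})

test_that("metagene union equals count-weighted mixture; strand flip reverses", {
  ann <- toy_annotation()
  # equal-mass sets: one 100-nt interval each, fully inside gA
  a <- data.frame(chrom = "chr1", start = 1200, end = 1300, strand = "+")
  b <- data.frame(chrom = "chr1", start = 9400, end = 9500, strand = "+")
  pa <- metagene_profile(a, ann, 20); pb <- metagene_profile(b, ann, 20)
  pu <- metagene_profile(rbind(a, b), ann, 20)
  expect_equal(pu, (pa + pb) / 2, tolerance = 1e-12)

  # flipping every gene strand mirrors the profile of unstranded intervals
  flipped <- ann$genes
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  ann_flip <- gene_annotation(flipped)
  iv <- data.frame(chrom = "chr1", start = c(1200, 21500),
                   end = c(1300, 21600), strand = "*")
  expect_equal(metagene_profile(iv, ann_flip, 50),
               rev(metagene_profile(iv, ann, 50)), tolerance = 1e-12)
})
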