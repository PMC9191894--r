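# Fixture builders shared across tests. Everything is generated in code;
# no data files ship with the tests.

# Two coding genes on opposite strands plus one noncoding single-exon gene.
# Gene lengths are multiples of common bin counts (10, 100) on purpose.
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(1000L, 20000L, 100L),
    tx_end = c(11000L, 30000L, 1100L),
    cds_start = c(2000L, 21000L, 100L),
    cds_end = c(10000L, 29000L, 100L),
    exon_starts = I(list(c(1000L, 5000L, 9000L), c(20000L, 26000L), 100L)),
    exon_sizes = I(list(c(2000L, 2000L, 2000L), c(4000L, 4000L), 1000L)),
    stringsAsFactors = FALSE))
}

random_peaks <- function(n, annotation, width_range = c(20, 400)) {
  g <- annotation$genes
  gi <- sample(nrow(g), n, replace = TRUE)
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  lo <- g$tx_start[gi] - 200L
  hi <- pmax(lo + 1L, g$tx_end[gi] + 200L - w)
  start <- lo + floor(runif(n) * (hi - lo))
  data.frame(peak_id = sprintf("rp%04d", seq_len(n)),
             chrom = g$chrom[gi], start = start, end = start + w,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

small_sim <- function(seed, k_star = 2L, K = 4L, fold = 5) {
  prof <- rep(2, K)
  prof[k_star + 1L] <- 2 * fold
  simulate_cell_counts(sim_cells_config(
    n_clusters = K, cells_per_cluster = 30, n_genes = 60, n_targets = 10,
    target_peak_cluster = k_star, target_unspliced_profile = prof,
    rbp_profile = rep(8, K), background_mean = 2, seed = seed))
}

random_events <- function(n, seed_offset = 0) {
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             intron_start = s <- sample.int(100000L, n),
             intron_end = s + sample.int(5000L, n),
             cluster_id = sprintf("clu%d", seq_len(n)),
             dpsi = runif(n, -1, 1), fdr = runif(n),
             stringsAsFactors = FALSE)
}
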