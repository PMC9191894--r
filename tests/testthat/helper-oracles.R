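# Independent oracle implementations used to cross-check the package.
# Each is a deliberately naive re-derivation (loops, per-base counting,
# full enumeration) kept free of the code paths it checks.

# Naive per-cell engagement score: straight-line transcription of
# (sum_t u/N) / (r/N) with explicit loops over a dense matrix.
oracle_scores <- function(spliced, unspliced, gene_ids, rbp, targets,
                          total = "spliced+unspliced") {
  spliced <- as.matrix(spliced); unspliced <- as.matrix(unspliced)
  n_cells <- ncol(spliced)
  out <- rep(NA_real_, n_cells)
  for (c_ in seq_len(n_cells)) {
    N_c <- sum(spliced[, c_]) + if (total == "spliced+unspliced")
      sum(unspliced[, c_]) else 0
    r_c <- spliced[gene_ids == rbp, c_]
    if (r_c == 0) next
    u_sum <- 0
    for (g in targets) u_sum <- u_sum + unspliced[gene_ids == g, c_]
    out[c_] <- (u_sum / N_c) / (r_c / N_c)
  }
  out
}

# Percentile bootstrap CI of the median, coded independently but drawing
# the same RNG stream shape (n_boot iterations of sample()).
oracle_boot_ci <- function(x, n_boot, seed, conf = 0.95) {
  set.seed(seed)
  boots <- replicate(n_boot, median(sample(x, length(x), replace = TRUE)))
  unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), type = 7))
}

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins, probabilities from log-binomial-coefficient arithmetic.
oracle_fisher <- function(ip, input, ip_total, input_total) {
  m <- ip + input
  lo <- max(0L, m - input_total); hi <- min(ip_total, m)
  ks <- lo:hi
  logp <- lchoose(ip_total, ks) + lchoose(input_total, m - ks) -
    lchoose(ip_total + input_total, m)
  obs <- logp[ks == ip]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

# Upper-tail hypergeometric by term-wise enumeration.
oracle_hyper <- function(k, size_a, size_b, universe_n) {
  js <- k:min(size_a, size_b)
  sum(exp(lchoose(size_a, js) + lchoose(universe_n - size_a, size_b - js) -
            lchoose(universe_n, size_b)))
}

# Relative distance by per-query scan over sorted reference midpoints.
oracle_reldist <- function(query, reference) {
  d <- numeric(0); skipped <- 0L
  for (i in seq_len(nrow(query))) {
    rm_ <- sort((reference$start + reference$end)[
      reference$chrom == query$chrom[i]] / 2)
    x <- (query$start[i] + query$end[i]) / 2
    if (length(rm_) < 2L || x < rm_[1] || x > rm_[length(rm_)]) {
      skipped <- skipped + 1L
      next
    }
    best <- NA_real_
    for (j in seq_len(length(rm_) - 1L)) {
      if (x >= rm_[j] && x <= rm_[j + 1L]) {
        best <- if (rm_[j + 1L] > rm_[j]) {
          min(x - rm_[j], rm_[j + 1L] - x) / (rm_[j + 1L] - rm_[j])
        } else 0
        break
      }
    }
    d <- c(d, best)
  }
  list(d = d, n_skipped = skipped)
}

# Per-base feature category counter. For every base of the peak and every
# same-strand gene, derives the base's category straight from the gene
# definition; a base counts toward a category if any gene yields it.
oracle_base_category <- function(pos, gene, proximal_window = 500) {
  if (pos < gene$tx_start || pos >= gene$tx_end) return(NULL)
  ex_s <- gene$exon_starts[[1]]; ex_e <- ex_s + gene$exon_sizes[[1]]
  in_exon <- any(pos >= ex_s & pos < ex_e)
  coding <- gene$cds_start < gene$cds_end
  if (in_exon) {
    if (!coding) return("other")
    if (pos >= gene$cds_start && pos < gene$cds_end) return("CDS")
    before <- pos < gene$cds_start
    if (gene$strand == "+") return(if (before) "5UTR" else "3UTR")
    return(if (before) "3UTR" else "5UTR")
  }
  # intronic: distance to the flanking exon boundaries
  left <- max(ex_e[ex_e <= pos])
  right <- min(ex_s[ex_s > pos])
  d <- min(pos - left, right - 1 - pos)
  if (d < proximal_window) "proximal_intron" else "distal_intron"
}

oracle_assign_feature <- function(peak, genes, proximal_window = 500) {
  counts <- setNames(numeric(6), c("3UTR", "5UTR", "CDS", "proximal_intron",
                                   "distal_intron", "other"))
  for (pos in seq(peak$start, peak$end - 1L)) {
    cats <- character(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$chrom != peak$chrom) next
      if (peak$strand != "*" && g$strand != peak$strand) next
      cat <- oracle_base_category(pos, g, proximal_window)
      if (!is.null(cat) && cat != "other") cats <- c(cats, cat)
    }
    for (cat in unique(cats)) counts[cat] <- counts[cat] + 1
  }
  if (all(counts == 0)) return("other")
  names(counts)[which.max(counts)]
}

# Per-base metagene histogram; assumes every gene length is a multiple of
# n_bins so each base maps to exactly one bin.
oracle_metagene <- function(intervals, genes, n_bins) {
  prof <- numeric(n_bins)
  for (i in seq_len(nrow(intervals))) {
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (g$chrom != intervals$chrom[i]) next
      if (intervals$strand[i] != "*" && g$strand != intervals$strand[i]) next
      L <- g$tx_end - g$tx_start
      stopifnot(L %% n_bins == 0)
      os <- max(intervals$start[i], g$tx_start)
      oe <- min(intervals$end[i], g$tx_end)
      if (oe <= os) next
      for (pos in seq(os, oe - 1L)) {
        b <- ((pos - g$tx_start) * n_bins) %/% L
        if (g$strand == "-") b <- n_bins - 1L - b
        prof[b + 1L] <- prof[b + 1L] + 1
      }
    }
  }
  if (sum(prof) > 0) prof / sum(prof) else prof
}

# All-pairs greedy event matcher (quadratic, explicit).
oracle_match_events <- function(a, b, tolerance) {
  cand <- data.frame(idx_a = integer(0), idx_b = integer(0),
                     distance = numeric(0))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && a$strand[i] == b$strand[j] &&
        abs(a$intron_start[i] - b$intron_start[j]) <= tolerance &&
        abs(a$intron_end[i] - b$intron_end[j]) <= tolerance) {
      cand <- rbind(cand, data.frame(
        idx_a = i, idx_b = j,
        distance = abs(a$intron_start[i] - b$intron_start[j]) +
          abs(a$intron_end[i] - b$intron_end[j])))
    }
  }
  cand <- cand[order(cand$distance, cand$idx_a, cand$idx_b), ]
  taken_a <- c(); taken_b <- c(); n <- 0L
  for (r in seq_len(nrow(cand))) {
    if (!(cand$idx_a[r] %in% taken_a) && !(cand$idx_b[r] %in% taken_b)) {
      taken_a <- c(taken_a, cand$idx_a[r])
      taken_b <- c(taken_b, cand$idx_b[r])
      n <- n + 1L
    }
  }
  n
}
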