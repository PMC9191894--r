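# Synthetic eCLIP experiment: toy gene models, fixed-width candidate
# windows tiled over gene bodies, Poisson IP/input counts with an elevated
# IP rate at planted binding sites, and a truth table marking those sites.
# Peak *calling* is out of scope, so the candidate windows stand in for a
# caller's output and only the significance rule is exercised downstream.

#' Configuration for the eCLIP simulator
#'
#' Defaults plant 50 true binding sites over 30 genes with IP enrichment
#' 8-fold over a background of 20 expected input reads per 50-nt window,
#' with placement biased toward the 3'UTR and proximal introns (4:2 over
#' the other features), mirroring the binding-site distribution the scoring
#' pipeline expects to see.
#'
#' @param n_genes number of toy genes (laid head-to-tail on "chr1").
#' @param gene_length_range integer bounds (nt) for gene lengths.
#' @param feature_fractions named proportions of gene length for `utr5`,
#'   `cds`, `intron`, `utr3`; must sum to 1.
#' @param n_true_sites number of planted binding sites.
#' @param enrichment_lambda IP-over-input rate ratio at true sites (> 1).
#' @param background_rate expected input reads per candidate window.
#' @param feature_bias named relative placement weights of true sites over
#'   categories `5UTR`, `CDS`, `proximal_intron`, `distal_intron`, `3UTR`.
#' @param window_size candidate window width in nt (default 50,
#'   non-overlapping tiles).
#' @param n_cds_exons CDS exon count per gene (introns = n_cds_exons - 1).
#' @param proximal_window proximal-intron distance in nt (default 500).
#' @param outside_factor fraction of the library falling outside candidate
#'   windows, expressed as a multiple of the expected in-window background
#'   (default 9, i.e. windows hold ~10 percent of reads). Determines the
#'   reported library totals.
#' @param seed integer RNG seed.
#' @return object of class `sim_eclip_config`.
#' @export
sim_eclip_config <- function(n_genes = 30,
                             gene_length_range = c(3000L, 8000L),
                             feature_fractions = c(utr5 = 0.05, cds = 0.25,
                                                   intron = 0.55,
                                                   utr3 = 0.15),
                             n_true_sites = 50, enrichment_lambda = 8,
                             background_rate = 20,
                             feature_bias = c("5UTR" = 1, "CDS" = 1,
                                              "proximal_intron" = 2,
                                              "distal_intron" = 0.5,
                                              "3UTR" = 4),
                             window_size = 50, n_cds_exons = 4,
                             proximal_window = 500, outside_factor = 9,
                             seed = 1) {
  stopifnot(length(gene_length_range) == 2L,
            gene_length_range[1] <= gene_length_range[2])
  if (abs(sum(feature_fractions) - 1) > 1e-6) {
    stopf("feature_fractions must sum to 1")
  }
  if (!all(c("utr5", "cds", "intron", "utr3") %in% names(feature_fractions))) {
    stopf("feature_fractions needs names utr5, cds, intron, utr3")
  }
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes", min = 1L),
    gene_length_range = as.integer(gene_length_range),
    feature_fractions = feature_fractions,
    n_true_sites = assert_count(n_true_sites, "n_true_sites"),
    enrichment_lambda = assert_number(enrichment_lambda, "enrichment_lambda",
                                      min = 1, strict_min = TRUE),
    background_rate = assert_number(background_rate, "background_rate",
                                    min = 0, strict_min = TRUE),
    feature_bias = feature_bias,
    window_size = assert_count(window_size, "window_size", min = 1L),
    n_cds_exons = assert_count(n_cds_exons, "n_cds_exons", min = 1L),
    proximal_window = assert_number(proximal_window, "proximal_window",
                                    min = 0),
    outside_factor = assert_number(outside_factor, "outside_factor", min = 0),
    seed = assert_count(seed, "seed"))
  if (!all(FEATURE_LEVELS[FEATURE_LEVELS != "other"] %in%
           names(cfg$feature_bias))) {
    stopf("feature_bias needs names %s",
          paste(FEATURE_LEVELS[FEATURE_LEVELS != "other"], collapse = ", "))
  }
  structure(cfg, class = "sim_eclip_config")
}

# Deterministic gene layout given lengths/strands: contiguous genomic
# segments 5'UTR | CDS-exon/intron alternation | 3'UTR, mirrored on "-".
build_toy_gene <- function(gene_id, chrom, offset, len, strand, fr,
                           n_cds_exons) {
  len5 <- round(fr[["utr5"]] * len)
  len3 <- round(fr[["utr3"]] * len)
  lencds <- round(fr[["cds"]] * len)
  lenint <- len - len5 - len3 - lencds
  n_int <- max(n_cds_exons - 1L, 0L)
  split_even <- function(total, k) {
    if (k == 0L) return(integer(0))
    base <- total %/% k
    out <- rep(base, k); out[seq_len(total - base * k)] <- base + 1L
    out
  }
  cds_sz <- split_even(lencds, n_cds_exons)
  int_sz <- split_even(lenint, n_int)
  # transcript-order category runs (5' -> 3')
  runs <- list(c("utr5", len5))
  for (j in seq_len(n_cds_exons)) {
    runs[[length(runs) + 1L]] <- c("cds", cds_sz[j])
    if (j <= n_int) runs[[length(runs) + 1L]] <- c("intron", int_sz[j])
  }
  runs[[length(runs) + 1L]] <- c("utr3", len3)
  cats <- vapply(runs, `[`, character(1), 1L)
  sizes <- as.integer(vapply(runs, `[`, character(1), 2L))
  keep <- sizes > 0L
  cats <- cats[keep]; sizes <- sizes[keep]
  if (strand == "-") { cats <- rev(cats); sizes <- rev(sizes) }
  starts <- offset + cumsum(c(0L, sizes[-length(sizes)]))
  seg <- data.frame(start = starts, end = starts + sizes, tx_cat = cats,
                    stringsAsFactors = FALSE)
  exonic <- seg[seg$tx_cat != "intron", ]
  # merge adjacent exonic runs into exon blocks
  ex_s <- integer(0); ex_e <- integer(0)
  for (i in seq_len(nrow(exonic))) {
    if (length(ex_e) && exonic$start[i] == ex_e[length(ex_e)]) {
      ex_e[length(ex_e)] <- exonic$end[i]
    } else {
      ex_s <- c(ex_s, exonic$start[i]); ex_e <- c(ex_e, exonic$end[i])
    }
  }
  cds_rows <- seg[seg$tx_cat == "cds", ]
  list(gene = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         tx_start = offset, tx_end = offset + len,
                         cds_start = if (nrow(cds_rows)) min(cds_rows$start)
                                     else offset,
                         cds_end = if (nrow(cds_rows)) max(cds_rows$end)
                                   else offset,
                         exon_starts = I(list(ex_s)),
                         exon_sizes = I(list(ex_e - ex_s)),
                         stringsAsFactors = FALSE),
       segments = seg)
}

# Analysis category of a genomic position from the simulator's own segment
# table (kept independent of assign_peak_feature on purpose).
sim_position_category <- function(pos, segments, strand, proximal_window) {
  row <- which(segments$start <= pos & pos < segments$end)
  if (!length(row)) return("other")
  seg <- segments[row[1], ]
  cat <- switch(seg$tx_cat, utr5 = "5UTR", utr3 = "3UTR", cds = "CDS",
                intron = {
                  d <- min(pos - seg$start, seg$end - 1 - pos)
                  if (d < proximal_window) "proximal_intron"
                  else "distal_intron"
                })
  cat
}

#' Simulate an eCLIP experiment with planted binding sites
#'
#' Generates BED12-compatible toy gene models, tiles each gene body with
#' fixed-width candidate windows, plants `n_true_sites` binding sites by
#' sampling windows with `feature_bias` placement weights, and draws
#' Poisson read counts: IP at `background_rate * enrichment_lambda` for
#' true sites and `background_rate` elsewhere; input at `background_rate`
#' everywhere. Library totals add `outside_factor` times the expected
#' in-window background for reads outside the candidate set.
#'
#' @param config a [sim_eclip_config()].
#' @return list with `annotation` (a [gene_annotation()]), `peaks`
#'   (a [peak_set()]) and `truth` (data.frame `peak_id`, `gene_id`,
#'   `category` of planted sites, with the per-category placement
#'   probabilities as attribute `"placement_prob"`).
#' @export
simulate_eclip <- function(config) {
  stopifnot(inherits(config, "sim_eclip_config"))
  with_seed(config$seed, {
    lens <- sample(seq(config$gene_length_range[1],
                       config$gene_length_range[2]),
                   config$n_genes, replace = TRUE)
    strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    offset <- 1000L
    genes <- vector("list", config$n_genes)
    segs <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      gb <- build_toy_gene(sprintf("Gene%03d", i), "chr1", offset, lens[i],
                           strands[i], config$feature_fractions,
                           config$n_cds_exons)
      genes[[i]] <- gb$gene
      segs[[i]] <- gb$segments
      offset <- offset + lens[i] + 500L
    }
    gene_df <- do.call(rbind, genes)
    annotation <- gene_annotation(gene_df)

    # candidate windows: non-overlapping tiles of each gene body
    win <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
      g <- gene_df[i, ]
      n_w <- (g$tx_end - g$tx_start) %/% config$window_size
      if (n_w < 1L) return(NULL)
      s <- g$tx_start + (seq_len(n_w) - 1L) * config$window_size
      data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                 start = s, end = s + config$window_size, gene_idx = i,
                 stringsAsFactors = FALSE)
    }))
    win$peak_id <- sprintf("peak%05d", seq_len(nrow(win)))
    win$category <- vapply(seq_len(nrow(win)), function(r) {
      mid <- (win$start[r] + win$end[r]) %/% 2
      sim_position_category(mid, segs[[win$gene_idx[r]]], win$strand[r],
                            config$proximal_window)
    }, character(1))

    if (config$n_true_sites > nrow(win)) {
      stopf("n_true_sites (%d) exceeds the %d candidate windows",
            config$n_true_sites, nrow(win))
    }
    weights <- config$feature_bias[win$category]
    weights[is.na(weights)] <- 0
    true_idx <- if (config$n_true_sites > 0) {
      sort(sample(seq_len(nrow(win)), config$n_true_sites, replace = FALSE,
                  prob = weights))
    } else integer(0)
    is_true <- seq_len(nrow(win)) %in% true_idx

    bg <- config$background_rate
    ip <- rpois(nrow(win), bg * ifelse(is_true, config$enrichment_lambda, 1))
    input <- rpois(nrow(win), bg)
  })

  outside <- round(config$outside_factor * nrow(win) * config$background_rate)
  peaks <- peak_set(data.frame(peak_id = win$peak_id, chrom = win$chrom,
                               start = win$start, end = win$end,
                               strand = win$strand, ip_reads = ip,
                               input_reads = input,
                               stringsAsFactors = FALSE),
                    ip_total = sum(ip) + outside,
                    input_total = sum(input) + outside)
  truth <- win[is_true, c("peak_id", "gene_id", "category")]
  rownames(truth) <- NULL
  wsum <- tapply(weights, win$category, sum)
  placement <- setNames(rep(0, length(FEATURE_LEVELS)), FEATURE_LEVELS)
  placement[names(wsum)] <- wsum / sum(weights)
  attr(truth, "placement_prob") <- placement
  list(annotation = annotation, peaks = peaks, truth = truth)
}
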