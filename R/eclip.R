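# eCLIP peak enrichment against size-matched input.
#
# A peak is significant when it holds more IP reads than input reads and its
# Bonferroni-corrected two-sided Fisher exact p-value falls below alpha
# (default 1e-8). Fold enrichment compares the peak's share of the IP
# library with its share of the input library.

#' Candidate eCLIP peak set with IP/input read counts
#'
#' @param peaks data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `strand`, `ip_reads`, `input_reads` (coordinates 0-based half-open).
#' @param ip_total,input_total usable-read totals of the IP and size-matched
#'   input libraries. These are metadata supplied with the peak calls, not
#'   recomputed from the candidate windows.
#' @return object of class `peak_set`: the validated data.frame plus totals.
#' @export
peak_set <- function(peaks, ip_total, input_total) {
  need <- c("peak_id", "chrom", "start", "end", "strand", "ip_reads",
            "input_reads")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stopf("peak table lacks columns: %s",
                          paste(miss, collapse = ", "))
  ip_total <- assert_count(ip_total, "ip_total", min = 1L)
  input_total <- assert_count(input_total, "input_total", min = 1L)
  if (any(peaks$start < 0) || any(peaks$end <= peaks$start)) {
    stopf("peak intervals must satisfy 0 <= start < end")
  }
  if (!all(peaks$strand %in% c("+", "-", "*"))) stopf("bad strand values")
  if (any(peaks$ip_reads < 0) || any(peaks$input_reads < 0)) {
    stopf("read counts must be nonnegative")
  }
  if (any(peaks$ip_reads > ip_total) || any(peaks$input_reads > input_total)) {
    stopf("per-peak reads cannot exceed library totals")
  }
  structure(list(peaks = as.data.frame(peaks), ip_total = ip_total,
                 input_total = input_total), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  sig <- if ("significant" %in% names(x$peaks)) sum(x$peaks$significant)
         else NA_integer_
  cat(sprintf("peak_set: %d peaks (ip_total=%d, input_total=%d, significant=%s)\n",
              nrow(x$peaks), x$ip_total, x$input_total, format(sig)))
  invisible(x)
}

#' Fold enrichment of IP over size-matched input
#'
#' FE = (ip_reads/ip_total) / (input_reads/input_total). A peak with IP
#' reads but zero input reads has infinite enrichment; a peak with zero
#' reads in both libraries is undefined (`NaN`).
#'
#' @param ip_reads,input_reads per-peak read counts (vectorized).
#' @param ip_total,input_total library totals (> 0).
#' @return numeric vector of fold enrichments (may contain `Inf`/`NaN`).
#' @export
fold_enrichment <- function(ip_reads, input_reads, ip_total, input_total) {
  ip_total <- assert_count(ip_total, "ip_total", min = 1L)
  input_total <- assert_count(input_total, "input_total", min = 1L)
  if (any(ip_reads > ip_total) || any(input_reads > input_total)) {
    stopf("reads exceed library totals")
  }
  fe <- (ip_reads / ip_total) / (input_reads / input_total)
  fe[ip_reads == 0 & input_reads == 0] <- NaN
  fe
}

#' Two-sided Fisher exact test of a peak's IP/input counts
#'
#' Tests the 2x2 table \[\[ip_reads, ip_total-ip_reads\],
#' \[input_reads, input_total-input_reads\]\]. Computed directly from the
#' noncentral-free hypergeometric likelihood in log space: the two-sided p
#' sums the probabilities of all tables (same margins) no more likely than
#' the observed one, with the conventional 1e-7 relative tolerance for
#' likelihood ties. Because per-peak read counts are small relative to the
#' library totals, the support has at most `ip_reads + input_reads + 1`
#' points and the sum is exact and fast.
#'
#' @inheritParams fold_enrichment
#' @param sided `"two"` (default) or `"greater"` (IP-enriched one-sided).
#' @return numeric vector of p-values.
#' @export
fisher_peak_test <- function(ip_reads, input_reads, ip_total, input_total,
                             sided = c("two", "greater")) {
  sided <- match.arg(sided)
  ip_total <- assert_count(ip_total, "ip_total", min = 1L)
  input_total <- assert_count(input_total, "input_total", min = 1L)
  if (length(input_reads) != length(ip_reads)) {
    stopifnot(length(input_reads) == 1L || length(ip_reads) == 1L)
  }
  n <- max(length(ip_reads), length(input_reads))
  ip_reads <- rep_len(ip_reads, n); input_reads <- rep_len(input_reads, n)
  if (any(ip_reads > ip_total) || any(input_reads > input_total)) {
    stopf("reads exceed library totals")
  }
  vapply(seq_len(n), function(i) {
    a <- ip_reads[i]; c_ <- input_reads[i]
    m <- a + c_                       # peak-read margin
    if (m == 0) return(1)
    lo <- max(0, m - input_total); hi <- min(ip_total, m)
    k <- lo:hi
    logp <- dhyper(k, ip_total, input_total, m, log = TRUE)
    log_obs <- logp[k == a]
    if (sided == "greater") {
      sum(exp(logp[k >= a]))
    } else {
      min(1, sum(exp(logp[logp <= log_obs + log(1 + 1e-7)])))
    }
  }, numeric(1))
}

#' Annotate a peak set with enrichment statistics and significance calls
#'
#' Computes fold enrichment, raw and Bonferroni-corrected Fisher p-values
#' over the m candidate peaks, and flags peaks significant when the IP read
#' count strictly exceeds the input read count AND the corrected p-value is
#' below `alpha`.
#'
#' @param x a [peak_set()].
#' @param alpha family-wise significance threshold (default 1e-8).
#' @param sided sidedness of the Fisher test, see [fisher_peak_test()].
#' @return the peak set with columns `fold_enrichment`, `p_raw`, `p_bonf`,
#'   `significant` added to `$peaks`.
#' @export
call_significant <- function(x, alpha = 1e-8, sided = c("two", "greater")) {
  stopifnot(inherits(x, "peak_set"))
  alpha <- assert_number(alpha, "alpha", min = 0, max = 1)
  m <- nrow(x$peaks)
  if (m == 0L) stopf("no candidate peaks to test")
  p <- x$peaks
  p$fold_enrichment <- fold_enrichment(p$ip_reads, p$input_reads,
                                       x$ip_total, x$input_total)
  p$p_raw <- fisher_peak_test(p$ip_reads, p$input_reads, x$ip_total,
                              x$input_total, sided = sided)
  p$p_bonf <- pmin(1, p$p_raw * m)
  p$significant <- p$ip_reads > p$input_reads & p$p_bonf < alpha
  x$peaks <- p
  x$alpha <- alpha
  x
}

#' Derive an RBP target set from significant peaks
#'
#' Target genes are the unique genes overlapped (same strand, at least one
#' nucleotide) by at least one significant peak. The RBP frequently binds
#' its own transcript; such peaks remain in the peak report but the RBP gene
#' is removed from the returned target set.
#'
#' @param x a [peak_set()] annotated by [call_significant()].
#' @param annotation a [gene_annotation()] covering the peak chromosomes.
#' @param rbp_gene_id identifier of the immunoprecipitated RBP's gene.
#' @return a [target_set()].
#' @export
derive_target_set <- function(x, annotation, rbp_gene_id) {
  stopifnot(inherits(x, "peak_set"), inherits(annotation, "gene_annotation"))
  if (!"significant" %in% names(x$peaks)) {
    x <- call_significant(x)
  }
  sig <- x$peaks[x$peaks$significant, , drop = FALSE]
  if (!nrow(sig)) {
    stopf(paste("no significant peaks: cannot derive a target set.",
                "Relax alpha or check library totals."))
  }
  pk <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$start + 1L, sig$end),
                               strand = sig$strand)
  genes <- annotation$genes
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tx_start + 1L,
                                                genes$tx_end),
                               strand = genes$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pk, gn, minoverlap = 1L,
                                ignore.strand = FALSE))
  ids <- unique(genes$gene_id[S4Vectors::subjectHits(hits)])
  ids <- setdiff(ids, rbp_gene_id)
  if (!length(ids)) {
    stopf("significant peaks overlap no gene other than the RBP itself")
  }
  target_set(rbp_gene_id, ids, provenance = "eCLIP significant peaks")
}

#' Write / read a peak set (BED6 + counts TSV + totals JSON)
#'
#' `write_peak_set()` writes `<prefix>.bed` (BED6; score column carries the
#' IP read count), `<prefix>_counts.tsv` (`peak_id`, `ip_reads`,
#' `input_reads`, plus any computed statistics) and `<prefix>_totals.json`.
#' `read_peak_set()` reads them back.
#'
#' @param x a [peak_set()].
#' @param prefix path prefix for the three files.
#' @return `prefix` (write) or a [peak_set()] (read).
#' @export
write_peak_set <- function(x, prefix) {
  stopifnot(inherits(x, "peak_set"))
  p <- x$peaks
  bed <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                    name = p$peak_id, score = p$ip_reads, strand = p$strand)
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cnt <- p[, setdiff(names(p), c("chrom", "start", "end", "strand")),
           drop = FALSE]
  write_tsv(cnt, paste0(prefix, "_counts.tsv"))
  jsonlite::write_json(list(ip_total = x$ip_total,
                            input_total = x$input_total),
                       paste0(prefix, "_totals.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_peak_set
#' @export
read_peak_set <- function(prefix) {
  bed <- utils::read.delim(paste0(prefix, ".bed"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "peak_id", "score", "strand")
  cnt <- read_tsv(paste0(prefix, "_counts.tsv"))
  tot <- jsonlite::read_json(paste0(prefix, "_totals.json"))
  df <- merge(bed[, c("peak_id", "chrom", "start", "end", "strand")], cnt,
              by = "peak_id", sort = FALSE)
  df <- df[match(bed$peak_id, df$peak_id), ]
  rownames(df) <- NULL
  peak_set(df, tot$ip_total, tot$input_total)
}
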