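# Peak-to-feature assignment and metagene percentile profiles.
#
# A peak's category is the gene feature with the largest base overlap,
# counted against the strand-matched union of each category's segments; ties
# go to the higher-priority category (3'UTR > 5'UTR > CDS > proximal intron
# > distal intron). Intronic bases within `proximal_window` nt of an exon
# boundary count as proximal intron. Peaks overlapping no same-strand gene
# are "other".

segments_grl_by_category <- function(annotation, proximal_window) {
  segs <- annotation_segments(annotation, proximal_window)
  gr <- GenomicRanges::GRanges(segs$chrom,
                               IRanges::IRanges(segs$start + 1L, segs$end),
                               strand = segs$strand)
  S4Vectors::mcols(gr)$category <- segs$category
  lapply(setNames(nm = FEATURE_LEVELS[FEATURE_LEVELS != "other"]),
         function(cat) {
           GenomicRanges::reduce(gr[S4Vectors::mcols(gr)$category == cat])
         })
}

#' Assign peaks to gene feature categories
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open), or a [peak_set()].
#' @param annotation a [gene_annotation()].
#' @param proximal_window intronic bases within this many nt of an exon
#'   boundary are proximal intron (default 500, the usual CLIP convention).
#' @return character vector of categories, one per peak, from
#'   `c("3UTR", "5UTR", "CDS", "proximal_intron", "distal_intron", "other")`.
#' @export
assign_peak_feature <- function(peaks, annotation, proximal_window = 500) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(peaks)))
  if (!nrow(peaks)) return(character(0))
  if (any(peaks$end <= peaks$start)) stopf("malformed interval (end <= start)")
  by_cat <- segments_grl_by_category(annotation, proximal_window)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end),
                               strand = peaks$strand)
  ov <- vapply(by_cat, function(segs) {
    # peaks on chromosomes absent from the annotation simply do not overlap
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(pk, segs, ignore.strand = FALSE))
    w <- suppressWarnings(GenomicRanges::width(IRanges::pintersect(
      pk[S4Vectors::queryHits(hits)], segs[S4Vectors::subjectHits(hits)])))
    out <- numeric(length(pk))
    if (length(hits)) {
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }, numeric(length(pk)))
  ov <- matrix(ov, nrow = length(pk),
               dimnames = list(NULL, names(by_cat)))
  # columns are already in priority order: ties resolved by first maximum
  cat <- apply(ov, 1L, function(row) {
    if (all(row == 0)) "other" else names(by_cat)[which.max(row)]
  })
  unname(cat)
}

#' Genomic feature distribution of a peak set
#'
#' Counts peaks per feature category and normalizes to fractions (the
#' "genomic distribution of peaks" summary).
#'
#' @inheritParams assign_peak_feature
#' @return data.frame with columns `category`, `count`, `fraction`; the
#'   fractions sum to 1.
#' @export
feature_distribution <- function(peaks, annotation, proximal_window = 500) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  if (!nrow(peaks)) stopf("empty peak set")
  cats <- assign_peak_feature(peaks, annotation, proximal_window)
  tab <- table(factor(cats, levels = FEATURE_LEVELS))
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Metagene percentile profile of interval coverage
#'
#' Maps each gene body to the unit interval 5' to 3' (strand-aware: on minus
#' strand genomic right is 0) and apportions every interval's base overlap
#' with each same-strand gene across `n_bins` equal percentile bins by
#' fractional base overlap. The profile is normalized to sum to 1.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open); `strand = "*"` matches both gene strands.
#' @param annotation a [gene_annotation()].
#' @param n_bins number of percentile bins (default 100).
#' @return numeric vector of length `n_bins` summing to 1 (all zero if no
#'   interval overlaps a gene).
#' @export
metagene_profile <- function(intervals, annotation, n_bins = 100) {
  n_bins <- assert_count(n_bins, "n_bins", min = 1L)
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  if (any(g$tx_end <= g$tx_start)) stopf("zero-length gene body")
  prof <- numeric(n_bins)
  iv <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end),
                               strand = intervals$strand %||% "*")
  gn <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$tx_start + 1L, g$tx_end),
                               strand = g$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(iv, gn, ignore.strand = FALSE))
  for (h in seq_along(hits)) {
    qi <- S4Vectors::queryHits(hits)[h]; si <- S4Vectors::subjectHits(hits)[h]
    L <- g$tx_end[si] - g$tx_start[si]
    os <- max(intervals$start[qi], g$tx_start[si])
    oe <- min(intervals$end[qi], g$tx_end[si])
    a <- (os - g$tx_start[si]) / L
    b <- (oe - g$tx_start[si]) / L
    if (g$strand[si] == "-") { tmp <- a; a <- 1 - b; b <- 1 - tmp }
    # apportion [a, b) across bins by overlap length
    lo <- max(1L, floor(a * n_bins) + 1L)
    hi <- min(n_bins, ceiling(b * n_bins))
    for (k in lo:hi) {
      bin_a <- (k - 1) / n_bins; bin_b <- k / n_bins
      w <- max(0, min(b, bin_b) - max(a, bin_a))
      prof[k] <- prof[k] + w * L   # in base units
    }
  }
  s <- sum(prof)
  if (s > 0) prof <- prof / s
  prof
}
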