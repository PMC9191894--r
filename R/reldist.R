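# Relative-distance colocalization statistic (bedtools reldist semantics):
# the position of each query interval's midpoint between its two flanking
# reference midpoints, scaled to [0, 0.5]. Under spatial independence the
# distribution is flat with mean 0.25; colocalized sets pile up near 0.

#' Relative distance between query and reference intervals
#'
#' For each query midpoint x lying between consecutive sorted reference
#' midpoints L <= x <= R (same chromosome), computes
#' `d = min(x - L, R - x) / (R - L)`. Queries outside the reference
#' midpoint span, or on chromosomes with fewer than two reference
#' intervals, are skipped and counted.
#'
#' @param query,reference data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open). Strand is ignored, as in the underlying genomic
#'   convention.
#' @param bin_width histogram bin width on \[0, 0.5\] (default 0.01).
#' @return list with `d` (numeric vector of relative distances, in query
#'   order among retained queries), `n_skipped`, and `histogram`
#'   (data.frame `reldist`, `count`, `total`, `fraction`).
#' @export
relative_distance <- function(query, reference, bin_width = 0.01) {
  stopifnot(all(c("chrom", "start", "end") %in% names(query)),
            all(c("chrom", "start", "end") %in% names(reference)))
  if (!nrow(reference)) stopf("empty reference interval set")
  bin_width <- assert_number(bin_width, "bin_width", min = 0, strict_min = TRUE)
  qmid <- (query$start + query$end) / 2
  rmid <- (reference$start + reference$end) / 2
  d_all <- rep(NA_real_, nrow(query))
  n_skipped <- 0L
  for (chrom in unique(query$chrom)) {
    qi <- which(query$chrom == chrom)
    rm_ <- sort(rmid[reference$chrom == chrom])
    if (length(rm_) < 2L) { n_skipped <- n_skipped + length(qi); next }
    x <- qmid[qi]
    inside <- x >= rm_[1] & x <= rm_[length(rm_)]
    n_skipped <- n_skipped + sum(!inside)
    xi <- x[inside]
    k <- findInterval(xi, rm_, rightmost.closed = TRUE)
    L <- rm_[k]; R <- rm_[k + 1L]
    d <- ifelse(R > L, pmin(xi - L, R - xi) / (R - L), 0)
    d_all[qi[inside]] <- d
  }
  d <- d_all[!is.na(d_all)]
  n_bins <- ceiling(0.5 / bin_width)
  idx <- pmin(floor(d / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  hist <- data.frame(reldist = round((seq_len(n_bins) - 1L) * bin_width, 10),
                     count = counts, total = length(d),
                     fraction = if (length(d)) counts / length(d)
                                else rep(0, n_bins))
  list(d = d, n_skipped = n_skipped, histogram = hist)
}
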