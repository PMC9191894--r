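# Matching differential-splicing events across datasets. Events are intron
# intervals from upstream differential-splicing analysis (consumed, never
# computed here), carrying a cluster id, dPSI effect size and FDR.

#' Validate a splicing event table
#'
#' @param events data.frame with columns `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `cluster_id`, `dpsi`, `fdr` (coordinates 0-based
#'   half-open; `dpsi` in \[-1, 1\], `fdr` in \[0, 1\]).
#' @return the validated data.frame (class `splicing_events`).
#' @export
splicing_events <- function(events) {
  need <- c("chrom", "strand", "intron_start", "intron_end", "cluster_id",
            "dpsi", "fdr")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("event table lacks columns: %s",
                          paste(miss, collapse = ", "))
  events <- as.data.frame(events)
  if (any(events$intron_end <= events$intron_start)) {
    stopf("intron_start must be < intron_end")
  }
  if (any(events$fdr < 0 | events$fdr > 1)) stopf("fdr outside [0, 1]")
  if (any(abs(events$dpsi) > 1)) stopf("dpsi outside [-1, 1]")
  class(events) <- c("splicing_events", "data.frame")
  events
}

#' Match splicing events between two datasets
#'
#' Two events match when chromosome and strand agree and both intron
#' boundaries agree within `tolerance` nucleotides. Each event matches at
#' most one partner: candidate pairs are ranked by total boundary distance
#' (ties by row order in `a`, then `b`) and taken greedily, which is
#' deterministic.
#'
#' @param a,b splicing event tables (see [splicing_events()]).
#' @param tolerance maximum per-boundary discrepancy in nt (default 0,
#'   i.e. identical splice site locations).
#' @return list with `pairs` (data.frame `idx_a`, `idx_b`, `distance`),
#'   `n_matched`, and `jaccard` = matched / (nA + nB - matched).
#' @export
match_splicing_events <- function(a, b, tolerance = 0) {
  a <- splicing_events(a); b <- splicing_events(b)
  tolerance <- assert_number(tolerance, "tolerance", min = 0)
  cand <- NULL
  for (i in seq_len(nrow(a))) {
    j <- which(b$chrom == a$chrom[i] & b$strand == a$strand[i] &
                 abs(b$intron_start - a$intron_start[i]) <= tolerance &
                 abs(b$intron_end - a$intron_end[i]) <= tolerance)
    if (length(j)) {
      d <- abs(b$intron_start[j] - a$intron_start[i]) +
        abs(b$intron_end[j] - a$intron_end[i])
      cand <- rbind(cand, data.frame(idx_a = i, idx_b = j, distance = d))
    }
  }
  pairs <- data.frame(idx_a = integer(0), idx_b = integer(0),
                      distance = numeric(0))
  if (!is.null(cand)) {
    cand <- cand[order(cand$distance, cand$idx_a, cand$idx_b), ]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      ia <- cand$idx_a[r]; ib <- cand$idx_b[r]
      if (!used_a[ia] && !used_b[ib]) {
        keep[r] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
      }
    }
    pairs <- cand[keep, ]
    rownames(pairs) <- NULL
  }
  n_matched <- nrow(pairs)
  list(pairs = pairs, n_matched = n_matched,
       jaccard = n_matched / (nrow(a) + nrow(b) - n_matched))
}

#' Upper-tail hypergeometric gene-set overlap test
#'
#' Probability of observing at least `k` genes in common between two gene
#' sets of sizes `size_a` and `size_b` drawn from a universe of `universe_n`
#' genes: `P(X >= k)` for `X ~ Hypergeometric(universe_n, size_a, size_b)`,
#' computed in log space for numerical range.
#'
#' @param k observed overlap count.
#' @param size_a,size_b gene-set sizes.
#' @param universe_n size of the gene universe (e.g. genes expressed in the
#'   compared experiments; supplied by the caller).
#' @param log return the natural log p-value instead.
#' @return the upper-tail p-value (or its log).
#' @examples
#' hypergeometric_overlap(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometric_overlap <- function(k, size_a, size_b, universe_n,
                                   log = FALSE) {
  k <- assert_count(k, "k"); size_a <- assert_count(size_a, "size_a")
  size_b <- assert_count(size_b, "size_b")
  universe_n <- assert_count(universe_n, "universe_n", min = 1L)
  if (size_a > universe_n || size_b > universe_n) {
    stopf("set sizes cannot exceed the universe")
  }
  if (k > min(size_a, size_b)) stopf("overlap k exceeds the smaller set")
  lp <- phyper(k - 1, size_a, universe_n - size_a, size_b,
               lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}
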