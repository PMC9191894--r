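# RBP-target engagement scoring.
#
# The score asks, cell by cell, how much nascent (unspliced) target RNA is
# available per unit of RBP expression:
#
#   E_c = ( sum_{g in targets} u_{g,c} / N_c ) / ( r_c / N_c )
#
# where u_{g,c} is the unspliced count of target gene g in cell c, r_c the
# RBP's count and N_c the cell's total read count. Both normalizations use
# the same N_c, so algebraically E_c = sum(u)/r_c; the normalized form is
# retained because N_c is a user-visible modelling choice.

resolve_totals_mode <- function(total = c("spliced+unspliced", "spliced")) {
  match.arg(total)
}

#' Engagement score of a single cell
#'
#' Computes the per-cell RBP-target engagement score: the fraction of
#' library-normalized unspliced target-gene counts over the
#' library-normalized RBP count. Cells in which the RBP is undetected
#' (denominator zero, score undefined) are flagged as excluded unless a
#' pseudocount is requested.
#'
#' @param counts a [cell_counts()] object.
#' @param targets a [target_set()]; targets absent from the count matrix are
#'   dropped with a message, but at least one must be present and the RBP
#'   gene itself must be present.
#' @param cell cell index (1-based) or cell identifier.
#' @param total which counts form the per-cell total N_c:
#'   `"spliced+unspliced"` (default) or `"spliced"`. The score is invariant
#'   to this choice because numerator and denominator share N_c.
#' @param rbp_counts which matrix supplies the RBP count r_c: `"spliced"`
#'   (default; mature mRNA gauges protein availability) or
#'   `"spliced+unspliced"`.
#' @param pseudocount nonnegative value added to r_c; default 0, in which
#'   case r_c = 0 yields an excluded cell rather than a score.
#' @return a list with `score` (nonnegative real, `NA` when excluded) and
#'   `excluded` (logical).
#' @seealso [score_cells()] for all cells at once.
#' @export
engagement_score_cell <- function(counts, targets, cell,
                                  total = c("spliced+unspliced", "spliced"),
                                  rbp_counts = c("spliced",
                                                 "spliced+unspliced"),
                                  pseudocount = 0) {
  res <- score_cells(counts, targets, total = total, rbp_counts = rbp_counts,
                     pseudocount = pseudocount, quiet = TRUE)
  if (is.character(cell)) cell <- match(cell, counts$cell_ids)
  if (is.na(cell) || cell < 1L || cell > nrow(res)) stopf("unknown cell")
  list(score = res$score[cell], excluded = res$excluded[cell])
}

#' Engagement scores for all cells
#'
#' Applies the per-cell engagement score to every cell of a count object.
#' Deterministic and order-preserving; scores are invariant to uniform
#' per-cell scaling of all counts and to gene ordering.
#'
#' @inheritParams engagement_score_cell
#' @param per_target if `TRUE`, additionally returns a per-target score
#'   matrix (`u_{g,c}/r_c`) as attribute `"per_target"`; the default single
#'   score per cell sums over targets before the ratio.
#' @param quiet suppress the dropped-target message.
#' @return a data.frame with columns `cell_id`, `cluster`, `score`,
#'   `excluded`. Excluded cells (RBP count zero with zero pseudocount) carry
#'   `NA` scores. The number of requested targets missing from the matrix is
#'   available as attribute `"n_targets_dropped"`.
#' @examples
#' s <- matrix(c(4, 1, 2, 8, 2, 4), 3, 2,
#'             dimnames = list(c("Rbp", "t1", "t2"), NULL))
#' u <- matrix(c(0, 2, 3, 0, 4, 6), 3, 2, dimnames = dimnames(s))
#' cc <- cell_counts(s, u, rownames(s), c("c1", "c2"), c(0, 0))
#' score_cells(cc, target_set("Rbp", c("t1", "t2")))
#' @export
score_cells <- function(counts, targets,
                        total = c("spliced+unspliced", "spliced"),
                        rbp_counts = c("spliced", "spliced+unspliced"),
                        pseudocount = 0, per_target = FALSE, quiet = FALSE) {
  stopifnot(inherits(counts, "cell_counts"), inherits(targets, "target_set"))
  total <- resolve_totals_mode(total)
  rbp_counts <- match.arg(rbp_counts)
  pseudocount <- assert_number(pseudocount, "pseudocount", min = 0)

  if (!targets$rbp_gene_id %in% counts$gene_ids) {
    stopf("RBP gene '%s' not found in count matrix", targets$rbp_gene_id)
  }
  present <- intersect(targets$target_gene_ids, counts$gene_ids)
  n_dropped <- length(targets$target_gene_ids) - length(present)
  if (!length(present)) {
    stopf("none of the %d target genes are present in the count matrix",
          length(targets$target_gene_ids))
  }
  if (n_dropped > 0L && !quiet) {
    message(sprintf("score_cells: %d of %d target genes absent from matrix; proceeding on %d",
                    n_dropped, length(targets$target_gene_ids),
                    length(present)))
  }

  n_c <- Matrix::colSums(counts$spliced)
  if (total == "spliced+unspliced") n_c <- n_c + Matrix::colSums(counts$unspliced)
  if (any(n_c <= 0)) stopf("every cell must have total read count N_c > 0")

  u_sum <- Matrix::colSums(counts$unspliced[present, , drop = FALSE])
  r_c <- as.numeric(counts$spliced[targets$rbp_gene_id, ])
  if (rbp_counts == "spliced+unspliced") {
    r_c <- r_c + as.numeric(counts$unspliced[targets$rbp_gene_id, ])
  }
  r_c <- r_c + pseudocount

  excluded <- r_c == 0
  score <- rep(NA_real_, length(r_c))
  # normalized form: (sum u / N_c) / (r_c / N_c)
  score[!excluded] <- (u_sum[!excluded] / n_c[!excluded]) /
    (r_c[!excluded] / n_c[!excluded])

  out <- data.frame(cell_id = counts$cell_ids,
                    cluster = counts$cluster_labels,
                    score = score, excluded = excluded,
                    stringsAsFactors = FALSE)
  attr(out, "n_targets_dropped") <- n_dropped
  if (isTRUE(per_target)) {
    pt <- as.matrix(counts$unspliced[present, , drop = FALSE])
    pt <- sweep(pt, 2, ifelse(excluded, NA_real_, r_c), "/")
    colnames(pt) <- counts$cell_ids
    attr(out, "per_target") <- pt
  }
  out
}

#' Cluster-level summary of engagement scores
#'
#' Summarizes per-cell scores per cluster by the median, with a 95 percent
#' percentile-bootstrap confidence interval of the median. Excluded cells
#' never enter the summary; a cluster whose cells are all excluded is
#' reported with `NA` summaries and a warning.
#'
#' @param per_cell data.frame from [score_cells()] (columns `cluster`,
#'   `score`, `excluded`), or a numeric score vector if `cluster_labels` is
#'   given.
#' @param cluster_labels optional labels when `per_cell` is a bare vector.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `cluster`, `n_cells_used`, `n_excluded`,
#'   `median_score`, `ci_low`, `ci_high`, one row per cluster in sorted
#'   cluster order.
#' @export
summarize_clusters <- function(per_cell, cluster_labels = NULL, n_boot = 1000,
                               seed = 1, conf = 0.95) {
  if (is.numeric(per_cell) && !is.data.frame(per_cell)) {
    stopifnot(!is.null(cluster_labels))
    per_cell <- data.frame(cluster = cluster_labels, score = per_cell,
                           excluded = is.na(per_cell))
  }
  stopifnot(is.data.frame(per_cell),
            all(c("cluster", "score", "excluded") %in% names(per_cell)))
  if (!nrow(per_cell)) stopf("empty per-cell input")
  n_boot <- assert_count(n_boot, "n_boot", min = 1L)
  alpha <- (1 - conf) / 2

  clusters <- sort(unique(per_cell$cluster))
  with_seed(seed, {
    rows <- lapply(clusters, function(cl) {
      sc <- per_cell$score[per_cell$cluster == cl & !per_cell$excluded]
      n_exc <- sum(per_cell$cluster == cl & per_cell$excluded)
      if (!length(sc)) {
        warnf("cluster %s: all cells excluded; null summary", format(cl))
        return(data.frame(cluster = cl, n_cells_used = 0L, n_excluded = n_exc,
                          median_score = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_))
      }
      boot <- vapply(seq_len(n_boot), function(i) {
        median(sample(sc, length(sc), replace = TRUE))
      }, numeric(1))
      ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
      data.frame(cluster = cl, n_cells_used = length(sc), n_excluded = n_exc,
                 median_score = median(sc), ci_low = ci[1], ci_high = ci[2])
    })
  })
  do.call(rbind, rows)
}

#' Rank clusters by median engagement score
#'
#' Orders clusters by decreasing median score; ties are broken by ascending
#' cluster label (and noted via message). Clusters with `NA` medians sort
#' last.
#'
#' @param per_cluster data.frame from [summarize_clusters()].
#' @return the `cluster` values in rank order (highest median first).
#' @export
rank_clusters <- function(per_cluster) {
  stopifnot(is.data.frame(per_cluster),
            all(c("cluster", "median_score") %in% names(per_cluster)))
  if (!nrow(per_cluster)) stopf("empty cluster summary")
  med <- per_cluster$median_score
  if (anyDuplicated(med[!is.na(med)])) {
    message("rank_clusters: tied medians broken by ascending cluster label")
  }
  ord <- order(-ifelse(is.na(med), -Inf, med), per_cluster$cluster)
  per_cluster$cluster[ord]
}
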