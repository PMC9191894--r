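# Proximal polyA-site usage (PPAU) and delta-PPAU classification.
#
# PPAU is the percentage of a gene's 3'UTR signal attributed to the most
# proximal polyA site; delta-PPAU = median PPAU(KO) - median PPAU(WT) over
# replicates. delta > 20 marks 3'UTR shortening, delta < -20 lengthening
# (strict inequalities; +/-20 exactly is "unchanged").

APA_CLASSES <- c("shortened", "lengthened", "unchanged", "undetermined")

#' Validate a 3'UTR isoform abundance table
#'
#' @param x data.frame with columns `gene_id`, `condition` (`"WT"`/`"KO"`),
#'   `replicate_id`, `isoform_id`, `is_proximal` (logical; exactly one
#'   isoform per gene/condition/replicate), `abundance` (nonnegative,
#'   TPM-like units).
#' @return the validated data.frame (class `apa_table`).
#' @export
apa_table <- function(x) {
  need <- c("gene_id", "condition", "replicate_id", "isoform_id",
            "is_proximal", "abundance")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("APA table lacks columns: %s",
                          paste(miss, collapse = ", "))
  x <- as.data.frame(x)
  x$is_proximal <- as.logical(x$is_proximal)
  if (!all(x$condition %in% c("WT", "KO"))) {
    stopf("condition must be 'WT' or 'KO'")
  }
  if (any(!is.finite(x$abundance)) || any(x$abundance < 0)) {
    stopf("abundances must be finite and nonnegative")
  }
  nprox <- aggregate(is_proximal ~ gene_id + condition + replicate_id,
                     data = x, FUN = sum)
  if (any(nprox$is_proximal != 1L)) {
    stopf("every gene x condition x replicate needs exactly one proximal isoform")
  }
  class(x) <- c("apa_table", "data.frame")
  x
}

#' PPAU of one gene in one replicate
#'
#' `PPAU = 100 * proximal abundance / total abundance` over all 3'UTR
#' isoforms of the gene. A replicate with zero total abundance is
#' undetermined (`NA`).
#'
#' @param abundance nonnegative isoform abundances.
#' @param is_proximal logical flags; exactly one must be `TRUE`.
#' @return PPAU percentage in \[0, 100\], or `NA` when total is 0.
#' @examples
#' compute_ppau(c(30, 70), c(TRUE, FALSE))  # 30
#' @export
compute_ppau <- function(abundance, is_proximal) {
  if (length(abundance) != length(is_proximal) || !length(abundance)) {
    stopf("abundance and is_proximal must be nonempty and equal length")
  }
  if (sum(is_proximal) != 1L) {
    stopf("exactly one isoform must be flagged proximal (got %d)",
          sum(is_proximal))
  }
  tot <- sum(abundance)
  if (tot == 0) return(NA_real_)
  100 * abundance[is_proximal] / tot
}

#' delta-PPAU between conditions
#'
#' Median over replicates per condition, then KO minus WT. Undetermined
#' (`NA`) replicates are dropped with a message; all replicates
#' undetermined in either condition is an error (use [ppau_results()] for
#' the tolerant per-gene pipeline).
#'
#' @param ppau_wt,ppau_ko replicate PPAU values per condition (percent).
#' @return delta-PPAU in percentage points.
#' @examples
#' delta_ppau(c(50, 50, 50), c(80, 75, 85))  # 30
#' @export
delta_ppau <- function(ppau_wt, ppau_ko) {
  n_na <- sum(is.na(ppau_wt)) + sum(is.na(ppau_ko))
  if (n_na > 0) {
    message(sprintf("delta_ppau: dropping %d undetermined replicate(s)", n_na))
  }
  wt <- ppau_wt[!is.na(ppau_wt)]; ko <- ppau_ko[!is.na(ppau_ko)]
  if (!length(wt) || !length(ko)) {
    stopf("all replicates undetermined in one condition")
  }
  median(ko) - median(wt)
}

#' Classify alternative polyadenylation from delta-PPAU
#'
#' `delta > 20` is "shortened" (more proximal usage in KO), `delta < -20`
#' "lengthened"; otherwise "unchanged". Exactly +/-20 is "unchanged"
#' (strict inequalities); non-finite deltas are "undetermined".
#'
#' @param delta delta-PPAU values in percentage points (vectorized).
#' @param threshold classification threshold (default 20).
#' @return character vector of classes.
#' @export
classify_apa <- function(delta, threshold = 20) {
  threshold <- assert_number(threshold, "threshold", min = 0)
  out <- rep("unchanged", length(delta))
  out[!is.finite(delta)] <- "undetermined"
  out[is.finite(delta) & delta > threshold] <- "shortened"
  out[is.finite(delta) & delta < -threshold] <- "lengthened"
  out
}

#' Full PPAU / delta-PPAU analysis of an abundance table
#'
#' Computes per-replicate PPAU for every gene and condition, condition
#' medians, delta-PPAU (KO - WT) and the APA class. Genes with all
#' replicates undetermined in either condition are classed "undetermined".
#'
#' @param x an [apa_table()] (or coercible data.frame).
#' @param threshold classification threshold, see [classify_apa()].
#' @return list with `per_replicate` (gene_id, condition, replicate_id,
#'   ppau) and `per_gene` (gene_id, median_ppau_wt, median_ppau_ko,
#'   delta_ppau, apa_class).
#' @export
ppau_results <- function(x, threshold = 20) {
  x <- apa_table(x)
  key <- interaction(x$gene_id, x$condition, x$replicate_id, drop = TRUE)
  idx <- split(seq_len(nrow(x)), key)
  per_rep <- do.call(rbind, lapply(idx, function(i) {
    data.frame(gene_id = x$gene_id[i[1]], condition = x$condition[i[1]],
               replicate_id = x$replicate_id[i[1]],
               ppau = compute_ppau(x$abundance[i], x$is_proximal[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_rep) <- NULL
  per_rep <- per_rep[order(per_rep$gene_id, per_rep$condition,
                           per_rep$replicate_id), ]
  genes <- unique(per_rep$gene_id)
  med_or_na <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    wt <- per_rep$ppau[per_rep$gene_id == g & per_rep$condition == "WT"]
    ko <- per_rep$ppau[per_rep$gene_id == g & per_rep$condition == "KO"]
    mwt <- med_or_na(wt); mko <- med_or_na(ko)
    data.frame(gene_id = g, median_ppau_wt = mwt, median_ppau_ko = mko,
               delta_ppau = mko - mwt, stringsAsFactors = FALSE)
  }))
  per_gene$apa_class <- classify_apa(per_gene$delta_ppau, threshold)
  rownames(per_gene) <- NULL
  list(per_replicate = per_rep, per_gene = per_gene)
}
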