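# Stranded gene models in 0-based half-open coordinates, with derived
# 5'UTR / CDS / intron / 3'UTR segments. refGene/BED12-style: one row per
# gene with exon blocks and a thick (CDS) region.

FEATURE_LEVELS <- c("3UTR", "5UTR", "CDS", "proximal_intron",
                    "distal_intron", "other")

#' Stranded gene models
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tx_start`, `tx_end`, `cds_start`, `cds_end`
#'   (0-based half-open; `cds_start == cds_end` marks a noncoding gene) and
#'   list-columns (or comma-separated strings) `exon_starts` (absolute) and
#'   `exon_sizes`.
#' @param one_based set `TRUE` if the supplied coordinates are 1-based
#'   closed (converted on input; all internal arithmetic is 0-based
#'   half-open).
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, one_based = FALSE) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end", "cds_start",
            "cds_end", "exon_starts", "exon_sizes")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("gene table lacks columns: %s",
                          paste(miss, collapse = ", "))
  genes <- as.data.frame(genes)
  parse_ints <- function(col) {
    if (is.list(col)) lapply(col, as.numeric)
    else lapply(strsplit(as.character(col), ","), as.numeric)
  }
  genes$exon_starts <- parse_ints(genes$exon_starts)
  genes$exon_sizes <- parse_ints(genes$exon_sizes)
  if (isTRUE(one_based)) {
    genes$tx_start <- genes$tx_start - 1L
    genes$cds_start <- genes$cds_start - 1L
    genes$exon_starts <- lapply(genes$exon_starts, function(s) s - 1)
  }
  if (anyDuplicated(genes$gene_id)) stopf("duplicate gene_id")
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  for (i in seq_len(nrow(genes))) {
    st <- genes$exon_starts[[i]]; sz <- genes$exon_sizes[[i]]
    if (length(st) != length(sz) || !length(st)) stopf("bad exon blocks")
    if (is.unsorted(st, strictly = TRUE)) stopf("exon starts must be sorted")
    if (any(st + sz > c(st[-1], genes$tx_end[i]) + 1e-9)) {
      stopf("exon blocks overlap or exceed tx bounds (gene %s)",
            genes$gene_id[i])
    }
    if (st[1] < genes$tx_start[i]) stopf("exon before tx_start")
    with_cds <- genes$cds_start[i] < genes$cds_end[i]
    if (with_cds && (genes$cds_start[i] < genes$tx_start[i] ||
                     genes$cds_end[i] > genes$tx_end[i])) {
      stopf("CDS outside transcript bounds (gene %s)", genes$gene_id[i])
    }
  }
  structure(list(genes = genes), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

# Derived 5'UTR/CDS/intron/3'UTR segments of every gene, 0-based half-open.
# Intronic positions within `proximal_window` nt of an exon boundary are
# "proximal_intron"; exons of noncoding genes are "other".
annotation_segments <- function(annotation, proximal_window = 500) {
  stopifnot(inherits(annotation, "gene_annotation"))
  proximal_window <- assert_number(proximal_window, "proximal_window", min = 0)
  out <- vector("list", nrow(annotation$genes))
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    st <- g$exon_starts[[1]]; sz <- g$exon_sizes[[1]]
    ex_s <- st; ex_e <- st + sz
    segs <- list()
    add <- function(s, e, cat) {
      if (e > s) segs[[length(segs) + 1L]] <<- c(s, e, cat)
    }
    coding <- g$cds_start < g$cds_end
    for (j in seq_along(ex_s)) {
      if (!coding) { add(ex_s[j], ex_e[j], "other"); next }
      # exonic pieces left of CDS, inside CDS, right of CDS
      left_cat <- if (g$strand == "+") "5UTR" else "3UTR"
      right_cat <- if (g$strand == "+") "3UTR" else "5UTR"
      add(ex_s[j], min(ex_e[j], g$cds_start), left_cat)
      add(max(ex_s[j], g$cds_start), min(ex_e[j], g$cds_end), "CDS")
      add(max(ex_s[j], g$cds_end), ex_e[j], right_cat)
    }
    if (length(ex_s) > 1L) {
      for (j in seq_len(length(ex_s) - 1L)) {
        is_ <- ex_e[j]; ie <- ex_s[j + 1L]
        w <- proximal_window
        if (ie - is_ <= 2 * w) {
          add(is_, ie, "proximal_intron")
        } else {
          add(is_, is_ + w, "proximal_intron")
          add(is_ + w, ie - w, "distal_intron")
          add(ie - w, ie, "proximal_intron")
        }
      }
    }
    m <- do.call(rbind, segs)
    out[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                           strand = g$strand,
                           start = as.numeric(m[, 1]),
                           end = as.numeric(m[, 2]),
                           category = m[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write / read gene models as BED12
#'
#' Standard BED12 encoding: `thickStart`/`thickEnd` carry the CDS,
#' `blockStarts` are exon starts relative to `chromStart`. Round trip is the
#' identity on the annotation's fields.
#'
#' @param annotation a [gene_annotation()].
#' @param path BED12 file path.
#' @return `path` (write) or a [gene_annotation()] (read).
#' @export
write_bed12 <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$tx_start + 1L, g$tx_end),
                               strand = g$strand)
  names(gr) <- g$gene_id
  # noncoding genes: rtracklayer encodes a zero-width thick as start==end
  thick_start <- ifelse(g$cds_start < g$cds_end, g$cds_start + 1L,
                        g$tx_start + 1L)
  thick_end <- ifelse(g$cds_start < g$cds_end, g$cds_end, g$tx_start)
  S4Vectors::mcols(gr)$thick <- IRanges::IRanges(thick_start, thick_end)
  blocks <- IRanges::IRangesList(lapply(seq_len(nrow(g)), function(i) {
    rel <- g$exon_starts[[i]] - g$tx_start[i]
    IRanges::IRanges(rel + 1L, width = g$exon_sizes[[i]])
  }))
  S4Vectors::mcols(gr)$blocks <- blocks
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mc <- S4Vectors::mcols(gr)
  tx_start <- GenomicRanges::start(gr) - 1L
  tx_end <- GenomicRanges::end(gr)
  if (!is.null(mc$thick)) {
    cds_start <- IRanges::start(mc$thick) - 1L
    cds_end <- IRanges::end(mc$thick)
    zero <- cds_end <= cds_start
    cds_start[zero] <- tx_start[zero]
    cds_end[zero] <- tx_start[zero]
  } else {
    cds_start <- tx_start; cds_end <- tx_end
  }
  if (!is.null(mc$blocks)) {
    exon_starts <- lapply(seq_along(gr), function(i) {
      tx_start[i] + IRanges::start(mc$blocks[[i]]) - 1L
    })
    exon_sizes <- lapply(seq_along(gr), function(i) {
      IRanges::width(mc$blocks[[i]])
    })
  } else {
    exon_starts <- as.list(tx_start)
    exon_sizes <- as.list(tx_end - tx_start)
  }
  gene_annotation(data.frame(
    gene_id = mc$name %||% names(gr) %||% paste0("gene", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end,
    exon_starts = I(exon_starts), exon_sizes = I(exon_sizes),
    stringsAsFactors = FALSE))
}

#' Read / write simple BED6 interval tables
#'
#' Minimal interval exchange (0-based half-open), used for splicing-cluster
#' intervals and peak positions.
#'
#' @param path BED file path.
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (read), or `path` (write).
#' @export
read_bed6 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  if (is.null(df$name)) df$name <- paste0("iv", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "*"
  df
}

#' @rdname read_bed6
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name %||% paste0("iv", seq_len(nrow(df))),
                    score = df$score %||% 0, strand = df$strand %||% "*")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
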