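#' Paired spliced/unspliced single-cell count matrices
#'
#' Container for velocyto-style gene-by-cell spliced and unspliced count
#' matrices with per-cell cluster labels, the input to engagement scoring.
#' Matrices must share dimensions and orderings; gene identifiers must be
#' unique.
#'
#' @param spliced,unspliced gene x cell matrices of nonnegative integer
#'   counts (base matrices or `Matrix` sparse matrices).
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of cell identifiers (columns).
#' @param cluster_labels per-cell cluster labels (coerced to integer).
#' @return An object of class `cell_counts`: a list with elements `spliced`,
#'   `unspliced` (dgCMatrix), `gene_ids`, `cell_ids`, `cluster_labels`.
#' @examples
#' s <- matrix(rpois(12, 5), 3, 4)
#' u <- matrix(rpois(12, 1), 3, 4)
#' cc <- cell_counts(s, u, paste0("g", 1:3), paste0("c", 1:4), c(0, 0, 1, 1))
#' @export
cell_counts <- function(spliced, unspliced, gene_ids, cell_ids,
                        cluster_labels) {
  spliced <- methods::as(methods::as(Matrix::Matrix(spliced, sparse = TRUE),
                                     "CsparseMatrix"), "dMatrix")
  unspliced <- methods::as(methods::as(Matrix::Matrix(unspliced, sparse = TRUE),
                                       "CsparseMatrix"), "dMatrix")
  if (!identical(dim(spliced), dim(unspliced))) {
    stopf("spliced and unspliced matrices must share dimensions")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stopf("duplicate gene_ids are not allowed")
  if (length(gene_ids) != nrow(spliced)) stopf("gene_ids length != nrow")
  if (length(cell_ids) != ncol(spliced)) stopf("cell_ids length != ncol")
  if (length(cluster_labels) != ncol(spliced)) {
    stopf("cluster_labels length must equal the number of cells")
  }
  for (m in list(spliced, unspliced)) {
    x <- m@x
    if (length(x) && (any(x < 0) || any(x != round(x)))) {
      stopf("counts must be nonnegative integers")
    }
  }
  rownames(spliced) <- rownames(unspliced) <- gene_ids
  colnames(spliced) <- colnames(unspliced) <- cell_ids
  structure(list(spliced = spliced, unspliced = unspliced,
                 gene_ids = gene_ids, cell_ids = cell_ids,
                 cluster_labels = as.integer(cluster_labels)),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d genes x %d cells, %d clusters\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cluster_labels))))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$spliced)

#' Write cell counts as Matrix Market files with TSV sidecars
#'
#' Writes `spliced.mtx`, `unspliced.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `clusters.tsv` into `dir`, the exchange format consumed by
#' [read_cell_counts()] and by the command-line interface.
#'
#' @param x a [cell_counts()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cell_counts <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$spliced, file.path(dir, "spliced.mtx"))
  Matrix::writeMM(x$unspliced, file.path(dir, "unspliced.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  write_tsv(data.frame(cell_id = x$cell_ids, cluster = x$cluster_labels),
            file.path(dir, "clusters.tsv"))
  invisible(dir)
}

#' Read cell counts written by [write_cell_counts()]
#'
#' @param dir directory containing `spliced.mtx`, `unspliced.mtx`,
#'   `genes.tsv`, `barcodes.tsv`, `clusters.tsv`.
#' @return a [cell_counts()] object.
#' @export
read_cell_counts <- function(dir) {
  spliced <- Matrix::readMM(file.path(dir, "spliced.mtx"))
  unspliced <- Matrix::readMM(file.path(dir, "unspliced.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  cl <- read_tsv(file.path(dir, "clusters.tsv"))
  if (!identical(as.character(cl$cell_id), cells)) {
    stopf("clusters.tsv cell order does not match barcodes.tsv")
  }
  cell_counts(spliced, unspliced, genes, cells, cl$cluster)
}

#' eCLIP-derived target set of an RBP
#'
#' A target set names the RBP gene (whose expression forms the score
#' denominator) and the genes whose pre-mRNAs it binds (score numerator).
#' The RBP's own gene is never a member of its target set.
#'
#' @param rbp_gene_id single gene identifier of the RBP.
#' @param target_gene_ids character vector of target gene identifiers.
#' @param provenance free-text origin, e.g. "eCLIP significant peaks".
#' @return An object of class `target_set`.
#' @export
target_set <- function(rbp_gene_id, target_gene_ids, provenance = "") {
  rbp_gene_id <- as.character(rbp_gene_id)
  stopifnot(length(rbp_gene_id) == 1L)
  target_gene_ids <- unique(as.character(target_gene_ids))
  if (!length(target_gene_ids)) stopf("target set must be nonempty")
  if (rbp_gene_id %in% target_gene_ids) {
    stopf("rbp_gene_id '%s' may not appear among its own targets", rbp_gene_id)
  }
  structure(list(rbp_gene_id = rbp_gene_id,
                 target_gene_ids = target_gene_ids,
                 provenance = as.character(provenance)),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set: RBP %s, %d targets (%s)\n", x$rbp_gene_id,
              length(x$target_gene_ids), x$provenance))
  invisible(x)
}

#' Write / read a target set as two-column TSV
#'
#' The file holds one target per row under a `target_gene_id` column, with
#' the RBP gene and provenance recorded in a comment header.
#'
#' @param x a [target_set()].
#' @param path file path.
#' @return `path` (write) or a [target_set()] (read).
#' @export
write_target_set <- function(x, path) {
  stopifnot(inherits(x, "target_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rbp_gene_id=%s provenance=%s", x$rbp_gene_id,
                     x$provenance), con)
  utils::write.table(data.frame(target_gene_id = x$target_gene_ids), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_set
#' @export
read_target_set <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# rbp_gene_id=", first)) {
    stopf("target set file lacks '# rbp_gene_id=...' header: %s", path)
  }
  rbp <- sub("^# rbp_gene_id=(\\S+).*$", "\\1", first)
  prov <- if (grepl("provenance=", first)) {
    sub("^.*provenance=", "", first)
  } else ""
  df <- read_tsv(path)
  target_set(rbp, df$target_gene_id, prov)
}
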