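# End-to-end orchestration over plain-text artifacts. One global seed is
# fanned out deterministically to per-stage streams so partial re-runs stay
# reproducible; identical config + seed gives bit-identical outputs.

#' Pipeline run configuration
#'
#' Collects all stage parameters. Unknown keys are rejected so config files
#' cannot silently misspell an option. Serializes losslessly to JSON.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "eclip_filter", "score", "annotate", "reldist", "apa")`
#'   (dependency order is enforced internally).
#' @param seed global integer seed, fanned out per stage.
#' @param outdir output directory.
#' @param alpha eCLIP family-wise significance threshold.
#' @param n_boot bootstrap resamples for cluster summaries.
#' @param n_bins metagene percentile bins.
#' @param tolerance splice-boundary matching tolerance (nt).
#' @param proximal_window proximal-intron distance (nt).
#' @param total per-cell total mode, see [score_cells()].
#' @param pseudocount RBP-count pseudocount, see [score_cells()].
#' @param apa_threshold delta-PPAU classification threshold.
#' @param sim_cells,sim_eclip,sim_apa named lists of overrides for
#'   [sim_cells_config()], [sim_eclip_config()], [sim_apa_config()]
#'   (their `seed` fields are derived from the global seed).
#' @param log_level one of "quiet", "info".
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "eclip_filter", "score",
                                  "annotate", "reldist", "apa"),
                       seed = 1, outdir = "rbpengage_run", alpha = 1e-8,
                       n_boot = 1000, n_bins = 100, tolerance = 0,
                       proximal_window = 500,
                       total = "spliced+unspliced", pseudocount = 0,
                       apa_threshold = 20, sim_cells = list(),
                       sim_eclip = list(), sim_apa = list(),
                       log_level = "info") {
  all_stages <- c("simulate", "eclip_filter", "score", "annotate",
                  "reldist", "apa")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- list(stages = all_stages[all_stages %in% stages],
              seed = assert_count(seed, "seed"), outdir = outdir,
              alpha = assert_number(alpha, "alpha", min = 0, max = 1),
              n_boot = assert_count(n_boot, "n_boot", min = 1L),
              n_bins = assert_count(n_bins, "n_bins", min = 1L),
              tolerance = assert_number(tolerance, "tolerance", min = 0),
              proximal_window = assert_number(proximal_window,
                                              "proximal_window", min = 0),
              total = resolve_totals_mode(total),
              pseudocount = assert_number(pseudocount, "pseudocount",
                                          min = 0),
              apa_threshold = assert_number(apa_threshold, "apa_threshold",
                                            min = 0),
              sim_cells = sim_cells, sim_eclip = sim_eclip,
              sim_apa = sim_apa,
              log_level = match.arg(log_level, c("quiet", "info")))
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' Unknown keys in the file are rejected.
#'
#' @param path JSON file path.
#' @param config a [run_config()].
#' @return a [run_config()] (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stopf("unknown config key(s): %s",
                         paste(bad, collapse = ", "))
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipe_log <- function(cfg, fmt, ...) {
  if (cfg$log_level != "quiet") {
    message(sprintf(paste0("[rbp-engage] ", fmt), ...))
  }
}

require_artifact <- function(path, stage, producer) {
  if (!file.exists(path)) {
    stopf("stage '%s' needs missing artifact '%s' (produced by stage '%s')",
          stage, path, producer)
  }
  path
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order: `simulate` writes all
#' synthetic inputs; `eclip_filter` applies the enrichment/significance rule
#' and derives the target set; `score` renames the simulated cell-count
#' target genes to the eCLIP-derived target identifiers and computes
#' per-cell and per-cluster engagement scores plus the cluster ranking;
#' `annotate` writes the peak feature distribution and metagene profile;
#' `reldist` computes the relative-distance histogram of significant peaks
#' against the planted sites; `apa` runs the PPAU analysis. A manifest with
#' parameters, seed, package version and md5 checksums of every output is
#' written last.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  stages <- config$stages

  if ("simulate" %in% stages) {
    pipe_log(config, "simulate: cells, eclip, apa (seed %d)", config$seed)
    sc <- do.call(sim_cells_config,
                  c(config$sim_cells,
                    list(seed = derive_seed(config$seed, "cells"))))
    sim_c <- simulate_cell_counts(sc)
    write_cell_counts(sim_c$counts, out("cells"))
    write_sim_truth(sim_c$truth, out("cells_truth.json"))

    se <- do.call(sim_eclip_config,
                  c(config$sim_eclip,
                    list(seed = derive_seed(config$seed, "eclip"))))
    sim_e <- simulate_eclip(se)
    write_bed12(sim_e$annotation, out("eclip_genes.bed"))
    write_peak_set(sim_e$peaks, out("eclip_peaks"))
    write_tsv(sim_e$truth, out("eclip_truth.tsv"))

    sa <- do.call(sim_apa_config,
                  c(config$sim_apa,
                    list(seed = derive_seed(config$seed, "apa"))))
    sim_a <- simulate_apa(sa)
    write_tsv(as.data.frame(sim_a$table), out("apa_abundances.tsv"))
    write_tsv(sim_a$truth, out("apa_truth.tsv"))
  }

  if ("eclip_filter" %in% stages) {
    require_artifact(out("eclip_peaks_counts.tsv"), "eclip_filter",
                     "simulate")
    peaks <- read_peak_set(out("eclip_peaks"))
    ann <- read_bed12(require_artifact(out("eclip_genes.bed"),
                                       "eclip_filter", "simulate"))
    peaks <- call_significant(peaks, alpha = config$alpha)
    pipe_log(config, "eclip_filter: %d / %d peaks significant at alpha=%g",
             sum(peaks$peaks$significant), nrow(peaks$peaks), config$alpha)
    write_peak_set(peaks, out("eclip_peaks_annotated"))
    ts <- derive_target_set(peaks, ann, rbp_gene_id = "Rbp1")
    write_target_set(ts, out("targets.tsv"))
  }

  if ("score" %in% stages) {
    require_artifact(out("targets.tsv"), "score", "eclip_filter")
    require_artifact(file.path(out("cells"), "spliced.mtx"), "score",
                     "simulate")
    ts <- read_target_set(out("targets.tsv"))
    counts <- read_cell_counts(out("cells"))
    truth <- read_sim_truth(out("cells_truth.json"))
    # identify the simulated target rows with the eCLIP-derived target
    # genes so the derived set drives the scoring
    n_map <- min(length(truth$target_gene_ids), length(ts$target_gene_ids))
    ids <- counts$gene_ids
    ids[match(truth$target_gene_ids[seq_len(n_map)], ids)] <-
      ts$target_gene_ids[seq_len(n_map)]
    counts <- cell_counts(counts$spliced, counts$unspliced, ids,
                          counts$cell_ids, counts$cluster_labels)
    use <- target_set(ts$rbp_gene_id, ts$target_gene_ids[seq_len(n_map)],
                      ts$provenance)
    per_cell <- score_cells(counts, use, total = config$total,
                            pseudocount = config$pseudocount, quiet = TRUE)
    per_cluster <- summarize_clusters(per_cell, n_boot = config$n_boot,
                                      seed = derive_seed(config$seed,
                                                         "boot"))
    ranking <- rank_clusters(per_cluster)
    pipe_log(config, "score: top cluster %s (planted k* = %s)",
             format(ranking[1]), format(truth$target_peak_cluster))
    hdr <- provenance_comment(list(total = config$total,
                                   n_boot = config$n_boot,
                                   seed = config$seed))
    write_tsv(per_cell, out("scores_per_cell.tsv"), hdr)
    write_tsv(per_cluster, out("scores_per_cluster.tsv"), hdr)
    write_tsv(data.frame(rank = seq_along(ranking), cluster = ranking),
              out("cluster_ranking.tsv"), hdr)
  }

  if ("annotate" %in% stages) {
    ann <- read_bed12(require_artifact(out("eclip_genes.bed"), "annotate",
                                       "simulate"))
    pk_prefix <- if (file.exists(out("eclip_peaks_annotated_counts.tsv"))) {
      out("eclip_peaks_annotated")
    } else {
      require_artifact(out("eclip_peaks_counts.tsv"), "annotate", "simulate")
      out("eclip_peaks")
    }
    peaks <- read_peak_set(pk_prefix)
    p <- peaks$peaks
    if ("significant" %in% names(p)) p <- p[p$significant, , drop = FALSE]
    if (!nrow(p)) stopf("annotate: no (significant) peaks to annotate")
    fd <- feature_distribution(p, ann, config$proximal_window)
    prof <- metagene_profile(p, ann, config$n_bins)
    hdr <- provenance_comment(list(proximal_window = config$proximal_window,
                                   n_bins = config$n_bins))
    write_tsv(fd, out("feature_distribution.tsv"), hdr)
    write_tsv(data.frame(bin = seq_along(prof) - 1L, fraction = prof),
              out("metagene_profile.tsv"), hdr)
  }

  if ("reldist" %in% stages) {
    require_artifact(out("eclip_truth.tsv"), "reldist", "simulate")
    pk_prefix <- if (file.exists(out("eclip_peaks_annotated_counts.tsv"))) {
      out("eclip_peaks_annotated")
    } else out("eclip_peaks")
    peaks <- read_peak_set(pk_prefix)
    p <- peaks$peaks
    if ("significant" %in% names(p)) p <- p[p$significant, , drop = FALSE]
    truth <- read_tsv(out("eclip_truth.tsv"))
    ref <- peaks$peaks[peaks$peaks$peak_id %in% truth$peak_id, ]
    if (nrow(p) && nrow(ref) >= 2L) {
      rd <- relative_distance(p, ref)
      write_tsv(rd$histogram, out("reldist_histogram.tsv"),
                provenance_comment(list(n = length(rd$d),
                                        skipped = rd$n_skipped)))
    } else {
      pipe_log(config, "reldist: skipped (needs peaks and >= 2 references)")
    }
  }

  if ("apa" %in% stages) {
    require_artifact(out("apa_abundances.tsv"), "apa", "simulate")
    tab <- read_tsv(out("apa_abundances.tsv"))
    res <- ppau_results(tab, threshold = config$apa_threshold)
    hdr <- provenance_comment(list(threshold = config$apa_threshold))
    write_tsv(res$per_replicate, out("ppau_per_replicate.tsv"), hdr)
    write_tsv(res$per_gene, out("ppau_per_gene.tsv"), hdr)
  }

  files <- setdiff(list.files(config$outdir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package = "rbpengage",
    version = as.character(utils::packageVersion("rbpengage")),
    seed = config$seed,
    stages = stages,
    parameters = unclass(config)[setdiff(names(config),
                                         c("stages", "seed", "outdir"))],
    files = as.list(setNames(
      unname(tools::md5sum(file.path(config$outdir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
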