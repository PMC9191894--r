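# Synthetic spliced/unspliced single-cell counts with planted ground truth.
#
# Stated world: K discrete clusters ordered along a pseudo-differentiation
# axis; counts are negative binomial around cluster-specific means, scaled
# by a per-cell log-normal library factor shared between the spliced and
# unspliced matrix of a cell (so that the score's per-cell normalization
# has a confounder to remove). Spliced and unspliced counts are drawn
# independently per gene/cell. The library factor has mean 1
# (meanlog = -sigma^2/2).

#' Configuration for the single-cell count simulator
#'
#' Defaults emulate a small myogenic-differentiation-like experiment:
#' 7 subclusters of 100 cells, one RBP gene expressed throughout (flat
#' profile, mean 10 spliced counts), 20 target genes whose unspliced
#' (pre-mRNA) abundance peaks 5-fold over background at cluster 5, and a
#' negative binomial with size 2 plus 0.3 log-normal library spread, all
#' typical of UMI-level single-cell data.
#'
#' @param n_clusters number of clusters K (>= 2), ordered along the axis.
#' @param cells_per_cluster cells simulated per cluster.
#' @param n_genes total genes (>= n_targets + 1; gene 1 is the RBP).
#' @param rbp_profile per-cluster mean spliced counts of the RBP (length K).
#' @param target_peak_cluster 0-based cluster index k* where target
#'   pre-mRNA abundance peaks.
#' @param n_targets number of target genes.
#' @param target_unspliced_profile per-cluster mean unspliced counts of
#'   target genes (length K, maximum at k*); default: `background_mean`
#'   everywhere and `5 * background_mean` at k*.
#' @param background_mean mean spliced counts of non-RBP genes.
#' @param background_unspliced_mean mean unspliced counts of non-target
#'   genes; default `0.25 * background_mean` (a typical unspliced fraction).
#' @param nb_dispersion negative-binomial size parameter (> 0); `Inf` gives
#'   Poisson counts.
#' @param libsize_sigma sdlog of the per-cell library factor (>= 0).
#' @param seed integer RNG seed.
#' @return object of class `sim_cells_config`.
#' @export
sim_cells_config <- function(n_clusters = 7, cells_per_cluster = 100,
                             n_genes = 200, rbp_profile = NULL,
                             target_peak_cluster = 5, n_targets = 20,
                             target_unspliced_profile = NULL,
                             background_mean = 2,
                             background_unspliced_mean = NULL,
                             nb_dispersion = 2, libsize_sigma = 0.3,
                             seed = 1) {
  K <- assert_count(n_clusters, "n_clusters", min = 2L)
  cfg <- list(
    n_clusters = K,
    cells_per_cluster = assert_count(cells_per_cluster, "cells_per_cluster",
                                     min = 1L),
    n_genes = assert_count(n_genes, "n_genes", min = 2L),
    rbp_profile = if (is.null(rbp_profile)) rep(10, K) else as.numeric(rbp_profile),
    target_peak_cluster = assert_count(target_peak_cluster,
                                       "target_peak_cluster"),
    n_targets = assert_count(n_targets, "n_targets", min = 1L),
    background_mean = assert_number(background_mean, "background_mean",
                                    min = 0),
    nb_dispersion = if (identical(nb_dispersion, Inf)) Inf else
      assert_number(nb_dispersion, "nb_dispersion", min = 0,
                    strict_min = TRUE),
    libsize_sigma = assert_number(libsize_sigma, "libsize_sigma", min = 0),
    seed = assert_count(seed, "seed"))
  if (cfg$target_peak_cluster >= K) {
    stopf("target_peak_cluster must be in [0, %d]", K - 1L)
  }
  cfg$background_unspliced_mean <- if (is.null(background_unspliced_mean)) {
    0.25 * cfg$background_mean
  } else assert_number(background_unspliced_mean, "background_unspliced_mean",
                       min = 0)
  cfg$target_unspliced_profile <- if (is.null(target_unspliced_profile)) {
    p <- rep(cfg$background_mean, K)
    p[cfg$target_peak_cluster + 1L] <- 5 * max(cfg$background_mean, 0.2)
    p
  } else as.numeric(target_unspliced_profile)
  if (length(cfg$rbp_profile) != K || length(cfg$target_unspliced_profile) != K) {
    stopf("profiles must have length n_clusters = %d", K)
  }
  if (any(!is.finite(cfg$rbp_profile)) || any(cfg$rbp_profile < 0) ||
      any(!is.finite(cfg$target_unspliced_profile)) ||
      any(cfg$target_unspliced_profile < 0)) {
    stopf("profile means must be finite and nonnegative")
  }
  if (cfg$n_genes < cfg$n_targets + 1L) {
    stopf("n_genes must exceed n_targets (RBP gene needs a row)")
  }
  structure(cfg, class = "sim_cells_config")
}

rcounts <- function(n, mu, size) {
  if (identical(size, Inf)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Simulate spliced/unspliced cell counts with planted truth
#'
#' Gene 1 (`"Rbp1"`) is the RBP: its spliced counts follow `rbp_profile`.
#' Genes 2..(n_targets+1) (`"Tgt..."`) are targets: their unspliced counts
#' follow `target_unspliced_profile`, peaking at cluster k*. All other
#' means are background. Each cell draws a log-normal library factor
#' (mean 1) multiplying every one of its means in both matrices.
#'
#' @param config a [sim_cells_config()].
#' @return list with `counts` (a [cell_counts()]) and `truth` (class
#'   `sim_truth`: `rbp_gene_id`, `target_gene_ids`, `target_peak_cluster`,
#'   `expected_cluster_scores` -- the plug-in score
#'   `n_targets * target_profile[k] / rbp_profile[k]` per cluster).
#' @examples
#' sim <- simulate_cell_counts(sim_cells_config(n_clusters = 3,
#'   cells_per_cluster = 10, n_genes = 30, n_targets = 5,
#'   target_peak_cluster = 1, seed = 42))
#' dim(sim$counts)
#' @export
simulate_cell_counts <- function(config) {
  stopifnot(inherits(config, "sim_cells_config"))
  K <- config$n_clusters
  n_cells <- K * config$cells_per_cluster
  n_genes <- config$n_genes
  clusters <- rep(seq_len(K) - 1L, each = config$cells_per_cluster)

  gene_ids <- c("Rbp1",
                sprintf("Tgt%03d", seq_len(config$n_targets)),
                sprintf("Bg%03d", seq_len(n_genes - config$n_targets - 1L)))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  is_target <- seq_len(n_genes) %in% (1L + seq_len(config$n_targets))

  # cluster-specific mean matrices (gene x cell), before library factors
  mu_s <- matrix(config$background_mean, n_genes, n_cells)
  mu_u <- matrix(config$background_unspliced_mean, n_genes, n_cells)
  mu_s[1L, ] <- config$rbp_profile[clusters + 1L]
  mu_u[is_target, ] <- rep(config$target_unspliced_profile[clusters + 1L],
                           each = config$n_targets)

  with_seed(config$seed, {
    sigma <- config$libsize_sigma
    libf <- exp(rnorm(n_cells, mean = -sigma^2 / 2, sd = sigma))
    mu_s <- sweep(mu_s, 2L, libf, "*")
    mu_u <- sweep(mu_u, 2L, libf, "*")
    spliced <- matrix(rcounts(length(mu_s), mu_s, config$nb_dispersion),
                      n_genes, n_cells)
    unspliced <- matrix(rcounts(length(mu_u), mu_u, config$nb_dispersion),
                        n_genes, n_cells)
  })

  counts <- cell_counts(spliced, unspliced, gene_ids, cell_ids, clusters)
  expected <- ifelse(config$rbp_profile > 0,
                     config$n_targets * config$target_unspliced_profile /
                       config$rbp_profile, NA_real_)
  truth <- structure(list(rbp_gene_id = "Rbp1",
                          target_gene_ids = gene_ids[is_target],
                          target_peak_cluster = config$target_peak_cluster,
                          expected_cluster_scores = expected),
                     class = "sim_truth")
  list(counts = counts, truth = truth)
}

#' Serialize / deserialize simulation truth as JSON
#'
#' @param truth a `sim_truth` list (from any simulator; any list of atomic
#'   fields round-trips).
#' @param path JSON file path.
#' @return `path` (write) or the truth list (read).
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("rbp_gene_id", "target_gene_ids") %in% names(x))) {
    class(x) <- "sim_truth"
  }
  x
}
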