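# Synthetic alternative-polyadenylation experiment: per-gene proximal and
# distal 3'UTR isoform abundances for WT and KO with replicates, planting a
# PPAU shift in chosen fractions of genes.

#' Configuration for the APA simulator
#'
#' Defaults: 200 genes, three replicates per condition, 15 percent of
#' genes shortened and 15 percent lengthened by a 30-point PPAU shift, with
#' 10 percent multiplicative abundance noise. Baseline WT PPAU is drawn
#' uniformly from `wt_ppau_range`, chosen so the default shift never leaves
#' \[0, 100\] (shifts that would are clipped and logged).
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition (default 3).
#' @param frac_shortened,frac_lengthened planted fractions of genes whose
#'   KO PPAU is shifted by `+ppau_shift` / `-ppau_shift`; must sum to <= 1.
#' @param ppau_shift planted PPAU change in percentage points (>= 0).
#' @param abundance_noise_cv coefficient of variation of the multiplicative
#'   log-normal noise on each isoform abundance (mean-1 noise).
#' @param wt_ppau_range baseline WT PPAU bounds (percent).
#' @param mean_expression log-normal location of per-gene total abundance
#'   (TPM-like; default exp-scale median 50).
#' @param seed integer RNG seed.
#' @return object of class `sim_apa_config`.
#' @export
sim_apa_config <- function(n_genes = 200, n_replicates = 3,
                           frac_shortened = 0.15, frac_lengthened = 0.15,
                           ppau_shift = 30, abundance_noise_cv = 0.1,
                           wt_ppau_range = c(30, 60), mean_expression = 50,
                           seed = 1) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes", min = 1L),
    n_replicates = assert_count(n_replicates, "n_replicates", min = 1L),
    frac_shortened = assert_number(frac_shortened, "frac_shortened",
                                   min = 0, max = 1),
    frac_lengthened = assert_number(frac_lengthened, "frac_lengthened",
                                    min = 0, max = 1),
    ppau_shift = assert_number(ppau_shift, "ppau_shift", min = 0),
    abundance_noise_cv = assert_number(abundance_noise_cv,
                                       "abundance_noise_cv", min = 0),
    wt_ppau_range = as.numeric(wt_ppau_range),
    mean_expression = assert_number(mean_expression, "mean_expression",
                                    min = 0, strict_min = TRUE),
    seed = assert_count(seed, "seed"))
  if (cfg$frac_shortened + cfg$frac_lengthened > 1) {
    stopf("planted fractions must sum to <= 1")
  }
  stopifnot(length(cfg$wt_ppau_range) == 2L,
            cfg$wt_ppau_range[1] <= cfg$wt_ppau_range[2],
            cfg$wt_ppau_range[1] >= 0, cfg$wt_ppau_range[2] <= 100)
  structure(cfg, class = "sim_apa_config")
}

#' Simulate 3'UTR isoform abundances with planted APA classes
#'
#' Every gene has a proximal and a distal 3'UTR isoform. A gene's WT PPAU
#' is uniform in `wt_ppau_range`; "shortened" genes get KO PPAU =
#' WT + shift, "lengthened" genes KO PPAU = WT - shift (clipped to
#' \[0, 100\] with a message if needed), the rest are unshifted. Replicate
#' abundances are `total * fraction` times independent mean-1 log-normal
#' noise with the configured CV per isoform.
#'
#' @param config a [sim_apa_config()].
#' @return list with `table` (an [apa_table()]) and `truth` (data.frame
#'   `gene_id`, `class`, `wt_ppau`, `ko_ppau`).
#' @export
simulate_apa <- function(config) {
  stopifnot(inherits(config, "sim_apa_config"))
  n <- config$n_genes
  n_short <- round(config$frac_shortened * n)
  n_long <- round(config$frac_lengthened * n)
  classes <- rep("unchanged", n)
  if (config$ppau_shift > 0) {   # a zero shift plants nothing
    if (n_short > 0) classes[seq_len(n_short)] <- "shortened"
    if (n_long > 0) classes[n_short + seq_len(n_long)] <- "lengthened"
  }
  gene_ids <- sprintf("ApaGene%04d", seq_len(n))

  with_seed(config$seed, {
    wt_ppau <- runif(n, config$wt_ppau_range[1], config$wt_ppau_range[2])
    ko_ppau <- wt_ppau +
      ifelse(classes == "shortened", config$ppau_shift,
             ifelse(classes == "lengthened", -config$ppau_shift, 0))
    n_clip <- sum(ko_ppau < 0 | ko_ppau > 100)
    if (n_clip > 0) {
      message(sprintf("simulate_apa: clipping planted KO PPAU to [0, 100] for %d gene(s)",
                      n_clip))
      ko_ppau <- pmin(pmax(ko_ppau, 0), 100)
    }
    total <- exp(rnorm(n, mean = log(config$mean_expression), sd = 1))
    cv <- config$abundance_noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    noise <- function(m) {
      if (cv == 0) rep(1, m) else exp(rnorm(m, -sdlog^2 / 2, sdlog))
    }
    rows <- vector("list", 2L * 2L * config$n_replicates)
    r <- 0L
    for (cond in c("WT", "KO")) {
      frac <- (if (cond == "WT") wt_ppau else ko_ppau) / 100
      for (rep_i in seq_len(config$n_replicates)) {
        r <- r + 1L
        rows[[r]] <- data.frame(
          gene_id = rep(gene_ids, 2L),
          condition = cond,
          replicate_id = sprintf("%s_rep%d", cond, rep_i),
          isoform_id = c(paste0(gene_ids, "_P"), paste0(gene_ids, "_D")),
          is_proximal = rep(c(TRUE, FALSE), each = n),
          abundance = c(total * frac * noise(n),
                        total * (1 - frac) * noise(n)),
          stringsAsFactors = FALSE)
      }
    }
  })
  tab <- apa_table(do.call(rbind, rows))
  truth <- data.frame(gene_id = gene_ids, class = classes,
                      wt_ppau = wt_ppau, ko_ppau = ko_ppau,
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}
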