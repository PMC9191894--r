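# rbpengage

**When is an RNA-binding protein actually doing its job?** An RBP can only
regulate a transcript in cells where both the RBP and its target RNA — for
splicing regulators, the nascent *pre-mRNA* — are present. `rbpengage`
implements, for single-cell spliced/unspliced count data along a
differentiation axis (e.g. myogenic subclusters of regenerating skeletal
muscle), the **RBP–target-RNA engagement score**

```
E_c = ( Σ_{g ∈ targets} u_{g,c} / N_c ) / ( r_c / N_c )
```

where `u_{g,c}` is the unspliced count of target gene `g` in cell `c`,
`r_c` the RBP's count and `N_c` the cell's total — i.e. the fraction of
library-normalized nascent target RNA per unit of normalized RBP
expression — summarized per cluster by the median with a 95% bootstrap CI.

Around the score it provides the companion statistics such a study needs:

* **eCLIP peak significance** — fold enrichment of IP over size-matched
  input with a two-sided Fisher exact test, Bonferroni control, and the
  rule *significant ⟺ IP reads > input reads AND corrected p < 1e-8*;
  target-set derivation from significant peaks.
* **Peak annotation** — feature assignment (3'UTR / 5'UTR / CDS /
  proximal intron / distal intron) with maximal-overlap-then-priority
  resolution, genomic distribution summaries, and metagene percentile
  profiles.
* **Colocalization** — the `reldist` relative-distance statistic between
  interval sets (flat with mean 0.25 under independence), and
  splice-event matching across datasets with a Jaccard index.
* **Gene-set overlap** — upper-tail hypergeometric test in log space.
* **APA / ΔPPAU** — proximal polyA-site usage (PPAU), ΔPPAU =
  median KO − median WT over replicates, and the strict ±20 classification
  into shortened / lengthened / unchanged 3'UTRs.
* **Synthetic data with planted truth** for every input family
  (negative-binomial spliced/unspliced matrices, toy gene models with
  Poisson eCLIP counts, 3'UTR isoform tables), so the whole pipeline is
  testable offline.

It is aimed at computational biologists who have upstream outputs in hand
(velocyto-style count matrices with cluster labels, called peaks with
IP/input counts, isoform quantifications) and want the downstream scoring
and statistics reproducible and tested.

## Worked example

Simulate a 7-cluster differentiation axis in which the targets' pre-mRNA
peaks 5-fold at cluster 5 while the RBP is expressed throughout, then ask
where the RBP is engaged:

```r
library(rbpengage)

sim     <- simulate_cell_counts(sim_cells_config(seed = 7))
targets <- target_set(sim$truth$rbp_gene_id, sim$truth$target_gene_ids)

per_cell    <- score_cells(sim$counts, targets)
per_cluster <- summarize_clusters(per_cell, n_boot = 1000, seed = 7)
per_cluster
#>   cluster n_cells_used n_excluded median_score ci_low ci_high
#> 1       0           98          2         4.47   3.55    5.93
#> 2       1           97          3         4.00   3.27    6.00
#> 3       2           99          1         4.80   3.80    6.43
#> 4       3           98          2         4.65   3.85    6.80
#> 5       4           94          6         4.92   3.91    6.38
#> 6       5           98          2        22.17  18.71   29.06
#> 7       6           98          2         3.76   2.94    4.93
rank_clusters(per_cluster)
#> [1] 5 4 2 3 0 1 6
```

Cluster 5 — where the pre-mRNA of the targets was planted — stands out
(median 22.2 vs ~4–5 elsewhere; the ~4.5 baseline is the background ratio
20 targets × 2 unspliced / 10 RBP counts = 4 plus sampling noise), and the
excluded cells are the few in which the RBP was not detected (`r_c = 0`,
score undefined).

The eCLIP side, from planted binding sites to significant peaks, feature
distribution and derived targets:

```r
ec     <- simulate_eclip(sim_eclip_config(seed = 7))
called <- call_significant(ec$peaks, alpha = 1e-8)
called
#> peak_set: 3340 peaks (ip_total=674902, input_total=668053, significant=50)
feature_distribution(called$peaks[called$peaks$significant, ], ec$annotation)
#>          category count fraction
#> 1            3UTR    12     0.24
#> 2            5UTR     0     0.00
#> 3             CDS     5     0.10
#> 4 proximal_intron    33     0.66
#> 5   distal_intron     0     0.00
#> 6           other     0     0.00
derive_target_set(called, ec$annotation, "Myrbp")
```

All 50 planted sites are recovered at α = 1e-8 with no false positives,
and their placement reflects the planted 3'UTR/proximal-intron bias.
And the APA classification:

```r
apa <- simulate_apa(sim_apa_config(seed = 7))
res <- ppau_results(apa$table)
table(res$per_gene$apa_class)
#> lengthened  shortened  unchanged
#>         30         30        140
```

matching the planted 15% + 15% of 200 genes. A full synthetic run of every
stage (simulate → eclip-filter → score → annotate → reldist → apa), with a
checksummed manifest, is one call:

```r
run_pipeline(run_config(seed = 7, outdir = "demo_run"))
```

or from the shell, stage by stage:

```sh
Rscript inst/cli/rbp-engage.R simulate cells --seed 7 --outdir demo
Rscript inst/cli/rbp-engage.R run --seed 7 --outdir demo_full
```

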