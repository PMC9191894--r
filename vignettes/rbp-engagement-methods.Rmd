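---
title: "Methods: RBP engagement scoring and companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RBP engagement scoring and companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpengage)
```

## The problem

An RNA-binding protein (RBP) can only act on a target transcript in cells
where both the RBP and the target RNA are present — and for splicing
regulators, the relevant target species is the nascent, still
intron-containing pre-mRNA. In single-cell RNA-seq, velocyto-style
quantification separates spliced from unspliced (pre-mRNA) reads per gene
per cell, which makes it possible to ask, cluster by cluster along a
differentiation axis, *when* an RBP is plausibly engaged with its targets.
This package implements that engagement score together with the statistics
that surround it in a typical study of RBP timing: eCLIP peak significance
against a size-matched input, peak-to-feature annotation and metagene
profiles, relative-distance colocalization, hypergeometric gene-set
overlap, and 3'UTR alternative-polyadenylation (APA) classification from
proximal polyA-site usage.

## The engagement score

For cell $c$ with total read count $N_c$, RBP count $r_c$, and eCLIP-derived
target set $T$ with unspliced counts $u_{g,c}$:

$$ E_c \;=\; \frac{\sum_{g \in T} u_{g,c} / N_c}{r_c / N_c} $$

Both numerator and denominator are normalized by the same per-cell total,
so algebraically $E_c = \sum_{g} u_{g,c} / r_c$; the implementation keeps
the normalized form (and tests the reduction to $10^{-12}$ relative error)
because $N_c$ is a modelling choice users can see and switch. Per cluster,
the score distribution is summarized by the median with a 95% percentile
bootstrap confidence interval.

Decisions taken where the method description left room:

* **$N_c$** is the column sum of spliced + unspliced counts by default
  ("total" is otherwise unqualified); a `total = "spliced"` switch exists,
  and the score is invariant to the choice because both terms share $N_c$.
* **$r_c$** is the RBP's *spliced* count by default — mature mRNA is the
  proxy for protein availability, not nascent transcription; switchable to
  spliced + unspliced.
* **Cells with $r_c = 0$** have an undefined score and are excluded from
  summaries rather than pseudocounted: a pseudocount would manufacture
  finite scores exactly in the clusters where the RBP is absent, distorting
  low-expression clusters. An optional `pseudocount` (default 0) is
  provided for sensitivity analyses.
* **One score per cell**, summing over targets before the ratio, matching
  a per-cluster score distribution display; `per_target = TRUE` exposes the
  per-target decomposition.
* **Cluster summary**: the methods text we follow contains an internal
  contradiction (scores "summed across all cells ... median of these
  scores"); we take the median across per-cell scores, which is the only
  reading consistent with showing a median ± 95% CI per cluster. The CI is
  a percentile bootstrap of the median (`n_boot = 1000`, seeded) since no
  interval method is stated.
* **Ambiguous-category reads** (the third velocyto matrix) are ignored.

`rank_clusters()` orders clusters by median score, breaking ties by
ascending cluster label (and saying so), giving a deterministic "where is
this RBP most engaged" answer.

## eCLIP peak significance

Candidate peaks carry IP and size-matched input read counts plus
library-level usable-read totals (metadata, never recomputed from the
candidate set). Per peak:

* fold enrichment $FE = (ip/ip_{tot}) / (in/in_{tot})$; zero input with
  nonzero IP is $+\infty$, zero in both libraries is undefined (`NaN`);
* a two-sided Fisher exact p-value on
  $[[ip,\; ip_{tot}-ip], [in,\; in_{tot}-in]]$, computed directly from the
  hypergeometric log-likelihood (the support has at most $ip + in + 1$
  points, so the sum is exact and fast at any library size), with the
  conventional $1{+}10^{-7}$ relative tolerance for likelihood ties;
* Bonferroni correction over the $m$ candidate peaks in the input set;
* significance iff the raw IP count strictly exceeds the input count AND
  the corrected p-value is below $\alpha = 10^{-8}$.

The direction filter uses raw counts, not library fractions, taken
literally from the rule it reproduces; sidedness is not stated in that
rule, so two-sided is the default with `sided = "greater"` available.
Target sets are the unique genes overlapped (same strand, ≥1 nt) by at
least one significant peak, minus the RBP's own gene (an RBP commonly
binds its own transcript; it stays in the peak report, not the target set).

## Annotation statistics

**Feature assignment.** A peak's category is the feature with maximal base
overlap against the strand-matched union of segments per category, ties
broken by priority 3'UTR > 5'UTR > CDS > proximal intron > distal intron.
"Proximal intron" means intronic bases within 500 nt of an exon boundary —
unstated in the source method, standard CLIP convention, configurable.
Exons of noncoding transcripts fall in "other".

**Metagene profile.** Each gene body maps to $[0,1]$ 5'→3' (strand-aware);
interval overlaps are apportioned to `n_bins = 100` percentile bins by
fractional base overlap and the profile is normalized to sum to 1.

**Relative distance.** For each query midpoint between consecutive sorted
reference midpoints $L \le x \le R$: $d = \min(x-L, R-x)/(R-L) \in
[0, 0.5]$, flat with mean 0.25 under independence. Queries outside the
reference span (or on chromosomes with fewer than two references) are
skipped and counted, matching the behavior of the standard `reldist`
command; the histogram uses 0.01-wide bins with $d = 0.5$ in the last bin.

**Event matching** requires chromosome and strand identity and both intron
boundaries within a tolerance (default 0 nt, i.e. identical splice sites);
pairing is greedy by total boundary distance with deterministic row-order
tie-breaks, each event matching at most once; the Jaccard index is
matched / (nA + nB − matched).

**Gene-set overlap** uses the upper-tail hypergeometric
$P(X \ge k)$ via `phyper(..., log.p = TRUE)` so p-values far below double
underflow in the tail sum remain representable on the log scale. The gene
universe is supplied by the caller — published overlap p-values are not
checkable without the underlying lists and universe, which is exactly why
the test suite checks the statistic against enumeration instead.

## PPAU and APA classification

Per gene, condition and replicate, $PPAU = 100 \times$ proximal isoform
abundance / total 3'UTR isoform abundance; the proximal flag is an input
(isoform quantification and polyA-site ordering are upstream).
$\Delta PPAU$ = median KO − median WT over replicates (median of an even
count is the midpoint). Classification is strict: $\Delta > 20$ shortened,
$\Delta < -20$ lengthened, boundary values unchanged. Replicates with zero
total abundance are undetermined and dropped; a gene undetermined in all
replicates of either condition is classed "undetermined" rather than
guessed — the source method does not say how such genes were handled.

## The synthetic world

The simulators *are* the package's test bed; their defaults state a world
once and the tests measure it, never the reverse.

**Cells** (`simulate_cell_counts`): K = 7 discrete clusters (a
myogenic-subcluster-scale axis) × 100 cells; 200 genes of which gene 1 is
the RBP (flat spliced mean 10) and 20 are targets whose unspliced mean is
background (2) in all clusters and 5× background at the peak cluster
k\* = 5 — the 5× contrast is the regime the planted-recovery acceptance
criterion specifies. Counts are negative binomial (size 2, typical UMI
overdispersion; `Inf` recovers Poisson), scaled by a per-cell log-normal
library factor (sdlog 0.3, meanlog −σ²/2 so the factor has mean 1) shared
between both matrices of a cell — the score's normalization must have a
real library-size confounder to remove. Spliced and unspliced counts are
drawn independently per gene/cell (no joint model is stated anywhere; this
is the simplest structure sufficient to test the score). The unspliced
background mean is 0.25 × background — a field the spec's config does not
carry, added because a typical unspliced fraction is ~20–25% of spliced.
What this world does *not* contain: doublets, ambient RNA, a continuous
trajectory, gene–gene correlation; a green planted-recovery test
establishes correct arithmetic and ranking under the stated model, not
robustness to those artifacts.

**eCLIP** (`simulate_eclip`): 30 toy genes (3–8 kb) tiled head-to-tail on
one chromosome, each laid out 5'UTR | 4 CDS exons / 3 introns | 3'UTR with
fractions (0.05, 0.25, 0.55, 0.15); candidate peaks are non-overlapping
50-nt windows (peak calling is out of scope, so a candidate set stands in
for a caller's output). 50 true sites are sampled with placement weights
4:2:1:1:0.5 favoring 3'UTR and proximal intron; IP counts are Poisson at
λ×background (λ = 8, background 20 reads/window) at true sites and
background elsewhere, input is background everywhere. Library totals are
the in-window sums plus 9× the expected in-window background ("candidate
windows hold ~10% of the library") — totals are required metadata for the
Fisher test and the source supplies none for a synthetic world.

**APA** (`simulate_apa`): 200 genes × 2 isoforms × 3 replicates per
condition (three replicates matching the stated design); WT PPAU uniform
in [30, 60] — chosen so the default 30-point planted shift never needs
clipping at the [0, 100] boundary (shifts that would leave the range are
clipped and logged); 15% of genes shortened (+30), 15% lengthened (−30);
per-isoform mean-1 log-normal noise with CV 0.1. A zero `ppau_shift`
plants an all-"unchanged" truth.

## Numerical and testing notes

* Coordinates are 0-based half-open everywhere internally (BED
  convention); `one_based = TRUE` converts on input, and conversion
  round-trips are tested as the identity. GRanges interconversion happens
  only at overlap call sites.
* Fisher p-values: implementation sums `dhyper(log = TRUE)` terms;
  the independent test oracles are (a) full enumeration from
  log-binomial-coefficient arithmetic and (b) `stats::fisher.test`.
  Agreement is required to 1e-12 (enumeration) on tables with margins
  ≤ 200 — sampled, since the full census of such tables is ~2×10⁹.
* Bootstrap CIs use `quantile(type = 7)` on the resampled medians; the
  oracle test replays the identical seeded RNG stream in independently
  written code.
* Determinism: every simulator takes an explicit seed and restores the
  caller's RNG state; the pipeline fans one global seed out to per-stage
  streams by a fixed affine hash (kept below 2³¹), and the end-to-end
  determinism test compares md5 checksums of every output file across
  reruns.
* The `run` pipeline derives its scoring target set from the simulated
  eCLIP experiment (renaming simulated cell-count target genes to the
  derived identifiers) so the stage composition — filter, derive, score,
  rank — is exercised as one chain.

## Known limitations

* Cluster labels, splicing events and isoform quantifications are consumed
  as inputs; there is no clustering, velocity estimation, differential
  splicing or read processing here, by design.
* The engagement score is a ratio of noisy counts: with very low RBP
  expression it is heavy-tailed, and the exclusion rule (not scoring
  $r_c = 0$ cells) means clusters where the RBP is off are summarized from
  the cells where it is not — interpret cluster medians together with
  `n_excluded`.
* The two-sided Fisher + direction filter combination is slightly
  conservative relative to a one-sided test at the same α.
* Feature fractions of real genes vary; the toy gene layout is contiguous
  and regular, adequate for testing assignment logic but not for
  calibrating expected genomic distributions.
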