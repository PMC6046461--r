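---
title: "Methods: contrast-centred rank-based gene-set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-centred rank-based gene-set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastSets)
```

## Scope and study design

`contrastSets` analyses factorial count experiments of the kind used to
study how an aging heart responds to a hypertensive stimulus: a 2×2
design crossing age (young vs aging) with treatment (sham vs DOCA,
a mineralocorticoid-excess model of hypertension), with two
*contrasts* of interest — sham vs DOCA **within** each age stratum.
The package covers the full chain from a gene-level count matrix to
pathway-level conclusions: filtering, normalization, per-contrast
differential expression, signed inverse-p gene ranking, pre-ranked
gene-set enrichment, per-sample rank-sum set scoring (Gsheat),
two-dimensional multi-contrast enrichment, and reconstruction of
factorial ANOVA statistics from published mean ± SEM ± n summaries.

## Differential expression

### Filtering and normalization

Genes averaging fewer than `minMean = 10` counts per sample across all
samples are removed before testing (`filterLowCounts`). The threshold
is the conventional low-count cutoff for bulk RNA-seq of solid tissue;
the operation retains exactly the genes at or above the mean and is
idempotent.

Between-sample scaling uses trimmed-mean-of-M factors (`tmmFactors`):
log2 ratios of library-size-normalized counts against a reference
sample (the one whose upper-quartile abundance is closest to the
average), trimmed 30% on ratio and 5% on abundance each side,
averaged, and rescaled to geometric mean 1. TMM assumes most genes are
not differential; with the strong planted effects the simulator can
produce, factors remain stable because the trim removes the affected
tail.

### The exact test

`nbExactContrast` tests each gene with a two-group exact test for
overdispersed counts. Counts are first scaled to a common effective
library size (the geometric mean of TMM-adjusted library sizes) —
a deliberate, simpler substitute for quantile-to-quantile count
adjustment; its accuracy is supported by the null calibration results
below. Writing $\phi$ for the dispersion, each group sum of $n$
equalized samples is treated as NB with size $n/\phi$, and the p-value
is the conditional probability, given the two-group total $S$, of
splits with probability no larger than the observed one:

$$p = \frac{\sum_{a:\,P(a) \le P(a_\mathrm{obs})} P(a)}{\sum_{a=0}^{S} P(a)},
\qquad P(a) = \mathrm{NB}(a;\, n_A/\phi,\, n_A m)\,
\mathrm{NB}(S-a;\, n_B/\phi,\, n_B m),$$

with $m = S/(n_A+n_B)$. At $\phi = 0$ this reduces to the conditional
binomial $\mathrm{Bin}(S, n_A/(n_A+n_B))$, which the tests verify
exactly. For totals above 20,000 the enumeration is restricted to a
±50-standard-deviation window (plus the observed split), whose
truncation error is far below machine precision.

The common dispersion is a method-of-moments estimate: per gene and
group, $(s^2 - \bar y)/\bar y^2$, pooled by degrees of freedom and
averaged across genes. Negative per-gene values are kept in the
average — truncating at zero would bias the common value upward.
A `shrunk` mode shrinks gene-wise moment estimates toward the common
value with 20 prior degrees of freedom; `common` is the default, and
on 2,000-gene null simulations its raw-p rejection fraction at 0.05 is
0.04–0.05 (the acceptance suite checks the band 0.03–0.07).

Fold changes are log2 ratios of normalized group means with a 0.5
prior count, so zero counts stay finite. FDR is Benjamini–Hochberg
(delegated to `p.adjust`; an independent brute-force step-up oracle in
the tests confirms it).

### Ranking metric

Genes are ordered from most up- to most down-regulated by
$\mathrm{sign}(\log_2 FC)/p$ (`signedInversePRank`). The metric is
undefined at $p = 0$, so p-values are floored at 1e-300; a zero fold
change scores 0. Ties (same p, same sign) are broken by |log2FC|
descending, then gene id, so downstream enrichment sees a strictly
deterministic ordering.

## Pre-ranked enrichment

`enrichmentScore` implements the weighted Kolmogorov–Smirnov running
sum: walking the ranked list, member genes advance the sum by
$|s|^w / \sum_{members} |s|^w$ and non-members retreat it by
$1/(N-k)$; the enrichment score is the extremum of largest magnitude
and the leading edge collects members at or before it (after it, for
negative scores).

The weight exponent deserves a note. The inverse-p metric spans an
enormous dynamic range (1 up to 1e300), so with $w = 1$ the hit
increments are dominated by the single most significant gene: any set
containing it saturates to $|ES| \approx 1$, the permutation null
acquires a point mass near 1, calibration inflates (~0.10 observed at
a nominal 0.05) and genuinely shifted sets become indistinguishable.
`enrichmentScore` keeps $w = 1$ as its own default for comparability
with the classic weighted statistic (and matches `fgsea`'s statistic
exactly in the tests), but `permutationEnrichment` — the significance
engine — defaults to $w = 0$, the classic KS form that depends only on
member positions and is invariant under monotone transformations of
the metric. With it, null rejection at 0.05 averages 0.052 and planted
1-log2-unit set shifts are recovered at FDR < 0.05.

Significance uses gene-label permutation (member positions resampled
at matched size), not sample permutation: with four samples per group
sample permutation is degenerate, and pre-ranked enrichment
conventionally permutes genes. The p-value uses the add-one estimator
$(1 + \#\{|ES_0| \ge |ES|\})/(B+1)$, so it is never zero, and FDR is
BH over permutation p-values — simpler than the NES-stratified scheme
of classic GSEA; the normalized score $ES / \overline{|ES_0^{same\ sign}|}$
is still reported for comparability. The size window defaults to
10–500 present members, standard practice.

## Gsheat: per-sample set activation

Within each sample, genes are ranked from least (1) to most expressed
($N$) on **raw counts**, ties receiving average fractional ranks so the
per-sample rank sum is exactly $N(N+1)/2$. Because ranks are invariant
under any per-sample monotone transform, CPM scaling or logging cannot
change a Gsheat score — normalization choice is irrelevant by
construction, which the tests assert. The average-tie policy is what
preserves the conservation identity exactly.

A set's score in a sample is the sum of its members' ranks
(`setScoreMatrix`); for $k$ present members the score lies in
$[k(k+1)/2,\, k(2N-k+1)/2]$, enforced as a class invariant. A
normalized form (raw / $k(N+1)/2$, equal to 1 at the null midpoint)
is available for cross-set comparison; the raw score drives all
testing.

Differential set activation between groups uses a moderated t: per-set
pooled variances are shrunk toward a prior estimated by moment
matching of the variance distribution under a scaled-inverse-chi-square
model (marginally $s^2 \sim s_0^2 F(d, d_0)$; the second moment gives
$d_0$, the first gives $s_0^2$), and the prior degrees of freedom are
added to the test. When the moments are incompatible with a finite
$d_0$ the prior is taken as infinite (full shrinkage to the pooled
variance); with fewer than 10 sets the ordinary pooled-variance t is
used instead. On simulated data the resulting p-values track an
established empirical-Bayes implementation at r > 0.999.

Heat-map display z-scores each set row across samples and clusters
rows and columns by average-linkage hierarchical clustering on
Euclidean distance with a yellow-high/dark-red-low palette; scaling
and linkage are display choices only — the ordered matrix is returned
for programmatic use. The enrichment-map export emits nodes (sets at
FDR < 0.05) and edges (Jaccard overlap ≥ 0.25), thresholds matching
common enrichment-map practice.

## Two-dimensional multi-contrast enrichment

Genes present in both contrasts are ranked within each (ascending in
the signed inverse-p score, so most down-regulated = rank 1; average
ranks at ties; genes missing from either contrast are dropped and
counted). Each set receives one signed displacement per axis:

$$s_d = \frac{2\,(\overline{R}_d - (N+1)/2)}{N} \in (-1, 1),$$

zero for the whole universe, positive when members sit above the
middle of the ranking. This scaled mean-rank displacement is the
package's single largest interpretive choice: it is bounded,
direction-signed, symmetric under axis swap and negation (both
properties are tested), and in the spirit of rank-MANOVA approaches to
multi-contrast enrichment.

Significance compares member vs non-member 2D rank vectors with a
two-sample Hotelling T² (F approximation) — fast and deterministic —
with a member-resampling permutation test as the reference engine; the
two agree in rank order at Spearman ≥ 0.99 on random sets, and the
Hotelling engine falls back to permutation (with a warning) when the
pooled covariance is numerically singular, as happens when the two
contrasts are identical. Quadrant labels follow the signs of
$(s_1, s_2)$; classification additionally requires FDR < 0.05 and a
material per-axis displacement $|s_d| \ge 0.1$, yielding both-up /
both-down / contrast-specific / discordant classes. The miRNA-target
mode is the same computation keyed by miRNA, reporting the set of
miRNAs whose targets are coherently down in both contrasts — the
signature of miRNA-mediated repression. Transcription-factor-target
analysis is the identical computation with a TF-target collection; no
separate code path exists.

Member-vs-nonmember (rather than member-vs-all) comparison was chosen
for the Hotelling engine so the two samples are disjoint, as the
two-sample statistic assumes.

## Phenotype statistics from published summaries

Both reconstruction operations depend on the data only through
per-cell (mean, SEM, n), so any full dataset realizing those summaries
gives identical answers — verified in the tests by comparing two
distinct reconstructions.

`anovaFromSummaries` fits the 2×2 cell-mean model by weighted least
squares with effect coding and reports Type III (marginal) sums of
squares per effect. Type III matches the behaviour of the commercial
statistics package conventionally used with such tables, and matters
here because one design cell (aging DOCA, n = 8) is larger than the
others. Within-cell SS is recovered as
$\sum_i (n_i - 1)\, n_i\, \mathrm{SEM}_i^2$. Percent variation is
$100 \cdot SS_{effect}/SS_{total}$; for balanced designs the effect
and residual percentages sum to exactly 100, under mild imbalance the
decomposition is approximate (a property of Type III, not of the
implementation). Agreement with a full-data Type III ANOVA on
reconstructed observations is at machine precision. On the published
septal-thickness row the disease effect reproduces at 79.5% vs the
printed 80.6% — within the ±2-point tolerance implied by
two-significant-digit rounding of the printed means and SEMs. Other
rows of that published table describe serial examinations whose extra
timepoints are not recoverable from a single 2×2 of summaries, so only
the internally consistent row is used as a worked example.

`welchTFromSummaries` is the Welch t with Satterthwaite degrees of
freedom computed directly from the summaries; `familyBh` applies BH
within declared endpoint families.

## The synthetic-data generator

`simulateCounts` draws NB counts with
$\log_2 \mu_{gs} = \mathrm{baseline}_g + \log_2 \mathrm{lib}_s +
\mathrm{age}_g \cdot \mathbb{1}[\mathrm{aging}] + \mathrm{effects}$,
and $\phi_g = \phi_0 + \mathrm{slope}/\mu_g$. Defaults encode the
study conditions: group sizes (6, 4, 4, 4) matching the sequencing
arms; baseline log2 means N(5, 2) giving a realistic expression range
with a low-expression tail that exercises the count filter; dispersion
$(\phi_0, \mathrm{slope}) = (0.05, 2)$ — conventional bulk-tissue
values, flagged as conventions since no dispersion estimates exist for
the motivating data; library-size factors log-normal(0, 0.15); 5%
planted differential genes per contrast at |log2FC| = 2; age main
effects N(0, 0.25), deliberately smaller than treatment effects so the
factorial structure exists without dominating; and 5 activated sets
per contrast shifted by 1 log2 unit member-wise in the DOCA samples of
their stratum. A single integer seed fans out deterministically to
per-component sub-seeds, so ground truth is fully recoverable from
config + seed and output is byte-identical under a fixed seed.

The generator emulates NB sampling noise, library-size variation and
coherent set activation. It does **not** emulate batch effects, sample
outliers, gene–gene correlation within samples beyond set-driven mean
shifts, or composition effects from a few extremely abundant genes —
so passing tests demonstrate statistical correctness of the machinery
under the stated model, not robustness to those real-data phenomena.

Test and acceptance runs use 2,000 genes and 100 sets — the package's
chosen working scale for validation, large enough for stable
calibration estimates (roughly 1,600 genes survive filtering) while
keeping the full suite quick; a 14,410-gene run reproduces the
post-filter scale of the motivating experiment and is supported but
not exercised by default.

## Numerical choices and degenerate inputs

* Exact-test enumeration windows: full enumeration to S = 20,000,
  ±50 SD window beyond; observed split always included.
* p-value floors: 1e-300 throughout, keeping scores finite and
  p ∈ (0, 1].
* A set spanning the whole ranked universe has no miss steps; its
  running sum is reported (it climbs to exactly 1) with a degenerate
  flag and warning.
* Sets with fewer than 2 present members are skipped with a warning in
  every set-level operation; an empty surviving collection is an
  error.
* All-zero samples are an error naming the sample; an all-zero matrix
  filters to an empty result with a warning.
* Identical groups give log2FC = 0 and p = 1 exactly; identical set
  scores give t = 0, p = 1.

## Limitations

* The exact test implements the classic two-group NB test; no GLM
  framework, quasi-likelihood or covariates (e.g., batch) are
  provided.
* Permutation p-values have resolution 1/(B+1); FDR over them is
  conservative relative to NES-stratified schemes when many sets are
  truly active.
* The 2D displacement formula is one defensible choice among rank
  statistics for multi-contrast enrichment; magnitudes are comparable
  within an analysis, not across packages.
* Reconstruction from summaries cannot recover repeated-measures
  structure; tables of serial measurements mix timepoints the 2×2
  model cannot see.
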