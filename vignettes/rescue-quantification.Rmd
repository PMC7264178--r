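---
title: "Quantifying double-mutant rescue in transcriptomes and H3K4me3 landscapes"
author: "epirescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying double-mutant rescue in transcriptomes and H3K4me3 landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirescue)
```

## The scientific problem

Chromatin writer and eraser enzymes that act on the same mark — here
H3K4 trimethylation, deposited by a methyltransferase and removed by a
demethylase — can in principle be balanced against each other: combining a
writer-deficient mutant with an eraser-deficient mutant may *mutually
suppress* the molecular defects of either single mutant. The experimental
design that probes this is a four-genotype factorial: wild type (`WT`), a
writer heterozygote (`A_HET`), an eraser knockout (`B_KO`), and the double
mutant (`DM`), each profiled by RNA-seq and by spike-in-calibrated H3K4me3
ChIP-seq.

`epirescue` implements the genomic analysis layer of such a design:

1. negative-binomial differential testing of genes (DEGs) and of H3K4me3
   regions (DMRs) for the five informative contrasts
   (A vs WT, B vs WT, DM vs WT, DM vs A, DM vs B);
2. spike-in nucleosome QC and normalization for the ChIP arm;
3. *rescue quantification*: does the double mutant move the single
   mutants' molecular changes back toward wild type, and which features
   drive that movement;
4. integration of mRNA and chromatin changes (quadrant analysis) and
   Fisher gene-set enrichment of rescue-driving genes.

A synthetic-data module generates complete experiments with known planted
effects, so every stage is validated against ground truth rather than
against itself.

## The model

### Counts

Counts for feature $g$ in sample $j$ are modeled as negative binomial,

$$ y_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\ \alpha_g\right), \qquad
   \mu_{gj} = s_j\, q_g\, 2^{\beta_{g}(\mathrm{genotype}_j)}, \qquad
   \mathrm{Var}(y_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2, $$

with per-sample size factors $s_j$, baseline abundance $q_g$, and a log2
genotype effect $\beta_g$. Size factors are the classical median-of-ratios
(`size_factors()`): the median over all-positive features of the ratio of
a sample's count to the feature's geometric mean. Size factors are defined
up to a shared constant; only their ratios matter, and those are exactly
equivariant under rescaling of a sample.

Dispersions are estimated by the method of moments
(`estimate_dispersions()`): on normalized counts, with per-genotype
centering, $\hat\alpha_g = \max\{\alpha_{\min}, (v_g - \xi m_g)/m_g^2\}$
where $v_g$ is the pooled within-genotype variance, $m_g$ the mean,
$\xi = \overline{1/s_j}$ corrects the Poisson term for normalization, and
$\alpha_{\min} = 10^{-8}$. There is deliberately no shrinkage of
dispersions toward a mean-variance trend and no fold-change shrinkage:
the rescue statistics downstream consume raw group-mean contrasts, and
shrunken fold changes would bias the slope estimates that quantify rescue.
An optional pooled mode (`method = "common"`) gives every feature the mean
of the raw per-feature estimates, appropriate when dispersion is
exchangeable across features (as in the simulator).

### The Wald test and its reference distribution

`nb_wald_test()` fits, per feature, the NB log-link model of the genotype
indicator with offsets $\log s_j$ and fixed $\hat\alpha_g$ (a small
vectorized Newton iteration per group), and tests
$\mathrm{stat} = \widehat{\log_2\!\mathrm{FC}} / \mathrm{SE}$ with SE from
the Fisher information.

A numerical choice that matters: the reference distribution for the Wald
statistic is Student's *t* with the dispersion-estimation residual degrees
of freedom ($n - K$; 12 for four genotypes with four replicates), not the
normal. Per-feature moment dispersions carry substantial sampling noise,
and plugging them into a normal-referenced Wald statistic is
anticonservative — in our null calibrations the nominal-0.05 rejection
rate was close to 0.08, and genome-wide minimum p values were inflated
enough to produce spurious BH discoveries in every null run. With the *t*
reference the rejection rate sits at the nominal level and null
experiments produce empty strict DEG sets, as they should. When the
pooled common dispersion is used, its effective degrees of freedom are
essentially infinite and the reference reduces to the normal.

Features with zero counts in every sample of a contrast are excluded from
testing and from the BH ranking (the GLM is undefined); features where one
group is all-zero have an infinite fold-change MLE without shrinkage and
are flagged with `NA` statistics rather than reported as spurious
certainties. `bh_adjust()` is a literal Benjamini–Hochberg step-up, with
`NA` propagation and deterministic ordering.

### Thresholds

The screens use fixed thresholds, exposed as configuration rather than
hard-coded: DEGs at BH-adjusted $p < 0.1$ (strict) or raw $p < 0.005$
(relaxed); DMRs at adjusted $p < 0.05$ (strict) or raw $p < 0.05$
(relaxed). The relaxed screens exist for the writer heterozygote, whose
remaining functional allele produces effects too mild for the strict
screen at realistic replication; which genotypes use the relaxed screen is
a pipeline setting (`deg_relaxed_for`), defaulting to `A_HET` only. All
inequalities are strict.

## Spike-in normalization

Barcoded recombinant nucleosomes carrying a panel of methylation states
(15 barcodes, two of them carrying the target mark, in the default
configuration) are added before immunoprecipitation. They serve two
purposes.

**Specificity QC** (`spike_specificity()`): the fraction of spike reads
carrying the target mark per IP. The default pass criterion — target
fraction at least 0.8 in every IP — encodes "the target mark dominates
with negligible off-target signal"; the exact value is a package default,
not an externally fixed constant.

**Depth normalization** (`spike_norm_coefficients()`): for IP $i$,

$$ E_i = \frac{\mathrm{spike}_i / \mathrm{total}_i}
              {\mathrm{spike}_{\mathrm{input}} / \mathrm{total}_{\mathrm{input}}},
   \qquad c_i = \frac{E_i}{\mathrm{geomean}(E)}, \qquad
   s^{\mathrm{eff}}_i = \frac{\mathrm{total}_i\, c_i}
                             {\mathrm{geomean}(\mathrm{total} \cdot c)} . $$

Normalized signal is $\mathrm{count}/s^{\mathrm{eff}}_i$. Anchoring $c_i$
at the geometric mean keeps the coefficients log-symmetric; the
convention (higher spike enrichment ⇒ larger effective depth ⇒ signal
divided down) is fixed and documented here because the direction is not
forced by the definition alone. Two properties motivate the construction:
$c_i$ is invariant to uniform sequencing-depth rescaling of an IP, and a
genome-wide signal gain — which dilutes the constant spike and is exactly
the change that per-depth normalization erases — is preserved. The
`total` quantities are the user's total mapped read counts (any common
scale); the pipeline reads them from a `total_reads` design column and
falls back to column sums. Black-list filtering and peak calling are
upstream of this package: the input contract is a count matrix over an
agreed region set (BED, 0-based half-open).

## Rescue statistics

All rescue statistics consume the five-contrast fold-change table
(`build_fold_change_table()`), computed under one shared normalization so
that contrast additivity
$\log_2\mathrm{FC}(\mathrm{DM\ vs\ A}) =
 \log_2\mathrm{FC}(\mathrm{DM\ vs\ WT}) -
 \log_2\mathrm{FC}(\mathrm{A\ vs\ WT})$
holds to numerical tolerance.

**Direction cross-classification** (`classify_direction()`): a feature
changed in one mutant is `opposite`, `same`, or `unchanged` in the other.
"Changed in the other mutant" requires nominal $p < 0.05$ there — sign
alone would classify pure noise — and the nominal level is configurable.
A fold change of exactly zero is `unchanged` regardless of its p value.

**Group shift test** (`group_rescue_test()`): a paired Wilcoxon
signed-rank test of DM versus single-mutant fold changes over a feature
set, the group-level readout of rescue. The signed-rank engine
(`signed_rank_test()`) drops zero differences, uses mid-ranks for ties,
computes the exact null distribution by convolution for $n \le 25$
(doubling the possibly half-integer mid-ranks to integers), and otherwise
a tie-corrected normal approximation with continuity correction.
Two-sided p doubles the smaller tail, capped at one. Tests are two-sided
by default throughout; one-sided alternatives are available but nothing
in the package asserts a direction a priori.

**Slope against unity** (`slope_test()`): regressing DM fold changes on
single-mutant fold changes through the origin, a slope below one is
fold-change shrinkage — partial rescue — and its size is directly
interpretable (slope $\approx a$ means the double mutant retains a
fraction $a$ of the single mutant's misregulation). Two estimators ship:

* `ols_origin`: $\hat b = \sum xy / \sum x^2$, t test of
  $(\hat b - 1)/\mathrm{SE}$ on $n-1$ df. This is the default, matching
  the plain reading of "linear regression".
* `sma_origin`: the standardized major axis through the origin,
  $\hat b = \mathrm{sign}(\sum xy)\sqrt{\sum y^2 / \sum x^2}$, tested via
  the correlation of the rotated axes $(y - x,\ y + x)$ against an F
  reference on $(1, n-1)$ df. SMA treats noise in both coordinates
  symmetrically, which is arguably right when both axes are estimated
  fold changes.

Both are first-class because the choice is genuinely ambiguous in the
field's practice — figure legends say "linear regression" while the
commonly cited slope-test implementation defaults to SMA — so the method
is recorded in every result rather than silently assumed. Degenerate
inputs are defined exactly: $y = x$ gives statistic 0 and $p = 1$; a
perfect non-unit fit gives $p = 0$; all-zero $x$ is an error.

**Rescue drivers** (`call_rescue_drivers()`): the explicit screen for
features that move strongly off the single mutant while the double mutant
sits near wild type —
$|\log_2\mathrm{FC}(\mathrm{single\ vs\ DM})| > 2$ and
$|\log_2\mathrm{FC}(\mathrm{DM\ vs\ WT})| < 0.7$ for RNA, with the first
threshold relaxed to 1 in the chromatin-integration domain. Inequalities
are strict, so a fold change of exactly 2 is not a driver.

**Direction-stratified DMR summary** (`dmr_rescue_summary()`): for
chromatin, rescue is evaluated on the loci consistent with each enzyme's
activity — hypomethylated regions for the writer mutant, hypermethylated
for the eraser mutant — stratified by the opposite/same classification,
with per-class fold-change quartiles and group shift tests.

## Integration and enrichment

`annotate_peaks()` assigns each region to the gene with the nearest TSS
(midpoint distance; ties broken by the lexicographically smaller gene id,
a deterministic rule) with feature classes prioritized promoter
($\pm$1 kb of the TSS) > exon > intron > distal, strand-aware, 0-based
half-open coordinates throughout.

`quadrant_analysis()` classifies paired mRNA ($x$) and H3K4me3 ($y$) fold
changes by sign: Q1 $(x<0,y>0)$, Q2 $(x>0,y>0)$, Q3 $(x<0,y<0)$,
Q4 $(x>0,y<0)$. Because a bare "chi-squared test" on four counts is
ambiguous, three labeled variants are always computed: a 4-cell goodness
of fit against the uniform quarter split, a 2-cell concordance test
(Q2+Q3 vs Q1+Q4), and 2-cell tests within each $x$ sign (Q2 vs Q4,
Q3 vs Q1). Exact zeros are excluded from the quadrants and reported as a
fifth count, and the counts are invariant under positive rescaling of
either axis. Pearson's $r$ on the paired fold changes accompanies the
counts.

`fisher_enrichment()` is a one-sided Fisher exact test per gene set from
the hypergeometric tail, with the classical cross-product odds ratio
$ad/bc$ (0 for empty overlap, guarded $\infty$ when a margin vanishes)
and BH adjustment across sets. Note that some popular enrichment web
tools report a deviation-adjusted odds ratio instead of $ad/bc$; the
classical definition is used here and stated in the output. The universe
defaults to the tested features — enrichment against the whole genome
would conflate expression filtering with biology. Gene sets arrive as
GMT; none are shipped.

## The synthetic-data generator

`simulate_rnaseq()` / `simulate_chipseq()` generate the four-genotype
design: NB counts with lognormal baselines, uniform per-sample depth
factors, planted single-mutant effects, and a double mutant whose effects
compose additively in log2 space, attenuated multiplicatively by
$a \in [0,1]$ for the rescued fraction:

$$ \beta_{\mathrm{DM}} = a^{[\mathrm{rescued}]}
   (\beta_A + \beta_B). $$

This construction makes slope-below-one the *identifiable* planted target
of the rescue statistics: for rescued features the DM-vs-single slope is
exactly $a$ in truth. Defaults encode the emulated biology: eraser-KO
effects predominantly up (8% up / 3% down of features), writer-HET
effects predominantly down (1% / 4%), a quarter of one mutant's affected
features oppositely affected in the other, effect magnitudes lognormal
around one log2 unit, dispersion 0.05, depth factors uniform on
[0.7, 1.3], RNA 4 replicates and ChIP 3 replicates per genotype plus one
input. Effect-size magnitudes are calibration choices — the real
experiments' effect sizes are not published as distributions — made once
and documented here, not tuned.

The ChIP simulator scales region counts by a per-IP efficiency $e_i$
(confounding biology with antibody performance, which is exactly what
spike normalization must undo) and encodes $e_i$ in the spike table:
target barcodes captured $\propto e_i$, off-target barcodes at a small
relative rate (default 0.02), input carrying all barcodes uniformly.
Spike counts are Poisson — spike depth is small relative to genomic
reads. Promoter regions sit on a deterministic synthetic gene layout so
chromatin and expression can be integrated per gene, optionally
inheriting the RNA truth so that mRNA and H3K4me3 changes are coupled.

What the generator does *not* emulate: read-level artifacts (alignment,
duplicates, mappability), GC bias, a mean-dispersion trend, correlated
features, batch structure, or outlier samples. Passing tests on this
generator therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to everything real data can do;
with real data the usual upstream QC still applies.

## Problem sizes and reproducibility

The validation suite runs at desk scale, chosen to give sharp checks at
interactive runtimes: null calibration on 2,000 genes × 16 samples over
20 seeds; slope recovery with 300 planted DEGs among 1,000 genes over 100
replicate simulations per attenuation value (0.5, 0.7, 0.9); driver
fidelity with planted margins of 0.5 log2 units beyond the thresholds;
spike recovery on 1,000 regions; oracle equivalences (signed-rank vs full
$2^n$ enumeration, Fisher vs tail summation, BH vs literal step-up,
nearest-TSS vs exhaustive search) on hundreds of random instances. Every
simulation is seeded; `run_pipeline()` is byte-deterministic given its
configuration, and reruns are verified checksum-identical.

## Known limitations

* Per-feature moment dispersions are noisy at few replicates; the *t*
  reference restores calibration but power is below that of
  information-sharing estimators on real data with a mean-dispersion
  trend.
* Fold-change estimates for features with one all-zero group are `NA` by
  design; downstream set operations treat them as untestable rather than
  imputing extreme fold changes.
* The nearest-TSS assignment is the classical heuristic; it does not
  model enhancer–promoter contacts.
* A single shared input is assumed for spike normalization; multiple
  inputs are pooled by total counts.
* No causal claim connects rescue-driving genes to phenotype; the package
  quantifies molecular rescue only.
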