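# epirescue

Quantifying mutual suppression (genetic rescue) between a chromatin
**writer** mutant and a chromatin **eraser** mutant from genomic count
data.

## The problem

H3K4 methylation is balanced by methyltransferases (writers) and
demethylases (erasers), and mutations in either class cause
neurodevelopmental disorders. A natural question is whether the two
defects can cancel: in a four-genotype factorial design — wild type
(`WT`), writer heterozygote (`A_HET`), eraser knockout (`B_KO`), and the
double mutant (`DM`) — does the double mutant's transcriptome and H3K4me3
landscape move back toward wild type?

`epirescue` is for analysts working with such designs. It takes
feature-by-sample count matrices (RNA genes, ChIP regions), a sample
design table, a region BED, a spike-in barcode table, gene annotation,
and gene sets (GMT), and produces the full rescue analysis:

* **DE core** — median-of-ratios size factors, method-of-moments NB
  dispersions, a per-feature negative-binomial Wald contrast without
  fold-change shrinkage, Benjamini–Hochberg adjustment, and DEG calling
  at the strict (`padj < 0.1`) / relaxed (`p < 0.005`) screens.
* **Spike-in ChIP** — antibody-specificity QC from barcoded nucleosome
  spike-ins, per-IP normalization coefficients
  `c_i = E_i / geomean(E)` from IP/input spike enrichment
  `E_i = (spike_i/total_i) / (spike_input/total_input)`, effective size
  factors, and DMR calling (`padj < 0.05` strict, `p < 0.05` relaxed).
* **Rescue statistics** — the five-contrast fold-change table,
  opposite/same/unchanged direction cross-classification, paired
  Wilcoxon signed-rank group shift tests (exact by enumeration-equivalent
  convolution for `n <= 25`), through-origin regression slopes tested
  against 1 (`slope = sum(xy)/sum(x^2)` by OLS, or the standardized major
  axis `sign(sum(xy)) * sqrt(sum(y^2)/sum(x^2))`), and rescue-driver
  calling at `|log2FC(single vs DM)| > 2` and `|log2FC(DM vs WT)| < 0.7`
  (1 and 0.7 in the chromatin-integration domain).
* **Integration** — nearest-TSS peak annotation (promoter ±1 kb > exon >
  intron > distal), mRNA-by-H3K4me3 quadrant analysis with labeled
  chi-squared variants and Pearson correlation, and Fisher exact gene-set
  enrichment with the classical `ad/bc` odds ratio.
* **Synthetic data** — a generator that plants single-mutant effects and
  a double-mutant effect `beta_DM = a * (beta_A + beta_B)` for rescued
  features (`a` in `[0,1]`), plus spike-in structure encoding per-IP
  efficiency, so every stage is testable against ground truth.

See the methods vignette (`vignettes/rescue-quantification.Rmd`) for the
model, parameter meanings, and design rationale.

## Worked example

Simulate an eraser-heavy experiment with 60% of affected genes rescued at
attenuation `a = 0.4`, then quantify the rescue:

```r
library(epirescue)

cfg <- sim_config(n_genes = 800, frac_rescued = 0.6, attenuation_a = 0.4,
                  effect_logmean = 0.7, seed = 42)
sim  <- simulate_rnaseq(cfg)
sf   <- size_factors(sim$counts)
disp <- estimate_dispersions(sim$counts, sf = sf)
de   <- lapply(list(A_vs_WT = c("A_HET","WT"), B_vs_WT = c("B_KO","WT"),
                    DM_vs_WT = c("DM","WT"),  DM_vs_A = c("DM","A_HET"),
                    DM_vs_B = c("DM","B_KO")),
               function(ct) nb_wald_test(sim$counts, ct, sf = sf,
                                         dispersions = disp))
degs <- call_degs(de$B_vs_WT, "strict")
fc   <- build_fold_change_table(de)

up <- match(degs$feature[degs$direction == "up"], fc$feature)
group_rescue_test(fc$log2FC_B_vs_WT[up], fc$log2FC_DM_vs_WT[up])
#> group rescue test: n = 65, median fc 1.743 -> 1.115 (attenuated),
#>   W = 233, p = 4.19e-08 [normal]

i <- match(degs$feature, fc$feature)
slope_test(fc$log2FC_B_vs_WT[i], fc$log2FC_DM_vs_WT[i])
#> slope test (ols_origin): slope = 0.6137 [0.5279, 0.6995],
#>   p(H0 slope=1) = 3.51e-14, n = 94
```

Reading the output: the 94 strict eraser-KO DEGs keep their direction in
the double mutant but with shrunken fold changes — the up-regulated set's
median log2 fold change drops from 1.74 to 1.12 (signed-rank
p = 4.2e-08), and the regression of DM on single-mutant fold changes has
slope 0.61, significantly below 1. That matches the planted truth: 60% of
genes attenuated to 0.4 of their single-mutant effect and 40% left alone
gives an expected slope of `0.6*0.4 + 0.4*1 = 0.64`.

The whole analysis can also be driven from a YAML configuration:

```r
cfg <- read_pipeline_config(system.file("extdata", "config_demo.yaml",
                                        package = "epirescue"))
report <- run_pipeline(cfg, out_dir = "demo_run")
```

or from the shell via
`Rscript inst/scripts/run_pipeline.R --config config.yaml --out outdir`.

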