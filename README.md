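# spheroprot

Differential proteomics for 3D spheroid vs 2D monolayer comparisons
from multi-batch isobaric-labeling (TMTpro) reporter-ion data.

## What problem this solves, and for whom

Quantitative comparison of spheroid and monolayer cultures of several
cell lines needs more multiplexed samples than one 18-plex run holds,
so samples are spread across several TMT batches bridged by pooled
reference channels. This package is for proteomics analysts who have
protein-level reporter signal-to-noise tables from such a design and
want a reproducible, scriptable pipeline for:

- inclusion filtering (unique-peptide mean S/N > 3 aggregation,
  master-protein retention, whole-batch-NA exclusion, contaminant
  removal — `NA` and `0` kept distinct throughout);
- the normalization cascade: zero floor (0.1), sample-wise median
  normalization, log2, per-batch pooled-reference scaling, row
  centering, plus PCA and correlation QC;
- row-wise one-way ANOVA from explicit sums of squares, per-cell-line
  log2 fold changes (lfc = mean log2 3D − mean log2 2D), volcano
  thresholds (p < 0.01, |lfc| > 1; relaxed p < 0.05 for membrane
  analyses), top-30%-by-sd heatmap selection;
- cross-cell-line concordance classes (common-up / common-down /
  discordant / not-common) and plasma-membrane annotation ratios;
- enrichment statistics: exact hypergeometric over-representation with
  Benjamini–Hochberg adjustment, and weighted running-sum GSEA
  (ES from hits weighted by |score|^w) with a seeded gene-label
  permutation null;
- carboplatin chemosensitivity: background-corrected
  percent-of-control and four-parameter logistic (4PL) fits,
  `f(c) = bottom + (top − bottom)/(1 + (c/c0)^h)`, with closed-form
  GI50 `c0·((top − 50)/(50 − bottom))^(1/h)`.

A first-class synthetic-data generator emulates the full design
(4 cell lines × {2D, 3D} × 3 replicates over 4 batches, 3 pooled
reference channels per batch, per-(protein, batch) multiplicative
batch effects, sparse zeros, spiked 3D-only contaminants) with ground
truth labels, so every stage is testable without raw repository data.
See `vignettes/spheroprot-methods.Rmd` for the model and every
numerical choice.

## Worked example

```r
library(spheroprot)
cfg <- pipeline_config(seed = 1, synthetic = synthetic_params(seed = 1))
man <- run_pipeline(cfg)          # add outdir = "run1" to write TSVs
man
#> spheroprot run manifest (seed 1)
#>               stage n_proteins
#>              ingest       6040
#>       master_filter       6040
#>  contaminant_filter       6000
#>           normalize       6000
#>        differential       6000
#>         concordance        600
cnt <- report_counts(man)
cnt$n_quantified
#> [1] 6000
cnt$per_line
#>           PEO1           PEO4       UWB1.289 UWB1.289+BRCA1
#>            578            588            580            586
cnt$concordance
#>   common_up common_down  discordant  not_common
#>         251         238          44          67
```

Reading: 6040 generated rows lose the 40 spiked contaminants; of 6000
proteins, ~580 per cell line pass p < 0.01 and |lfc| > 1 (the world
injects 600 true differentials, 90% with a shared sign); 533 are
significant in all four lines, split into 251 up, 238 down and 44
discordant — the three classes always sum to the all-lines
intersection. Dose–response:

```r
plate <- simulate_plate(condition = "PEO1_2D", c0 = 25, noise_sd = 5,
                        seed = 1)
pct <- percent_of_control(plate)
nz <- pct$concentration_uM > 0
fit_4pl(pct$concentration_uM[nz], pct$mean_pct[nz])
#> 4PL fit: bottom=5.63 top=94.8 hill=1.23 c0=30.04 | GI50=30.26 | rss=21.5
```

With 5% measurement noise on a curve whose true midpoint is 25 µM, the
fitted midpoint lands at 30 µM for this seed; across 50 seeds the
median recovers within 10% (tested).

## Command line

```sh
inst/exec/spheroprot simulate --seed 1 --outdir sim      # synthetic data
inst/exec/spheroprot run-all  --seed 1 --outdir run1     # end-to-end
inst/exec/spheroprot gi50 --plate plate.csv --out fits.tsv
```

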