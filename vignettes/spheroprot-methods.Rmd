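---
title: "Methods: multi-batch reporter-ion proteomics for 3D/2D comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-batch reporter-ion proteomics for 3D/2D comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroprot)
```

## The problem

Comparing the proteomes of 3D spheroid and 2D monolayer cultures of the
same cell lines requires more multiplexed samples than a single
isobaric-labeling (TMTpro, 18-plex) run can hold: four cell lines grown
in two dimensions with three biological replicates is 24 samples, spread
over four mass-spectrometry batches. Reporter-ion signal-to-noise (S/N)
values are only comparable within a batch; each batch therefore carries
aliquots of pooled reference samples, and the analysis must (i) bridge
batches through those references, (ii) call per-protein 3D-vs-2D
differences per cell line, (iii) intersect the calls across cell lines,
and (iv) feed derived sets into annotation-ratio, over-representation
and gene-set-enrichment statistics. A separate assay fits carboplatin
dose–response curves to compare chemosensitivity (GI50) between culture
dimensions.

`spheroprot` implements this pipeline as composable, tested stages, with
a synthetic-data generator that produces ground-truth-labeled datasets
with the same multiplexed structure, so every stage can be validated
without access to raw repository data.

## The generative model behind the synthetic data

On the log2 scale, the generator draws for protein $p$, sample $s$ in
cell line $l$ and dimension $d$, measured in batch $b$:

$$\log_2 x_{ps} = \mu_p + \lambda_{pl} + \delta_{pl}\,[d = 3D] +
  \varepsilon_{ps} + \beta_{pb}$$

with baseline $\mu_p \sim N(7, 2^2)$ (an S/N-like scale for summed
reporter intensities), cell-line offsets
$\lambda_{pl} \sim N(0, \sigma_\text{line}^2)$, dimension effects
$\delta_{pl} = \pm\,e$ for differential proteins (zero otherwise),
replicate noise $\varepsilon_{ps} \sim N(0, \sigma_\varepsilon^2)$, and
a per-(protein, batch) multiplicative batch offset
$\beta_{pb} \sim N(0, \sigma_\text{batch}^2)$. A reference pool is the
*linear-scale mean* of the sample abundances pooled into its set —
pooling physically precedes labeling, so the pool itself carries no
batch offset; its measured aliquot in batch $b$ does carry
$\beta_{pb}$. This form is chosen deliberately: because samples and
reference aliquots of one batch share $\beta_{pb}$ exactly, subtracting
the per-batch reference mean removes the batch effect identically, which
turns the pipeline's central claim ("references correct batch effects")
into an exact, testable property rather than a visual impression.

Default parameters state the emulated world once: 6000 proteins, 10%
differential with effect $e = 2$ log2 units, 90% of effects shared with
one sign across cell lines, $\sigma_\text{line} = 0.5$,
$\sigma_\text{batch} = \sigma_\varepsilon = 0.25$ (batch artifacts
comparable to replicate noise, making correction visibly necessary),
observed zeros at rate 0.004 (under the 0.5% prevalence the filtering
rules assume), and 40 contaminant rows present only in 3D sample
channels (a desk-scale stand-in for the hundreds of mouse-matrix
protein groups such experiments identify; the count is a parameter, not
a claim). Sample-to-batch assignment is a seeded random shuffle dealt
evenly, reference pools a seeded random partition into three sets —
randomized layouts under the stated constraints, since real channel
maps are study-specific.

What the generator does **not** emulate: peptide-spectrum-level noise,
isotopic-impurity crosstalk between channels, missingness that
correlates with abundance, or batch effects that are not multiplicative
per protein. A green test on synthetic data therefore establishes that
the code implements the model's arithmetic and statistics correctly —
not that the model captures every pathology of real reporter-ion data.

## Filtering rules

Three inclusion rules are applied before normalization, in any order
(they commute and are idempotent):

* **Peptide aggregation** (optional path): only peptides unique to one
  protein group are used, kept when their mean reporter S/N across
  channels is *strictly* greater than 3; protein value = sum of
  retained peptide S/N. Summation is the standard reporter-quant
  aggregate.
* **Master-protein retention**: a protein missing (`NA`) across an
  entire batch is dropped; a protein with observed zeros is kept —
  in multiplexed data a zero is read as true biological absence,
  whereas a batch-wide `NA` means the protein was never quantified in
  that run. `NA` and `0` are distinct states end-to-end, including in
  the TSV dialect (empty cell vs literal `0`).
* **Contaminant removal**: any protein group containing at least one
  listed contaminant accession is removed (Matrigel-derived mouse
  proteins occur only in 3D harvests, so the generator spikes them
  into 3D channels only).

## The normalization cascade

1. **Zero replacement**: observed zeros become 0.1 so ratios and logs
   are defined. The floor is absolute; it is the one step that is not
   scale-equivariant, which matters only for all-but-absent proteins.
2. **Sample-wise median normalization**: each channel is divided by its
   median and rescaled by the grand median of channel medians (the
   target constant is a display choice; the grand median keeps values
   on the familiar S/N-like scale).
3. **log2 transform.**
4. **Reference scaling**: per batch, subtract each protein's mean over
   that batch's reference channels — from every channel, references
   included, so cross-batch reference replicates become comparable and
   their residual spread is a direct QC readout.
5. **Row centering**: subtract each protein's mean over the biological
   sample channels ("centered at zero across all samples").

Two exactness notes, both verified by tests. First, on noise-free
synthetic data the reference-scaling step removes the injected batch
offsets *identically* (cross-batch reference variance below 1e-18) and
the recovered fold changes equal the injected effects to 1e-9. Second,
those exact statements hold for the cascade with the median step
disabled (`normalize_quant(median_norm = FALSE)`): channel medians are
order statistics, so on data whose channels share a common true loading
the median step is a no-op only in expectation, with realization error
of order $1/(n \cdot f)$ ($f$ the value density at the median —
roughly 0.01 log2 units at 6000 proteins). On real data the step earns
its keep by absorbing loading differences; on synthetic data it has
nothing to remove, and the full-cascade fold-change error is bounded
(< 0.05) rather than zero. This is a property of median normalization
itself, not of this implementation.

QC displays are computed from the normalized matrix: PCA via SVD of the
row-mean-subtracted matrix (complete rows only; variance fractions from
squared singular values) and Pearson correlation matrices at sample
level or between per-cell-line 3D/2D log2-ratio vectors. Pearson is
used throughout; missing values are excluded pairwise, never imputed.

## Differential calling

Row-wise classical (equal-variance) one-way ANOVA, computed from
explicit between/within sums of squares. Per cell line, the 3D-vs-2D
p-value is the two-group ANOVA on that line's six samples (identical to
the squared pooled t); the global p for the heatmap selection is the
eight-group ANOVA. Degenerate rows follow fixed conventions: all values
identical gives $F = 0, p = 1$; zero within-group variance with unequal
means gives the smallest representable positive p with a `degenerate`
flag. No multiple-testing correction is applied at the protein level —
the thresholds are raw-p conventions (0.01 strict, 0.05 relaxed) — but
`bh_adjust()` is available.

Fold change is `mean(log2 3D) − mean(log2 2D)`; positive = up in
spheroids. The volcano filter uses strict inequalities
(`p < thresh` and `|lfc| > thresh`), so a fold change of exactly 1 is
not significant. The heatmap selection keeps, among proteins with
global ANOVA p < 0.01, the top 30% by per-protein sd (ceiling rule,
ties at the cutoff all kept; the rounding rule is a declared choice).

## Concordance and membrane ratios

Proteins significant in *every* cell line are classified by sign
unanimity into common-up, common-down, or discordant; these three
classes always partition the all-lines intersection (a conservation law
the tests enforce on arbitrary inputs). Proteins significant somewhere
but not everywhere are `not_common`. "Detected across all lines" is
read as significant-in-all, since the quantified universe has no
missing values by construction after filtering.

The membrane analysis counts annotated members of each differential set
(by cell line, by pair intersection, or the all-lines set), splits them
by direction, and reports `100 × n_membrane / n_total` against the
universe baseline `100 × |annot ∩ universe| / |universe|`. The
concordance analysis conventionally runs at the strict threshold and
the membrane analysis at the relaxed one; both are configuration.

## Enrichment statistics

* **ORA**: upper-tail hypergeometric by exact summation of the mass
  function, universe = retained proteins of the experiment (not the
  whole annotation database), BH adjustment across sets.
* **GSEA**: the weighted running-sum statistic on the ranked log2(3D/2D)
  vector — hits increment by $|s|^w / \sum_\text{hits} |s|^w$
  (default $w = 1$; $w = 0$ reduces to the classical KS statistic on
  ranks), misses decrement uniformly; ES is the signed maximum
  deviation. The null is gene-label permutation (sample permutation is
  meaningless at $n = 3$ per group), default $B = 1000$, seeded. The
  p-value is computed against same-sign null scores, the standard GSEA
  convention; this stratification is what makes the p-value uniform
  under a random-set null, which the calibration test checks by KS. An
  unstratified `(1 + #tail)/(B + 1)` would be capped near the sign
  probability (~0.5) and could never be calibrated. GO terms are
  treated as flat sets; no hierarchy propagation or redundancy
  trimming.

## Dose–response

Background correction subtracts the mean of cell-free wells per
replicate (falling back to the condition-level background, then to 0
with a warning); percent-of-control divides by the corrected zero-dose
signal; replicate curves are summarized as mean ± sd across the
independent experiments. The 4PL model
$f(c) = b + (t - b)/(1 + (c/c_0)^h)$ is fitted by least squares in
$(b, t, \log c_0, \log h)$ — the log parameterization keeps $c_0, h$
positive — with a deterministic multi-start grid (quartiles of the dose
range × Hill slopes 0.5–4), Nelder–Mead, a BFGS pass, and a final
Gauss–Newton polish, so exact model data is recovered to ~1e-6 without
any randomness. GI50 is the *absolute* 50%-of-control crossing, solved
in closed form as $c_0((t - 50)/(50 - b))^{1/h}$ and reported `NA` when
50 is not strictly between the asymptotes; it differs from the relative
midpoint $c_0$ whenever $b + t \ne 100$. The zero dose anchors the
control but is excluded from the log-dose fit; doses span 0–300 µM by
default.

## Numerical and design choices

* Determinism: every stochastic stage (generator, GSEA permutations)
  takes a seed; the pipeline threads one root seed. Identical
  configuration gives byte-identical written outputs (checked by file
  hash).
* Pool-consistency is exact on the linear scale when batch offsets are
  absent; with offsets, a reference channel equals its pool mean times
  the batch factor (the tests state it that way).
* Degenerate inputs are errors with named batches/conditions (missing
  references, zero-variance PCA input, control signal below
  background), not silent results.
* Thresholds are never baked in: `pipeline_config()` carries
  p_strict = 0.01, p_relaxed = 0.05, lfc_min = 1, sd_top_frac = 0.3,
  zero_floor = 0.1, peptide_sn_min = 3 as overridable defaults.

## Known limitations

Headline counts from any real experiment (thousands of differential
proteins, specific intersection sizes) depend on the deposited raw data
and are not reproduced here; the package reproduces the *procedures*
and their arithmetic identities, and validates them on the synthetic
world described above. Moderated (empirical-Bayes) statistics,
imputation, isotopic-impurity correction and plate-layout effects are
out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1,
                       synthetic = synthetic_params(seed = 1))
man <- run_pipeline(cfg, outdir = "run1")
report_counts(man)
```
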