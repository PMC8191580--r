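---
title: "Methods: autoencoder decomposition of the tumor microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoencoder decomposition of the tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Bulk tumor expression mixes two transcriptional programs: what the
infiltrating immune cells express (tumor-extrinsic, TE) and what the
tumor cells themselves express (tumor-intrinsic, TI). decompTME
separates them in three steps.

**Screening.** Genes are ranked by their correlation with an ordinal,
pathology-derived lymphocyte infiltration score. The top-k positive
genes (panel GH′) are dominated by immune-cell transcripts; the top-k
negative genes (GL′) by tumor-cell programs that exclude immune
infiltrate. Spearman is the default coefficient because the lymphocyte
score is an ordinal IHC grade; Pearson is available by argument. The
correlation is computed in z-score space. Neither the coefficient nor
the space is pinned down by the reference procedure; both choices are
config-exposed.

**Compression.** Each panel is compressed by a symmetric autoencoder
(default d → 400 → 100 → 20, mirrored decoder). Every hidden layer is
followed by a ReLU; the reconstruction output is linear because the
targets are z-scores and can be negative. Whether the bottleneck itself
is pre- or post-activation is ambiguous in the source procedure; the
default is post-activation ReLU (so node scores are non-negative), and
`linear_bottleneck = TRUE` switches to the linear reading. The loss is
the regularized square loss — sum over samples of half the squared
reconstruction error plus λ‖w‖², with biases excluded from the
penalty — minimized by mini-batch SGD with momentum.

**Selection.** Each of the 20 bottleneck node scores is dichotomized at
the cohort median and screened with a univariate Cox
proportional-hazards fit; the node with the smallest Wald p-value per
compartment becomes the signature (ties break to the smaller node
index). No multiple-testing correction is applied across the 20 nodes:
the scan is exploratory and mirrors a raw per-node −log10(p) profile.
After selection the score sign is oriented so that higher TE = lower
hazard and higher TI = higher hazard, matching the directional
convention of the compartments; the sign is stored in the model bundle
and applied everywhere downstream, including gene attribution.

## Attribution

The contribution of gene *i* to a bottleneck node is the sum over all
encoder paths of the products of traversed weights — equivalently
column `node` of the product of the encoder weight matrices. Biases
and ReLU nonlinearities are deliberately excluded: the quantity is the
exact linearized path weight as printed in the source formulas, not a
saliency method, and the implementation is tested against a
brute-force triple-loop path enumeration. The signed attribution
ranking feeds pre-ranked GSEA.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `k` (panel size) | 1000 | reference setup; use ≤ n_genes/2 |
| `hidden` | 400, 100 | reference architecture for d_in = 1000; must decrease strictly to the bottleneck |
| `bottleneck` | 20 | reference setup; performance is flat nearby |
| `lambda` | 1e-4 | unreported upstream; weak ridge, config-exposed |
| `learning_rate` / `momentum` | 0.01 / 0.9 | unreported upstream; standard SGD values |
| `batch_size` / `epochs` | 32 / 500 | unreported upstream; epochs is the only stop criterion (no early stopping) |
| `clip_norm` | 5 | see numerical choices |
| `pseudo` | 1 | log2(x+1) for non-negative RNA-seq input |
| `min_overlap` | 0.5 | hard floor on panel genes present when scoring a foreign cohort; warning below 0.8 |
| `genome_size` | 3.1e9 | CNV-burden denominator (human) |
| GSEA exponent `p` | 1 | classic weighted pre-ranked statistic |

## Numerical choices

- **Gradient clipping.** With the stated defaults (lr 0.01, momentum
  0.9, batch 32) plain momentum SGD overshoots on z-scored expression
  panels: after an early dip the iterates jump into the all-dead-ReLU
  basin and the loss pins at the zero-reconstruction plateau. Per-batch
  clipping of the data-gradient global norm (default 5) removes the
  failure without touching the stated hyperparameters; final R² is
  insensitive to the threshold over 1–20.
- **Objective scaling.** The loss is a sum over samples. SGD updates
  use the batch-mean data gradient plus the ridge gradient scaled by
  1/n — a monotone rescaling that makes the step size independent of
  cohort size. The reported loss history is always the exact total
  loss (initial value plus one entry per epoch).
- **Ties.** Median dichotomization sends ties at the median to the low
  group. Panel-boundary correlation ties and attribution-weight ties
  break by gene-symbol lexicographic order, so panels and rankings are
  platform-reproducible.
- **Missing panel genes** in a scored cohort are filled with 0 — the
  cohort mean in z-score space. kNN-style imputation was rejected for
  determinism.
- **Duplicate gene rows** (microarray probes) collapse by arithmetic
  mean in first-occurrence order; the probe-to-symbol mapping used
  upstream is unreported, so this is a package choice.
- **Zero-copy CNV segments** are clamped to copy 0.5 before the log
  (with a warning) to avoid an infinite term; segments absent from the
  file count as diploid and contribute zero burden.
- **Degenerate inputs.** Constant genes are dropped (and reported)
  before z-scoring; constant node scores are skipped in the prognostic
  scan; an all-constant score vector refuses to dichotomize.

## Serialization

A trained bundle is a directory of full-precision (`%.17g`) TSV weight
matrices plus a `metadata.json` carrying panels, node indices, signs,
configuration and per-file checksums. Reloading reproduces encoder
outputs to below 1e-12; truncation or corruption is a hard error. HDF5
was considered and dropped: no HDF5 R binding is guaranteed in the
deployment environment, and plain text keeps bundles diffable.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` states the world the pipeline assumes: per-sample
latent factors `z_imm` and `z_int` (standard normal); a 250-gene block
loaded by `z_imm` and another by `z_int` (unit loading, log2 noise sd
0.5) inside 2000 genes; a 4-level ordinal lymphocyte score that is a
quantile-binned monotone function of `z_imm`; exponential survival
with log-hazard −0.7·z_imm + 0.7·z_int plus small age/sex/stage terms
and ~30% independent censoring; Poisson mutation counts with log-mean
rising in `z_int`; CNV segment counts rising as `z_imm` falls; and
Bernoulli response with logit `z_imm`. The default cohort size, 358,
matches the metastatic training cohort size the method targets.

Two design points deserve emphasis:

- **Factor coupling.** By default the two factors are independent.
  That world cannot exercise the GL′ arm: genes driven by an
  independent `z_int` have no systematic negative correlation with the
  lymphocyte score, so the top-negative panel is pure noise and the TI
  model has nothing to learn (observed: rho(TI score, z_int) ≈ 0).
  Real melanoma shows a strong negative TE–TI coupling (TI vs
  cytolytic index around −0.5), and `factor_corr = -0.5` plants it;
  the stratification and enrichment-recovery experiments in the
  acceptance suite run in that world.
- **What a green test does not establish.** The generator draws
  independent Gaussian noise per gene: no gene–gene correlation beyond
  the planted factors, no real gene symbols, no platform effects, no
  batch structure, no empirical TCGA covariance. Recovery of a planted
  one-dimensional factor is a much easier problem than resolving real
  immune-infiltrate heterogeneity; passing tests validate the
  machinery, not clinical performance.

## Acceptance experiments: design notes

- The planted-factor recovery experiment trains on a k = 250 panel
  screened from 2000 genes at n = 400 and requires the selected TE
  node to track `z_imm` (|Spearman| ≥ 0.8, median over 10 seeds).
  Observed values run ≈ 0.92–0.95; the ReLU bottleneck caps the
  attainable rank correlation slightly below 1 because samples in a
  node's dead region collapse to a tied zero score.
- The null-calibration experiment (no survival signal planted) checks
  the *per-node* dichotomized Cox test's type-I error at α = 0.05
  across 200 reduced-epoch pipeline runs × 20 nodes; selection of the
  minimum across 20 nodes is deliberately not corrected for, matching
  the exploratory scan.
- Enrichment recovery is only well-posed when the true set is a
  minority of the ranked list; the experiment therefore screens a
  k = 500 panel over a 150-gene immune block. With the negative
  factor coupling planted, the intrinsic block stays out of the
  top-positive panel and the TRUE_IMMUNE set ranks first in 10/10
  seeds.

## Known limitations

- Exact numeric reproduction of the reference node values is
  impossible by construction: the upstream training hyperparameters
  (λ, learning rate, epochs, batch size, initialization) are
  unreported and the trained weights were not released. The node
  index of each signature is therefore treated as data, re-derived per
  training run, rather than fixed constants.
- Briefly trained ReLU nodes can leave more than half the cohort at a
  tied zero score; after a protective sign flip the median then equals
  the maximum and the high group of a median split is empty. The
  survival functions raise a clear error in that case; remedies are
  longer training, `linear_bottleneck = TRUE`, or evaluating the
  continuous score with a Cox fit.
- Per-sample pathway activity beyond the mean z-score substitute
  (`pathway_activity()`) is out of scope, as are immune-cell abundance
  deconvolution, MAF parsing beyond non-silent counting, and any
  cohort downloading.
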