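# decompTME

Autoencoder decomposition of bulk tumor gene expression into
**tumor-extrinsic (TE)** and **tumor-intrinsic (TI)** prognostic
signatures, with gene-level attribution and full survival / response
evaluation. Built for transcriptomics researchers who want to separate
the immune-infiltrate signal from the tumor-cell program in a bulk
RNA-seq or microarray cohort and test whether either compartment
predicts outcome.

## The method

Given a gene × sample expression matrix and per-sample lymphocyte
infiltration scores (ordinal IHC grades):

1. **Normalize** — log2(x + 1), then z-score every gene across samples.
2. **Screen** — rank genes by Spearman correlation with the lymphocyte
   score; the top *k* positive genes form the immune panel GH′, the top
   *k* negative genes the tumor panel GL′ (*k* = 1000 in the reference
   setup).
3. **Compress** — train one symmetric autoencoder per panel
   (d → 400 → 100 → 20 mirrored, ReLU hidden layers, linear
   reconstruction output) by minimizing the regularized square loss

   L = Σᵢ ½‖xᵢ − D(E(xᵢ))‖² + λ‖w‖²

   with mini-batch SGD (momentum 0.9, gradient-norm clipping). The 20
   bottleneck nodes of each model are compressed expression features:
   F_H = E(GH′), F_L = E(GL′).
4. **Select** — dichotomize every node's score at the cohort median,
   fit a univariate Cox proportional-hazards model per node, and keep
   the node with the smallest Wald p per compartment: the TE signature
   (immune side, oriented so higher = lower hazard) and the TI
   signature (tumor side, higher = higher hazard).
5. **Score & attribute** — new cohorts are z-scored within themselves,
   aligned to the frozen panels and pushed through the trained
   encoders; the contribution of gene *i* to a node is the sum over
   all encoder paths of weight products,
   GW(i) = Σⱼₖ w¹ᵢⱼ · w²ⱼₖ · w³ₖ,node — the ranking input for
   pre-ranked GSEA.
6. **Evaluate** — Kaplan–Meier / log-rank, uni- and multivariate Cox,
   four-group TE×TI stratification, Harrell's C model comparison,
   responder Wilcoxon + ROC/AUC, and correlations against tumor
   mutation burden, CNV burden (Σ|log2(c/2)|·f / N) and the cytolytic
   (CYT) index √((GZMA+1)(PRF1+1)).

A built-in synthetic-cohort generator plants a latent immune factor and
a latent tumor-intrinsic factor (optionally negatively coupled, as
observed in melanoma) with survival, mutation, CNV and response data
wired to them, so the entire pipeline is testable without any external
downloads.

## Worked example

```r
library(decompTME)

co <- generate_cohort(simulation_config(
  n_samples = 300, n_genes = 1000, n_immune_genes = 150,
  n_intrinsic_genes = 150, factor_corr = -0.5, seed = 1))

bundle <- decompose_cohort(
  co$expression, co$lymph_scores, co$clinical, k = 150,
  config = training_config(epochs = 40, hidden = c(96, 48), seed = 1))

bundle$te$def$node_index              # which bottleneck node became TE
#> [1] 4
sc <- setNames(bundle$scores$te_score, bundle$scores$sample_id)
cor(sc, co$truth$z_imm, method = "spearman")  # recovers planted factor
#> [1] 0.9361351
km_logrank(dichotomize(sc), co$clinical)$p    # high vs low TE survival
#> [1] 4.751492e-16
head(rank_genes_for_gsea(bundle$te$gene_weights), 3)
#>     gene     weight rank
#> 1 G00111 0.05042691    1
#> 2 G00129 0.04818536    2
#> 3 G00047 0.04793225    3
```

The TE score tracks the planted immune factor (ρ ≈ 0.94), its median
split separates survival (log-rank p ≈ 5e-16 with the planted
protective log-hazard of −0.7), and the attribution ranking is
dominated by planted immune-block genes (`G00001`–`G00150`).

## Command line

```sh
Rscript -e 'decompTME::decomp_cli()' simulate --seed 1 --out-dir cohort/
Rscript -e 'decompTME::decomp_cli()' decompose \
    --expr cohort/expression.tsv --lymph-scores cohort/lymph_scores.tsv \
    --clinical cohort/clinical.tsv --k 250 --epochs 100 \
    --hidden 128,64 --out-dir run/
Rscript -e 'decompTME::decomp_cli()' score \
    --model run/model_bundle --expr cohort/expression.tsv --out scores.tsv
Rscript -e 'decompTME::decomp_cli()' survival \
    --scores scores.tsv --clinical cohort/clinical.tsv --out-dir run/
Rscript -e 'decompTME::decomp_cli()' gsea \
    --weights run/te_gene_weights.tsv --gmt cohort/gene_sets.gmt \
    --nperm 1000 --seed 7 --out gsea.tsv
```

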