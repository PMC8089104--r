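# scmodules

Single-cell RNA-seq analysis of lymphocyte populations from full-length
(Smart-seq2 style) data, built around a **power-free weighted gene
co-expression module analysis** with metadata-driven module prioritization.
The package targets studies of innate lymphoid cells (ILCs) and T cells
across tissues, where the questions are: which cell clusters exist, which
gene programs (modules) drive them, which metadata factor — tissue, donor,
cell subset — explains each program, and which cells carry T-cell receptor
V(D)J rearrangements.

## What it does

The pipeline runs, in order:

1. **QC and normalization** — TPM-scale values are converted to
   pseudo-counts (`value × read length`, rounded), cells are filtered on
   mitochondrial (> 40%), ribosomal (> 50%), protein-coding (< 50%) count
   fractions and detected genes (< 200); genes detected in fewer than five
   cells are dropped; counts are log-normalized
   (`ln(1 + count / total × 1000)`) and confounders (QC fractions, sex,
   cell-cycle scores) are regressed out per gene.
2. **Clustering** — highly variable genes, PCA (50 PCs), exact KNN graph
   (k = 10), shared-nearest-neighbor pruning (Jaccard ≥ 1/15), Louvain
   community detection (resolution 2.4).
3. **Differential expression** — a two-part hurdle test per gene: a
   detection G-test plus a Gaussian likelihood-ratio test on positive
   log-expression, combined as a chi-square statistic. Marker regime
   (log2FC > 0.25, FDR < 0.01) and permissive regime (|log2FC| > 0.1,
   p < 0.1) feed downstream steps.
4. **Gene modules** — on the permissive gene union: adjacency
   `a_ij = |cor(g_i, g_j)|` with **no soft-threshold power** (sparse
   single-cell correlations rarely approach 1, so a power would flatten
   the matrix), topological overlap

   ```
   TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),
   l_ij = Σ_u a_iu a_uj,  k_i = Σ_u a_iu
   ```

   Ward.D2 hierarchical clustering of `1 − TOM` cut into a fixed number of
   modules (default 100); per-cell module scores as the mean of min-max
   normalized member genes (in [0, 1]); a 5-NN correlation graph over
   modules.
5. **Module prioritization** — per (module, factor), a Gaussian GLM of the
   module score on the factor gives `Δdev = (dev_null − dev_model) /
   dev_null` (equal to R² in this family); modules are ranked by Δdev per
   factor, with ribosomal/mitochondrial "housekeeping" modules flagged out
   of the ranking.
6. **TCR rearrangements** — clone tables are filtered to count > 5, reduced
   to the dominant clone per (cell, chain), and each cell is classified as
   `none`, `TRA_B`, `TRG_D` or `TRA_B_G_D`; clone-frequency and
   clonal-overlap summaries follow.
7. **Cross-dataset comparison** — hypergeometric tests of per-cluster DEG
   overlap over a shared "expressed in ≥ 5 cells in both datasets"
   background, and Spearman correlation of cluster mean expression over the
   union of top-100 DEGs.

A synthetic-data generator (`generate_expression`, `generate_clone_table`,
`generate_qc_fixture`) plants co-expression modules tied to metadata
factors, subset-specific DE genes, QC violations and rearrangement
categories with known ground truth, so every stage is testable at desk
scale without any download.

## Worked example

```r
library(scmodules)

# simulate a small multi-tissue cohort with 6 planted co-expression modules
cfg <- synthetic_config(n_cells = 300, n_genes = 400,
                        planted_modules = make_planted_modules(6, 20, effect = 2),
                        seed = 101)
ds <- generate_expression(cfg)

res <- run_pipeline(
  pipeline_config(output_dir = "demo_out", tpm_scale = FALSE,
                  n_hvg = 300, n_pcs = 20, resolution = 1.0,
                  n_modules = 25, seed = 101,
                  qc = qc_thresholds(min_n_genes = 100)),
  data = list(counts = ds$counts, annotation = ds$annotation,
              metadata = ds$metadata))

table(res$clusters)
#>   0   1   2   3   4
#> 100  54  53  47  46

head(res$priority[res$priority$factor == "tissue", ], 3)
#>   module_id factor dev_null dev_model delta_dev housekeeping_flag rank
#> 3  module_3 tissue 14.73649  1.322773 0.9102382             FALSE    1
#> 5  module_5 tissue 15.03000  1.372219 0.9087014             FALSE    2
#> 9  module_9 tissue  2.27540  2.033657 0.1062420             FALSE    3
```

The clustering recovers the planted populations, and the two modules driven
by tissue identity in the simulation rank first and second for the tissue
factor with Δdev ≈ 0.91 — the tissue factor explains ~91% of their score
variance — while the next module explains almost nothing. Stage artifacts
(QC table, cluster labels, DE table, module assignment/scores, priority
table, run manifest) are written to `demo_out/`.

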