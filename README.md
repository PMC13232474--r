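# chromsig

Chromatin-derived subtype signatures and tumor-microenvironment analytics
for high-grade T1 (HGT1) bladder cancer.

HGT1 non-muscle-invasive bladder cancer splits at the chromatin level into
a luminal-like inflammatory (**LLI**) and a basal-like (**BL**) state
within conventional urothelial histology, plus a distinct micropapillary
(**MP**) state. `chromsig` implements the computational pipeline around
these subtypes for analysts working with H3K27ac ChIP-seq, RNA-seq,
scATAC-seq, IHC images and spatial cell tables:

* **Differential chromatin analysis** — library-size (size-factor)
  normalization, Spearman-correlation hierarchical clustering, PERMANOVA
  cluster validation (pseudo-*F* with seeded permutations), PCA, and a
  negative-binomial Wald test with the `padj ≤ 0.05`, `|log2FC| > 0.5`
  selection rule. The NB model is mean `μ = s_j·q_g·2^β`, variance
  `μ + φμ²`, with method-of-moments dispersion pooled across groups.
* **CDS derivation** — the Chromatin-Derived Score signatures: peaks are
  linked to the nearest TSS within 400 kb; candidate genes need
  `|log2FC| > 5` (LLI/BL) or `> 2` (MP) with `padj < 0.05` *and* a linked
  subtype-specific differential peak; the top 15 per subtype by
  fold-change magnitude form disjoint signatures, with a 5–25 size scan.
* **Scoring & classification** — a rank-walk single-sample enrichment
  score (weight `r^α`, α = 0.25, ideal-rank normalization) and a
  binned-control module score; bulk quartile and sign rules on
  `Δ = score_LLI − score_BL`; the single-cell quantile rule; marker-based
  CAF typing (FN1/C3/CD74/SLC14A1/PSCA) and M1/M2 polarization ratios.
* **CNV from scATAC** — off-target fragments binned at 1 Mb with
  effective-window correction; per-bin background as the mean density of
  the 100 GC-matched bins; `F_b = log2((c_b+ε)/(B_b+ε))`.
* **IHC image analysis** — moment-preserving (Tsai) thresholding of the
  stain channel, removal of blue-dominated (hematoxylin) pixels, exact
  Euclidean pixel-to-vessel distances, rank-sum comparison of marker
  distance distributions, H-scores (`3·%strong + 2·%moderate + %weak`).
* **Spatial & cohort statistics** — radial co-occurrence curves around
  anchor cells; contingency tables and chi-square tests; Kaplan–Meier
  curves and log-rank tests.
* **Synthetic cohorts with planted ground truth** — `sim_config()` plus
  `simulate_*()` generators for every input above, so the whole pipeline
  is testable end to end without external data.

## Worked example

Derive CDS signatures from a synthetic cohort, score and classify the
samples, validate the cluster structure, and call CNVs:

```r
library(chromsig)

cfg <- sim_config(seed = 42)          # 6 samples/subtype, planted lfc = 6
sim <- simulate_bulk_cohort(cfg)

sigs <- derive_cds(sim$peaks, sim$expr, sim$annotation,
                   sim$truth$subtype_of_sample)
sigs$LLI
#> <signature> LLI - 15 genes
head(sigs$LLI$table, 3)
#>     gene_id   log2fc         padj    peak_id
#> 1 gene_0365 6.544175  0.00000e+00 peak_00001
#> 2 gene_1128 6.460318 2.96878e-199 peak_00002
#> 3 gene_0629 6.395939  0.00000e+00 peak_00008

st <- score_table(normalize_counts(sim$expr, log2 = TRUE), sigs)
head(st[, c("unit_id", "score_LLI", "score_BL", "delta")], 3)
#>   unit_id score_LLI score_BL delta
#> 1  LLI_01     0.497   0.0372 0.459
#> 2  LLI_02     0.496   0.0570 0.439
#> 3  LLI_03     0.497   0.0185 0.478
table(classify_bulk_quartile(st))
#>           BL intermediate     LLI-like
#>            5            8            5

cl <- correlation_clustering(normalize_counts(sim$peaks, log2 = TRUE), k = 3)
permanova(cl$D, sim$truth$subtype_of_sample[colnames(cl$D)],
          n_perm = 999, seed = 1)
#> PERMANOVA F = 10.72, p = 0.001

fr <- simulate_fragments(cfg)
cnv <- call_cnv(fr$fragments, fr$bins, fr$peaks, k = 100)
#> planted gain (ratio 2):  median log2FC  0.96
#> planted loss (ratio 0.5): median log2FC -1.11
```

The 15 signature genes per subtype are exactly the planted ones; the
enrichment scores separate the subtypes cleanly (every LLI sample scores
~0.50 on its own signature against ~0.04 for BL), the quartile rule labels
the expected extremes at N = 18, PERMANOVA rejects exchangeability at the
smallest attainable p (0.001 at 999 permutations), and the planted copy
ratios {2, 0.5} come back as median log2 fold changes within 0.15 of ±1.

See `vignettes/chromatin-subtypes.Rmd` for the models, parameter
conventions and design decisions, and the documentation of the individual
functions for the remaining modules (IHC: `detect_marker_pixels()`,
`distance_to_vessel()`, `h_score()`; spatial: `co_occurrence()`;
survival: `km_estimate()`, `logrank_test()`).

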