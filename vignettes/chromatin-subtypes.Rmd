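---
title: "Chromatin-derived subtypes of HGT1 bladder cancer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-derived subtypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

High-grade T1 (HGT1) bladder cancer splits, at the chromatin level, into a
luminal-like inflammatory (LLI) and a basal-like (BL) state within
conventional urothelial (URO) histology, plus a distinct micropapillary (MP)
state. `chromsig` implements the computational machinery for working with
these subtypes: deriving chromatin-derived score (CDS) gene signatures from
H3K27ac enhancer profiles combined with expression, scoring and classifying
bulk samples and single cells, validating cluster structure, inferring copy
number from off-target scATAC fragments, measuring marker-to-vessel
distances in IHC images, and quantifying spatial co-occurrence — together
with a synthetic-data generator that plants known ground truth so every
stage can be validated end to end.

This vignette records the models, the tunable parameters, and the design
choices made where more than one reasonable implementation existed.

## The differential model

Peak-by-sample counts are treated as negative binomial with mean
$\mu_{gj} = s_j q_g 2^{\beta_g z_j}$ and variance $\mu + \phi\mu^2$, where
$s_j$ is a sample size factor, $q_g$ a peak intensity, and $\beta_g$ the
log2 fold change active in samples $j$ of the peak's subtype. Size factors
are total counts divided by their geometric mean, matching a
sequencing-depth normalization. The test `nb_differential()`:

* estimates $\phi$ per feature by method of moments on normalized counts,
  pooled across the two groups with degree-of-freedom weights and floored
  at $10^{-8}$ — no shrinkage, because the test is validated by type-I and
  power simulation rather than by equivalence to any external package;
* uses $\log_2\!\frac{\bar x_A + 0.5}{\bar x_B + 0.5}$ (the pseudocount
  bounds the fold change when a group mean is zero);
* forms a Wald statistic with a delta-method standard error from the NB
  variance, two-sided normal $p$, and Benjamini–Hochberg adjustment over
  all tested features.

Differential feature sets use an inclusive adjusted-$p$ cutoff
(`padj <= 0.05`) and a strict fold-change cutoff (`|log2fc| > 0.5`);
a feature sitting exactly on the fold-change boundary is excluded, one
exactly at the adjusted-$p$ boundary is kept. Under a complete null
(200 matrices of 2000 NB features, 6 vs 6), the fraction of features with
`padj <= 0.05` is about 0.004; a planted fold change of 6 at $\phi = 0.05$
is recovered within $\pm 0.5$ for 97–99% of features.

Cluster separation is tested with a one-way PERMANOVA on the
$1 - \rho_\text{Spearman}$ distance matrix: pseudo-$F$ from total and
within-group sums of squared distances, $p$ from seeded free label
permutations as $(1 + \#\{F_\pi \ge F\})/(n_\pi + 1)$, with an exhaustive
enumeration mode for small $n$. Average linkage is used for the
hierarchical tree (no linkage is canonical for correlation distances;
average is the common choice) and Spearman ties take average ranks.

## CDS signature derivation

Derivation integrates three pieces of evidence per candidate gene: a
subtype-specific differential peak, a matching differential expression
call, and physical proximity. Peaks are linked to the gene with the
nearest TSS within 400 kb of the peak midpoint (inclusive; equidistant
ties break to the lexicographically smaller gene id). Candidates must be
up in their subtype with `|log2fc| > 5` for LLI/BL or `> 2` for MP (the MP
contrast is gentler), `padj < 0.05` (strict here), and at least one linked
subtype-specific peak; the top 15 by fold-change magnitude form the
signature. LLI and BL derive from the direct LLI-vs-BL contrast; MP
derives against the pooled URO samples. Signatures are forced to be
disjoint — a gene claimed twice stays where its fold change is largest,
and the loser records the conflict.

The signature-size scan re-scores the cohort at sizes 5–25 and picks the
accuracy-maximizing size, breaking ties toward the smallest signature.
Because the single-sample score of one sample does not depend on the other
samples, leave-one-out accuracy coincides with plain accuracy, so the scan
computes the latter directly.

## Scoring and classification

`ss_enrichment_score()` is a rank-walk single-sample statistic: genes are
ranked by expression (descending, ties by gene id); walking down the list,
set members add a rank weight $r^\alpha$ ($r = N$ at the top) and
non-members subtract $1/(N - k)$; the score integrates the running sum
over all positions and scales by $1/N$. Member weights are normalized by
the *ideal* member weight sum — the weight the set would carry if it
occupied the top $k$ ranks — rather than by the realized member weights.
The realized normalization is not monotone: improving a weak member's rank
inflates its weight share at the expense of the top member, which can
lower the integral. With the ideal normalization the score is strictly
monotone under any rank improvement of a member, the all-genes degenerate
case is unchanged, and scores are comparable across samples. $\alpha$
defaults to 0.25.

`module_score()` reimplements the binned-control idea: genes are placed in
25 equal-frequency bins of average expression; each signature gene draws
100 seeded controls (with replacement) from the non-signature genes of its
bin, falling back to the nearest non-empty bin; the per-cell score is the
signature mean minus the pooled-control mean.

Classification rules are implemented exactly as stated decision rules on
top of these scores:

* bulk quartile rule — rank by $\Delta = \text{LLI} - \text{BL}$; top
  $\lceil N/4\rceil$ are `LLI-like`, bottom $\lceil N/4\rceil$ are `BL`,
  the rest `intermediate`; rank ties break by unit id so the labelling is
  deterministic;
* bulk sign rule — $\Delta > 0$ `LLI-like`, $\Delta < 0$ `BL-like`; both
  quoted inequalities are strict, so $\Delta = 0$ is `intermediate`;
* single-cell quantile rule — per subtype, a threshold at the $q$-th
  quantile (type 7) of that subtype's scores; a cell is labelled iff it
  meets exactly one subtype's threshold, otherwise `unidentified`. The
  level is read as $q = 0.75$, mirroring the bulk top-quartile usage; the
  exact level is a free parameter of the rule.

TME typing assigns each cell the CAF subtype whose canonical marker (FN1,
C3, CD74, SLC14A1, PSCA) has the highest z-scored expression, with
all-zero marker profiles and ties left unassigned; M1/M2 polarization is a
pair of module scores over the standard marker sets with a per-sample
$\#(M2>M1)/\#(M1>M2)$ ratio, flagged rather than divided when the
denominator is zero.

## CNV from off-target scATAC fragments

The genome is tiled into 1 Mb half-open bins (terminal partial bins keep
their true length). Fragments whose midpoint falls in an accessibility
peak are on-target and discarded; the rest are assigned to the bin
containing their midpoint (boundary midpoints go to the right-hand bin).
Coverage density divides counts by the *effective window* — bin length
minus peak-covered bases — and bins with less than 10% effective length,
or missing GC, are masked. Each bin's background is the mean density of
the 100 unmasked bins closest in GC fraction (ties by genomic order), the
focal bin excluded to avoid self-matching; the per-bin signal is
$F_b = \log_2\frac{c_b + \varepsilon}{B_b + \varepsilon}$ with
$\varepsilon$ = 1 fragment per effective Mb keeping sparse per-cell ratios
finite.

Two sizing notes matter. First, GC-matched backgrounds only remove bias if
the matched set is much smaller than the genome: with $k = 100$ drawn from
~180 bins the background would cover most of the genome and any sizeable
planted segment would contaminate its own background by
$\log_2(1 + 15/180) \approx 0.12$. The default synthetic genome therefore
uses three 200 Mb chromosomes (600 bins), keeping that contamination near
0.04 while leaving chromosome sizes configurable. Second, at realistic
per-cell sparsity (~500 fragments per cell) per-cell bin densities are of
the same order as $\varepsilon$, so per-cell $F$ is shrunk toward zero by
construction; per-cell mode preserves the gain/neutral/loss ordering with
higher variance, and quantitative recovery is a pseudobulk statement.

## IHC image pipeline

Images are converted to a stain-oriented grayscale,
$255 - \text{mean}(R,G,B)$, so dark stain is high-valued, then thresholded
by moment preservation (Tsai): the two-level image preserving the first
three histogram moments fixes a background fraction $p_0$, and the split
point is the 256-bin gray level whose cumulative fraction is closest to
$p_0$ (ties to the lower level; pixels at or above split + 1 are
foreground). Hematoxylin-stained nuclei are removed by the strict
blue-greater-than-red filter (ties retained, idempotent). Distances from
each marker pixel to the nearest vessel pixel are exact center-to-center
Euclidean distances — computed with a distance transform and verified
against a brute-force scan — scaled by pixel size. Distance distributions
are compared two-sided by rank sum: exact enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments when both sides have at most 8 pixels
pooled per group (average ranks under ties), otherwise the tie-corrected
normal approximation with continuity correction, which agrees with the
exact path to within about 0.01 at $n = 8$ vs 8. H-scores are
$3\cdot\%\text{strong} + 2\cdot\%\text{moderate} + \%\text{weak}$.
Vessel outlines are an input mask; no vessel segmentation is attempted.
Distances are pooled per image; per-tumor aggregation is the caller's
responsibility.

## Spatial co-occurrence and cohort statistics

The co-occurrence curve conditions on annuli around anchor cells: for each
annulus, every non-anchor point within that annulus of at least one anchor
is pooled once (presence semantics — the conditional-probability reading;
a pair-counting mode is available by flag), and the frequency of the
target category among pooled points is divided by its global frequency
among non-anchor points. Default radii are 10 log-spaced edges up to the
90th percentile of anchor-to-point distances. Empty annuli are flagged,
never interpolated. Units are whatever the coordinates are in.

Associations use Pearson chi-square without continuity correction (zero
expected cells raise an error suggesting collapsing categories); survival
uses the Kaplan–Meier estimator and the log-rank test with events
processed before censorings at tied times. Cox regression is out of scope.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions: 6 samples per subtype
(LLI/BL/MP), 2000 peaks, 1200 genes, 60 planted differential peaks per
subtype each placed within 10 kb of one of 15 planted signature genes,
planted log2 fold change 6, NB dispersion 0.05, totals drawn from
150k–300k. Eight decoy genes per subtype carry the expression fold change
without any nearby differential peak — derivation must reject them. Gene
TSS sit on a jittered grid (~150 kb spacing), so a planted peak's nearest
TSS is always its own gene. Single-cell mixtures add the five CAF
subtypes, M1/M2 macrophages and an unstructured population (200
cells/type, Poisson counts, 16-fold marker boost); technical dropout is
mean-dependent ($p = \text{rate}\cdot e^{-0.1\mu}$, rate 0.3) because in
real droplet data highly expressed canonical markers are essentially never
lost — uniform dropout would make single-marker typing fail by
construction, which is a statement about the generator, not the tissue.
Fragment sets plant a 30-bin gain (ratio 2) and a 30-bin loss (ratio 0.5)
with Beta(20, 20) per-bin GC and a configurable polynomial GC bias; IHC
images place DAB-colored blobs of one marker within 30 px of a vessel band
and the other beyond 90 px, over hematoxylin nuclei and Gaussian noise
(sigma 8) on a light background; spatial tables plant one category
attracted within 20 px of anchors (300 points per category in a 1000 px
field — chosen so anchors cover ~30% of the field and the planted
co-occurrence ratio is ~2, comfortably distinguishable from 1); survival
times are exponential with an LLI:BL hazard ratio of 3 and uniform
censoring. All streams derive from one seed, so every output is
byte-identical across reruns.

None of this is an estimate of the real cohorts. The generator has no
batch effects, no GC dependence in ChIP efficiency, no doublets or
ambient RNA, spherical marker blobs instead of tissue morphology, and
planted effects far cleaner than biology provides. Passing tests
demonstrate that the implementations recover what was planted under the
stated models — not that the models capture FFPE chromatin data.

## Problem sizes and numerical choices

The test suite and the acceptance script run, per invocation: 20 bulk
cohorts for derivation/classification; 200 null matrices of 2000 features
for test calibration; 400 PERMANOVA simulations at 199 permutations plus a
720-permutation exhaustive check; two fragment simulations of ~125k
fragments over 600 bins; 50 brute-force distance-transform comparisons on
64x64 masks; 400 null and 100 powered log-rank simulations. These sizes
keep every Monte-Carlo estimate's standard error well inside the margin it
is checked against while completing in a few minutes on one CPU.

Tie-breaks are deterministic everywhere (gene id in ranking, unit id in
quartiles, genomic order in GC matching, lower gray level in
thresholding); dispersion floors at $10^{-8}$; all-zero features report
$p = 1$ and fold change 0 rather than NA; degenerate inputs (constant
images, empty vessel masks, all-censored survival, all-zero distance
matrices) raise errors naming the problem instead of propagating NaN.

## Known limitations

The NB test has no covariates and no dispersion shrinkage — adequate for
planted-effect validation, less powerful than shrinkage estimators at
small $n$ on real data. The CDS size scan reports resubstitution-equal
accuracy, which is optimistic if scoring ever becomes cohort-dependent.
The CNV caller does not segment or smooth $F_b$ and reports bin-level
signal only; per-cell output is shrunk by $\varepsilon$ as described.
The IHC pipeline assumes the stain/counterstain color conventions stated
above and manual vessel outlines. Spatial co-occurrence treats points as
exchangeable within categories and ignores tissue boundaries.
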