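---
title: "Inferring CNV subclones from windowed mean expression: models and design choices"
author: "wmeclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring CNV subclones from windowed mean expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmeclone)
```

## The problem

Leptomeningeal disease (LMD) — tumor infiltration of the cerebrospinal
fluid (CSF) — can be sampled longitudinally by lumbar puncture during
immune checkpoint inhibitor (ICI) treatment. Each CSF sample yields a
single-cell RNA-seq UMI matrix containing a mixture of malignant cells and
immune cells, and a matched cell-free DNA (cfDNA) sample from which
whole-exome sequencing gives gene-level total copy ratios (tCR; germline
reference = 1) together with an estimate of tumor purity.

`wmeclone` implements the analysis machinery such a study needs:

1. copy-number structure inferred from expression via trimmed windowed
   means (uWME / WME / rWME);
2. subclone discovery by agglomerative clustering of a Kendall-tau
   distance, and tracking of subclone fractions over treatment time;
3. an orthogonal DNA-side check: purity-corrected cfDNA copy ratios and
   per-cell expression/copy-ratio concordance shifts between time points;
4. bin-matched background-subtracted gene-signature scores (IFN-γ
   response, antigen presentation, ...);
5. the longitudinal statistical layer: treatment-phase grouping, Wilcoxon
   rank-sum tests, two Cohen's *d* variants, Kendall tests, Bonferroni
   adjustment, and cell-count-based sample inclusion rules.

Because the patient-level data such a study rests on are restricted-access,
the package ships a first-class synthetic cohort generator that emulates
the study design and provides ground truth for every stage.

## Preprocessing

Barcodes are retained when they detect at least 400 genes (complexity) and
have a mean `log2(1 + TP10k)` over a curated housekeeping list of at least
1.6; peripheral-blood (PBL) data use a 200-gene complexity cutoff. Genes
are then retained if detected in at least 1% of the remaining barcodes
(0.0875% for the windowed-CNV input, which benefits from a denser gene
grid). Counts are normalized to 10,000 UMIs per cell (TP10k) and
log2-transformed with a pseudocount of 1.

Two conventions are worth making explicit:

* **Housekeeping score offset.** The cutoff is quoted on a log2(tp10k)
  scale; we compute `log2(1 + TP10k)` because zeros must be representable.
  The convention is recorded in the configuration so the cutoff semantics
  are never ambiguous.
* **Downsampling.** For CSF-vs-PBL comparisons every cell is adjusted to
  500 total UMIs by drawing without replacement from its observed UMI pool
  (a multivariate hypergeometric draw). Sampling without replacement is
  the physically faithful reading of "randomly selecting 500 UMIs";
  multinomial resampling would inflate variance slightly. Cells already at
  or below the target are kept unchanged and flagged, since 500 is an
  approximate mean depth rather than a hard floor.

## Windowed mean expression

Genes are ordered along the genome by a 1-based rank within each
chromosome; base-pair coordinates are never needed. Genes in the uppermost
decile of dropout rate and all immunoglobulin genes are excluded (IG
expression tracks B-cell state, not dosage). All stride-1 runs of 200
consecutive eligible genes on one chromosome form windows — consecutiveness
is defined on the *post-exclusion* ordering so every window has exactly 200
usable genes and the trimmed mean always has the same denominator.

For each cell and window, the **uWME** is the mean TP10k over member genes
after dropping the 5 largest values; trimming stops one highly expressed
gene from masquerading as an amplification. Exactly 5 values are dropped
even under ties (the trimmed sum is unaffected by which of several equal
values are dropped, so the statistic is reproducible). Only high-complexity
(> 1000 detected genes) tumor cells are profiled.

The non-malignant **reference** is a two-stage mean: cells are averaged
within each patient, then patients are averaged, so a patient's cell count
never weights the reference. Windows containing HLA/6p genes show strong
hematopoietic expression unrelated to tumor copy number; their reference
(and any zero reference) is imputed with the mean over all other windows of
the cross-patient means — the averaging order is windows-of-patient-means,
as the two-stage construction implies. **WME** is the per-window quotient
uWME / reference: 1 is the neutral copy state, and a clone carrying a
copy-number *c* segment shows WME ≈ *c*/2 over it. **rWME** replaces each
cell's WME profile by within-cell ranks (average ties), removing per-cell
scale before embedding and damping batch structure.

One reading we fixed deliberately: the top-5 trim operates per cell within
each window (the natural reading of a per-cell windowed profile), not on
window statistics across cells.

## Subclone discovery

The cell–cell distance is `1 − τ_K`, the tie-corrected Kendall correlation
(tau-b) between the *WME* profiles of two cells — ties are common in WME,
so the tie-corrected variant is the right default. Agglomeration uses
weighted linkage (WPGMA, `hclust(method = "mcquitty")`), and the dendrogram
is cut at a fixed cluster count (default k = 4; at that setting outlier
cells typically form singleton clusters, which are flagged and excluded
from clone-role assignment). The distance is computed on WME and the
PCA/UMAP embedding on rWME — the two representations serve different
purposes and we kept that separation rather than unifying them. The
embedding is visualization only; labels never derive from it.

Clone roles are assigned automatically from per-sample malignant-cell
fractions: with exactly two non-singleton clusters, the one whose fraction
rises from the first to the last time point is *ascendant*, the other
*descendant*; ties or more than two major clusters leave roles unassigned
with a warning rather than guessing.

The Kendall kernel is implemented in C++ (merge-sort inversion counting,
O(w log w) per pair, with per-cell presorted orders shared across pairs);
unit tests pin it exactly to an O(w²) pair-enumeration oracle and to
`stats::cor(method = "kendall")`.

## cfDNA concordance

Observed cfDNA copy ratios mix tumor and germline signal. With purity *p*
and germline ratio 1,

  tCR_corrected = (tCR_observed − (1 − p)) / p,

which is the exact inverse of the generator's mixture model; corrected
values below zero (possible under noise) are flagged, never clipped, so
the map stays affine. Because Kendall correlation is rank-based and the
correction is increasing-affine, per-cell expression/copy-ratio
correlations are identical for observed and corrected ratios.

For each cell we compute τ between its log-normalized expression and the
gene-matched copy ratios of an early and a late cfDNA profile; the shift
`Δ = τ_late − τ_early` points each cell toward the copy-number profile it
resembles more. Within a sample, the Theil–Sen slope (median of pairwise
slopes, undefined pairs excluded) of IFN-γ response score against Δ
quantifies the anti-correlation between inflammation and alignment with the
later, resistant profile. At the window level, the change in cluster-mean
WME per gene (genes mapped to the mean of the windows containing them) is
compared with the change in corrected tCR by Kendall correlation.

## Module scores

A signature score is the mean log-normalized expression of the set genes
minus a background: genes are binned (25 bins) by average expression over
the scored cells, and for each set gene 100 controls are sampled from its
bin, excluding set genes (including them would bias scores toward zero).
Bins smaller than the control count are used exhaustively with a warning.
Scores are recomputed whenever the cell subset changes, because the bins
are subset-relative — re-scoring after partitioning is part of the
contract, not an accident. The IFN-γ response and antigen presentation
signatures overlap; the overlap is removed from both before scoring.

## Statistics

Samples map to phases by days since first dose: ≤ 0 is pre-treatment
(day 0 is sampled before administration), < 30 early post, ≥ 30 late post.
Group comparisons aggregate per-cell values to per-sample means after
excluding samples with too few contributing cells (strict ">", defaults 20
T cells / 10 CD8 cells / 5 cells for module-score means; figure-legend
values — the alternative "at least 15" reading is available via
configuration rather than silently chosen). Tests are Wilcoxon rank-sum
(exact for small untied samples), effect sizes Cohen's *d* with a pooled
standard deviation or, for the paired variant *d*_pair, the pre-treatment
group's standard deviation; multiplicity uses Bonferroni. The sample-level
unit of analysis avoids pseudo-replication; cell-level comparisons remain
available where group sizes are quoted in cells.

## The synthetic cohort generator

The generator defines the study conditions the tests run under:

* 2,000 genes on 4 chromosomes (desk scale; acceptance analyses that need
  the study's windowing resolution use 8,000, the scale of the study's
  retained gene set), with contiguous immunoglobulin and HLA-flagged
  blocks so the exclusion and imputation rules are exercised by
  construction;
* per-gene baseline weights from a long-tailed log-normal
  (meanlog 0, sdlog 1.25); counts from a gamma–Poisson (negative binomial,
  size 2) given a per-cell log-normal library size — the standard UMI
  noise model, which produces realistic dropout without a separate
  zero-inflation term;
* library sizes of ~2,000 UMIs for immune cells and ~8,000 for malignant
  cells (tumor cells carry far more RNA; the CNV stack is restricted to
  complexity > 1000 cells, which this reproduces);
* two CNV clones given as segment lists (germline copy 2 elsewhere); a
  malignant cell's expected expression is baseline × copy/2, times a
  clone-and-time IFN-γ fold-change on a designated gene program
  (descendant clone responding strongly, ascendant weakly — the
  adaptive-selection signature);
* three time points (days 0, 21, 42) with clone mixing 0.9/0.1, 0.5/0.5,
  0.2/0.8; clone labels are allocated by largest-remainder rounding of the
  configured fractions (stratified allocation) so that configured and
  realized fractions agree to within one cell — fraction-recovery checks
  then measure clustering error, not label-sampling noise;
* matched cfDNA: true tumor tCR per gene is the fraction-weighted mean of
  clone copies over 2; the observed ratio is purity-mixed with germline 1
  plus Gaussian noise (sd 0.05), clipped at zero. Purities (0.55, 0.30,
  0.65) dip at response and rise at progression.

What the generator deliberately does **not** emulate: transcriptome-wide
co-expression structure, doublets, batch effects, and cell-type-specific
dispersion. Passing tests therefore demonstrate correctness of the
machinery under a faithful noise model, not performance guarantees on real
tissue.

## Numerical and degenerate-input choices

* Quantile for the dropout decile uses R's default (type 7) definition.
* A constant cell profile has undefined τ; its distances are set to 1
  (the uncorrelated value) with a warning rather than erroring out.
* Degenerate Theil–Sen pairs (duplicated x) are excluded; the estimator
  errors only when every pair is degenerate.
* Zero-variance references, empty gene sets after filtering, purity
  outside (0, 1], and missing metadata columns are hard errors naming the
  offending object.
* Every stochastic step (generator, downsampling, control sampling, UMAP)
  takes an explicit seed; a serialized configuration plus master seed
  reproduces a run byte-identically.

## Problem sizes used by the shipped checks

The test suite exercises toy fixtures (≤ 30 genes, ≤ 10 cells) against
brute-force oracles, desk-scale cohorts (300–2,000 genes, tens to hundreds
of cells) for behavioral properties, one study-scale cohort (8,000 genes,
600 malignant cells over three time points) for subclone recovery and
concordance direction, and 200 Monte-Carlo repeats of effect-free cohorts
(250 genes, 18 samples) for null calibration of the phase and compartment
tests. These sizes are the package's chosen verification conditions; the
functions themselves scale with the input.

## Known limitations

* Windowed means resolve dosage only down to ~window-size gene blocks;
  focal events smaller than a window are smeared, and window overlap makes
  neighboring windows strongly dependent (rank-based statistics on windows
  are therefore used descriptively, with significance only at the gene
  level).
* The reference assumes non-malignant expression is comparable across
  patients after TP10k; strong compartment- or treatment-driven shifts in
  immune composition propagate into WME as apparent dosage.
* Clone-role labeling compares first and last time points only;
  non-monotone trajectories are reported but not modeled.
* With two highly unbalanced clones, or clones whose CNV profiles are
  nested (one clone a strict subset of the other's events), the 1 − τ
  distance can leave the low-structure clone internally incoherent; the
  clustering then needs k above 2 and singleton screening, as in the
  packaged defaults.
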