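# wmeclone

Inferred copy-number subclone tracking from windowed mean expression, with
cfDNA concordance, for longitudinal single-cell cohorts.

## What problem this solves

In leptomeningeal disease (LMD), tumor cells infiltrate the cerebrospinal
fluid (CSF) and can be sampled repeatedly by lumbar puncture during immune
checkpoint inhibitor (ICI) treatment. Each sample yields a single-cell
RNA-seq UMI matrix (malignant plus immune cells) and, from the same fluid,
cell-free DNA whose whole-exome sequencing gives gene-level total copy
ratios (tCR) and a tumor-purity estimate. `wmeclone` is for analysts of
such cohorts who want to ask: *are there genetically distinct tumor
subclones, do their proportions shift under treatment, and does the shift
track an orthogonal DNA readout and an inflammation phenotype?*

## The method at its core

**Windowed mean expression (WME).** Genes are ordered along the genome and
grouped into all stride-1 windows of 200 consecutive eligible genes per
chromosome (genes in the top dropout decile and immunoglobulin genes are
excluded). For each high-complexity (> 1000 genes) tumor cell, the
unnormalized uWME of a window is the mean TP10k over member genes after
dropping the 5 largest values. A non-malignant reference per window is the
patient-balanced mean of immune-cell uWME (HLA/6p windows imputed with the
mean of the remaining windows), and

&nbsp;&nbsp;&nbsp;&nbsp;WME = uWME / reference,&nbsp;&nbsp;&nbsp;
rWME = within-cell ranks of WME,

so a clone carrying a copy-number *c* segment has WME ≈ *c*/2 over it.

**Subclones.** Cells are clustered by weighted-linkage (WPGMA)
agglomeration of the distance 1 − τ_K, where τ_K is the tie-corrected
Kendall correlation between two cells' WME profiles; the tree is cut at a
fixed k (default 4; singleton clusters flag outlier cells). The cluster
whose malignant-cell fraction rises from first to last time point is the
*ascendant* subclone, the other the *descendant*.

**cfDNA concordance.** Observed copy ratios are purity-corrected by
tCR_corr = (tCR_obs − (1 − p)) / p (germline = 1). Each cell's Kendall
correlation between expression and gene-matched tCR is computed against an
early and a late profile; Δτ = τ_late − τ_early points the cell toward the
copy-number profile it resembles. Theil–Sen slopes of IFN-γ module score
against Δτ quantify the inflammation/resistance anti-correlation.

**Module scores and statistics.** Gene-signature scores subtract a
bin-matched random-control background (25 expression bins, 100 controls per
set gene). The statistical layer provides treatment-phase grouping
(pre / < 30 d / ≥ 30 d), Wilcoxon rank-sum tests, Cohen's *d* (pooled and
reference-sd variants), Kendall tests, Bonferroni adjustment,
cell-count-based sample inclusion, and a depth-equalized (500-UMI
downsampled) CSF-vs-PBL comparison harness.

Because the cohorts this machinery targets are restricted-access, the
package includes a seeded synthetic cohort generator — negative-binomial
UMI counts, implanted CNV clones with shifting mixing fractions,
clone-specific IFN-γ response, matched purity-mixed cfDNA — that provides
ground truth for every stage.

## Worked example

```r
library(wmeclone)

sim <- simulate_cohort(sim_config(seed = 7))
sim$counts
#> <count_matrix> 2000 genes x 900 cells, 1009923 nonzero entries

fb <- filter_barcodes(sim$counts, sim$truth$signatures$housekeeping)
wme_in <- filter_genes(fb$counts, 0.000875)
st <- compute_wme_stack(wme_in, sim$annotation, sim$metadata)
st$window_set
#> <window_set> 958 windows of 200 genes (stride 1)

d <- kendall_distance_matrix(st$wme)
asg <- label_clones(cluster_wpgma(d, k = 2), sim$metadata)
asg
#> <subclone_assignment> 595 cells in 2 clusters (sizes: 316, 279)
#>   roles: descendant, ascendant

print(asg$fractions[, c("sample_id", "days_since_first_dose",
                        "cluster", "n_cells", "fraction")], digits = 3)
#>   sample_id days_since_first_dose cluster n_cells fraction
#> 1     P1-T1                     0       1     177    0.898
#> 2     P1-T1                     0       2      20    0.102
#> 3     P1-T2                    21       1     100    0.503
#> 4     P1-T2                    21       2      99    0.497
#> 5     P1-T3                    42       1      39    0.196
#> 6     P1-T3                    42       2     160    0.804
```

The generator implanted two clones mixed 0.9/0.1 → 0.5/0.5 → 0.2/0.8
across the three samples; the recovered fractions (0.898/0.102,
0.503/0.497, 0.196/0.804) match to within a few cells, and the rising
cluster is labeled ascendant. The full orchestration — preprocessing,
windowed CNV, subclones, cfDNA concordance, signature scores, statistics,
with TSV/JSON artifacts and a manifest — is available as
`run_pipeline(pipeline_config(seed = 7), outdir = "runs/demo")`, or from
the shell via `Rscript inst/scripts/run-pipeline.R --outdir runs/demo`.

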