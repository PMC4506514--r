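# methylaber

Methylation subtyping and per-gene aberration calling against a normal
reference panel, for Illumina 450K-style beta-value matrices from tumour
cohorts. The motivating setting is rhabdomyosarcoma: tumours cluster into
four methylation subgroups (two embryonal-like, E1/E2; two
alveolar-like, A1/A2) with distinct mutation spectra and survival, and
individual genes — *PTEN*-like tumour suppressors in particular — can be
epigenetically silenced in specific subgroups relative to normal
skeletal muscle.

## What it computes

**Preprocessing.** Beta/M conversion (M = log2(β/(1−β))), iterative
low-rank imputation of incomplete data on the M scale, removal of X/Y
probes, and selection of the top-variance 1% of probes as clustering
input.

**Subtyping and differential methylation.** Hierarchical clustering
(Euclidean/Ward by default) cut at k = 4; per-probe two-sided Wilcoxon
rank-sum tests between cluster groups (exact null for small groups,
tie-corrected normal approximation otherwise) with a raw P < 1e−8 and
>2-fold-change filter, rolled up per gene over promoter probes (within
1,500 bp of the TSS).

**Aberration model.** For each gene k, the two-way table of methylation
changes against the normal panel, d_ij = x_ij − c_j, is decomposed
rank-one:

    d_ij = a_i · b_j + e_ij,   ‖b‖₂ = 1,

separating a per-sample methylation score a_i from a per-probe pattern
b_j. Tumour scores are standardised against the normal panel's scores,
z_ik = (a_ik − μ_k)/σ_k, and gene k is called aberrant in sample i when
|z_ik| > T, with T chosen so the Gaussian plug-in estimate
FDR̂(T) = min(1, N·2Φ(−T)/max(1, R(T))) falls below q = 0.05.

**Cohort statistics.** Mutation-frequency tables by cluster, Fisher
exact enrichment, Welch t-tests on mutation burden, and
Kaplan–Meier/log-rank survival comparisons.

**Synthetic cohorts.** `simulateCohort()` generates full study-shaped
cohorts — 11/11/18/10 tumours in four planted clusters plus 48 normals,
bimodal Beta-distributed probes, planted per-gene aberrations,
missingness, and cluster-correlated mutation and survival tables — with
exact ground truth, so every stage is testable offline.

## Worked example

```r
library(methylaber)

cfg <- cohortConfig(seed = 7)          # default study-shaped cohort
sim <- simulateCohort(cfg)
sim$experiment
#> MethylationExperiment: 15342 probes x 98 samples
#>   tumours: 50  normals: 48
#>   promoter probes: 9942  missing beta: 0.99%

pp <- preprocessMethylation(sim$experiment)   # impute, drop X/Y, top 1%
cl <- clusterMethylation(pp$reduced, k = 4)
cl
#> MethylClustering: 50 samples in 4 clusters (euclidean / ward.D2)
#> cluster
#>  1  2  3  4
#> 11 11 18 10

ab <- callMethylationAberrations(pp$complete, q = 0.05)
ab
#> AberrationResult: 50 tumours x 2000 genes
#>   threshold T* = 3.1 (q = 0.05); 3996 aberration calls

head(aberrationCalls(ab)[aberrationCalls(ab)$gene == "g0001", ], 4)
#>      sample_id  gene direction        z
#> 1 tumour_E1_01 g0001     hyper 14.88295
#> 2 tumour_E1_02 g0001     hyper 16.81995
#> 3 tumour_E1_03 g0001     hyper 12.31646
#> 4 tumour_E1_04 g0001     hyper 14.89308
```

The recovered clusters match the planted 11/11/18/10 layout exactly, and
the planted hypermethylated gene `g0001` is called "hyper" in the E1/E2
tumours with z-scores far above the selected threshold (T* = 3.1): the
z-scores say how many normal-panel standard deviations each tumour's
promoter methylation score sits from the panel mean.

The bundled 60-case mutation-count table reproduces published
frequency arithmetic, e.g. FGFR4/RAS/AKT pathway mutations by cluster:

```r
rc <- rmsTargetedCohort()
mutationFrequency(rc$mutations, rc$grouping, pathway = "FGFR4/RAS/AKT")
#>   group count total percent
#> 1    E1     6    11    54.5
#> 2    E2     9    11    81.8
#> 3    A1     3    18    16.7
#> 4    A2     2    10    20.0
#> 5    NA     4    10    40.0
```

A file-based end-to-end driver with a checksummed run manifest is
available as `runPipeline(pipelineConfig(outdir, seed = 7))`.

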