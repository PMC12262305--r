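# sticatlas

Integrated molecular analysis of serous tubal intraepithelial carcinoma
(STIC), the fallopian-tube precursor lesion of high-grade serous ovarian
carcinoma (HGSC). The package is aimed at computational biologists working
with spatially profiled precursor-lesion cohorts: area-of-interest (AOI)
whole-transcriptome counts paired with low-input genome-wide DNA locus
counts and clinicopathological annotations.

## What it computes

**Molecular subtyping.** Consensus non-negative matrix factorization of
stabilized, batch-corrected AOI expression. For rank *r*, each of 100
seeded runs minimizes ‖X − WH‖_F by multiplicative updates and assigns AOI
*j* to argmax_k H[k, j]; the consensus matrix C[i, j] is the co-assignment
frequency, labels cut the average-linkage dendrogram of 1 − C, and the rank
is chosen by cophenetic correlation (ties: silhouette width, then smaller
rank).

**Aneuploidy.** RealSeqS-style reference-panel scoring. A sample's locus
fractions are matched to the 7 most similar of 30 euploid panel members
(Euclidean distance); for each of the 39 non-acrocentric autosome arms,

    Z_arm = (Observed_arm − μ_arm^panel) / σ_arm^panel

with gain called at Z > 5 and loss at Z < −5. Log2 ratios over 50-kb bins
are segmented by permutation-tested circular binary segmentation; focal
amplifications at 19q12, 19q13.2 and 8q24 require a sub-chromosomal
segment with log2 > 0.25; the aneuploidy index is the number of base pairs
with |log2| beyond ±0.25.

**Expression statistics.** Moderated two-group t-tests with
method-of-moments empirical-Bayes variance shrinkage, Benjamini–Hochberg
correction (significance: adjusted p < 0.05 and |log2FC| > 0.5), unique
top-50 subtype signatures, and preranked GSEA with a gene-set resampling
null.

**Integration.** Euclidean molecular distances of lesions to NFT / HGSC /
mesothelium centroids on the signature-gene union; per-gene Pearson
correlation between expression and the cytoband-mapped DNA segment log2
ratio across matched patients.

**Clinicopathological statistics.** Cross-tabs, expected-count-based test
selection, Pearson chi-square, r×c Fisher exact tests
(enumeration/Monte-Carlo), column percentages, H-scores, Ki67 categories.

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the full
data structure — four lesion subtypes with signature programs and a
progression axis, reference tissue groups, run-level batch effects,
per-patient DNA with arm losses and focal gains, a 30-member euploid
panel, and subtype-conditional clinical covariates — so that every stage
has measurable ground truth.

## Worked example

```r
library(sticatlas)

b <- generate_cohort(synth_config(seed = 1))
b
#> cohort_bundle: 2000 genes x 205 AOIs, 160 DNA samples, panel of 30, 20000 loci
#> subtype
#>        dormant immunoreactive          mixed  proliferative
#>             40             40             40             40

expr <- remove_batch_effects(variance_stabilize(b$expr))
lesion <- expr$meta$diagnosis == "STIC"
X <- nonneg_shift_clip(aoi_matrix(expr$values[, lesion],
                                  expr$meta[lesion, ], transformed = TRUE))$values

cr <- consensus_nmf(X, r = 4, n_runs = 100, seed = 7)
cr
#> consensus_result: rank 4 over 100 runs | cophenetic 0.998, dispersion 0.824, silhouette 0.954
#> cluster
#>  1  2  3  4
#> 40 40 40 40
adjusted_rand_index(cr$labels, b$truth$aoi_subtype[colnames(X)])
#> [1] 1
```

The cophenetic correlation (dendrogram fit of the consensus distances)
near 1 and the balanced 4×40 clusters say the factorization is stable and
recovers the four simulated subtypes exactly (adjusted Rand index 1).

```r
p <- aneuploidy_profile(b$dna[[1]], b$panel, b$genome, seed = 7)
subset(p$arm_z, call != "neutral")[, c("arm", "z", "call")]
#>    arm          z call
#> 6   3q  41.461978 gain
#> 16  8q   7.505816 gain
#> 25 13q -47.787261 loss
#> 30 17p -26.473418 loss
#> 31 17q -33.261190 loss
#> 35 19q  25.055425 gain
p$focal
#>    target called  seg_log2
#> 1   19q12   TRUE 0.8106376
#> 2 19q13.2   TRUE 0.8866263
#> 3    8q24   TRUE 0.8003066
p$index
#> [1] 25750000
```

Patient 1 simulates a proliferative lesion: the chromosome 13/17 arm
losses and the 3q gain are called at |Z| ≫ 5, the focal 19q12 / 19q13.2 /
8q24 amplifications are detected near their simulated log2 of 1 (their
mass also lifts the whole 8q and 19q arm fractions above the call
threshold, which is how focal events surface at arm level), and ~26 Mb
of the 220-Mb toy genome is counted as altered.

```r
t1 <- table1_counts()
percent_summary(t1$atypia)["High-grade", ]
#>        Dormant          Mixed Immunoreactive  Proliferative
#>           22.0           53.8           84.6           91.5
chi_square_test(t1$lymphocytes)$p
#> [1] 0.03104238
```

The bundled published cohort counts reproduce the printed percentages
(high-grade atypia in 91.5% of proliferative lesions) and association
p-values (stromal lymphocytes, p = 0.031).

The whole pipeline — simulate, preprocess, subtype, profile aneuploidy,
differential expression, integrate, associate — runs as one call:

```r
res <- run_pipeline(default_pipeline_config(seed = 1, out_dir = "demo"))
```

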