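---
title: "Methods: molecular subtyping and aneuploidy profiling of tubal precancerous lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular subtyping and aneuploidy profiling of tubal precancerous lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`sticatlas` implements the computational core of an integrated spatial
analysis of serous tubal intraepithelial carcinoma (STIC), the fallopian-tube
precursor of high-grade serous ovarian carcinoma (HGSC). The package covers
six analysis stages and a synthetic-cohort generator that makes all of them
testable without access to any proprietary cohort:

1. preprocessing of AOI (area-of-interest) expression counts: variance
   stabilization, run-level batch removal, a kBET-style mixing score, PCA;
2. molecular subtype discovery by consensus non-negative matrix
   factorization (NMF) with cophenetic/dispersion/silhouette rank metrics;
3. arm-level aneuploidy Z-scoring against a euploid reference panel, 50-kb
   bin log2 ratios, circular binary segmentation (CBS), focal amplification
   calls, and an aneuploidy index;
4. moderated-t differential expression, unique subtype signatures, and
   preranked gene-set enrichment (GSEA);
5. RNA-DNA integration: cytoband mapping, expression vs copy-number
   correlation, and Euclidean molecular distances to reference centroids;
6. clinicopathological association statistics (chi-square / exact tests,
   percentage summaries, H-score, Ki67 categories).

# The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws a cohort whose *structure* matches the study
design: four lesion subtypes (proliferative, immunoreactive, mixed,
dormant) with 40 AOIs each under the defaults, reference groups of normal
fallopian-tube epithelium (NFT), HGSC and ovarian mesothelium, four
simulated instrument runs acting as batches, per-patient DNA locus counts
over a 22-autosome toy genome, and a 30-member euploid reference panel.

Key modelling choices, each a package decision where the underlying study
reports no value:

* **Expression noise.** Counts are negative binomial with gene-specific
  dispersion drawn log-normally (`dispersion_meanlog = log(10)`,
  `dispersion_sdlog = 0.5`) around library sizes of 150k reads per AOI.
  Digital spatial profiling platforms report no canonical count model;
  an overdispersed count law is the field standard.
* **Subtype geometry.** Each subtype uniquely upregulates 50 signature
  genes by 2.0 log2 units. A *progression axis* through the proliferative
  signature places the subtypes at 0 (dormant), 0.5 (mixed), 0.75
  (immunoreactive) and 1.0 (proliferative), with HGSC beyond the
  proliferative pole and mesothelium on an orthogonal lineage program.
  This reproduces, by construction, the published qualitative ordering of
  molecular distances (dormant nearest NFT, proliferative nearest HGSC).
* **Copy-number events.** Chromosome 13/17/22 arm losses across subtypes
  and focal 19q12 / 19q13.2 / 8q24 gains concentrated in the proliferative
  subtype, mirroring the reported aneuploidy pattern. Events are
  deterministic per subtype by default (`cn_presence_prob = 1`); lowering
  the presence probability plants genuine within-subtype substructure,
  which consensus clustering will then legitimately discover as additional
  clusters.
* **Gene dosage.** Genes inside a realized event shift their expected
  expression by the event's log2 value, which is what makes the
  RNA-vs-DNA correlation recoverable.
* **Amplicon-efficiency jitter.** Every DNA sample (panel members
  included) multiplies its locus weights by a log-normal factor
  (`amplicon_jitter_sdlog = 0.2`). Without between-sample amplicon
  variability the panel-matching step would be meaningless (all members
  equidistant) and the panel SD unrealistically small; this jitter is the
  reason a "most similar subset of 7" exists to be found.
* **Toy genome.** Twenty-two 10-Mb autosomes, p/q boundary at 4 Mb, and
  acrocentric p arms on chromosomes 13, 14, 15, 21 and 22, so exactly 39
  scoreable arms exist by construction; 20,000 loci are placed uniformly
  (real repetitive-element loci are sequence-anchored, which is out of
  scope). An approximate human-scale arm/cytoband table
  (`hg_genome()`, bundled as a coarse synthetic stand-in, not an ideogram)
  is available for runs needing realistic genomic proportions.

What passing tests on this cohort do **not** show: recovery of the actual
published subtype labels, signatures, or aneuploidy heatmaps, which would
require the real cohort; robustness to probe-level artifacts, segmentation
errors in AOI selection, or batch effects that interact with biology
(simulated batch shifts are additive and independent of subtype).

# Preprocessing

`variance_stabilize()` divides each AOI by its upper-quartile size factor
(referenced to the median upper quartile, so identical AOIs get factor 1
and rescaling one AOI cancels exactly) and applies log2(x + 1).
`remove_batch_effects()` subtracts per-gene batch-mean deviations from the
grand mean; this least-squares correction preserves per-gene grand means
exactly and is idempotent.

**Order of operations.** The published pipeline describes correcting raw
counts and then variance-stabilizing. Least-squares batch removal assumes
roughly additive errors, which raw counts violate; the package therefore
defaults to stabilize-then-correct and offers the literal published order
behind `preprocess$order = "batch_first"` in the pipeline configuration
(log-transform, correct, back-transform, then stabilize). The default is a
numerical-sanity decision, not a claim about what the study did.

Batch mixing is scored kBET-style: for seeded random anchor AOIs, a
chi-square goodness-of-fit test compares the k-nearest-neighborhood batch
composition with global batch frequencies; the score is the rejection
fraction at level 0.05. It is a reimplementation of the rejection-rate
idea, not a port of the original package.

# Consensus NMF and rank selection

`nmf_factorize()` uses the classical multiplicative updates for the
Frobenius objective (loss provably nonincreasing; the trace is kept and
tested). Consensus clustering (`consensus_nmf()`) runs 100 seeded
factorizations (run *i* uses `seed + i`), assigns each AOI to the argmax
of its H column (ties toward the lower index), and averages co-assignment
into a consensus matrix; final labels cut the average-linkage dendrogram
of 1 - consensus at the rank. Batch-corrected expression is shifted by the
global minimum and clipped at zero beforehand (`nonneg_shift_clip()`), a
mandatory repair that published batch-corrected NMF analyses leave
implicit.

Rank selection maximizes the cophenetic correlation with ties broken by
higher mean silhouette width (computed on 1 - consensus distances, the
usual consensus-clustering practice), then by the smaller rank. Two
numerical points matter in practice. First, stability is only meaningful
between *converged* runs: half-converged factorizations blur the argmax
assignments at the true rank while surplus factors at over-fitted ranks
absorb the blur reproducibly, inverting the stability ordering — hence
the per-run defaults (`max_iter = 400`, `tol = 1e-6`, with the loss
evaluated each iteration from the update intermediates at no extra
matrix-product cost). Second, the cophenetic correlation of a 100-run
consensus is a Monte Carlo estimate with noise of a few thousandths, so
`select_rank()` treats candidates within `tie_eps = 0.005` of the
maximum as tied and resolves them by silhouette, then by the smaller
rank; an exact floating-point tie would almost never occur. On clean
cohorts several ranks then sit at near-perfect stability and the
silhouette identifies the parsimonious one, mirroring how published
analyses temper the quantitative metrics with interpretability.

# Aneuploidy

Arm-level statistics follow the reference-panel scheme: each sample is
matched to the 7 of 30 panel members closest in Euclidean distance between
locus-fraction vectors; for each of the 39 non-acrocentric autosome arms
the observed statistic is the summed locus fraction, and
Z = (observed - mu_panel) / sigma_panel with mu/sigma from the *matched*
members (n-1 denominator). Arms are called gained above +5 and lost below
-5. Whether the study computed mu/sigma over the matched 7 or all 30 is
ambiguous in the text; the matched subset is the default here. With only 7
matched members the Z statistic is t-distributed with 6 degrees of
freedom, so |Z| > 5 still occurs in roughly 0.3% of euploid arms — the
measured per-arm false-call rate on simulated euploid samples (under 1%)
is the operating characteristic the tests assert.

Bin-level ratios use 50-kb half-open bins, a pseudocount of
0.5 / n_loci, and the matched-panel mean as the reference. CBS is
reimplemented from the circular-split principle: the arc maximizing the
standardized mean difference is accepted if its permutation p (1000
seeded shuffles) falls below 0.01, recursively; the scan is compiled
(Rcpp) with sequential early termination once a split can no longer reach
significance, which keeps flat chromosomes cheap. Bit-compatibility with
the original segmentation package is a non-goal (no pruning/undo step).

A focal amplification at 19q12, 19q13.2 or 8q24 requires an overlapping
segment with log2 > 0.25 spanning less than 90% of its arm — the
"sub-chromosomal" requirement made operational; the 90% cutoff is a
package decision. The aneuploidy index sums binned base pairs whose
segment-assigned log2 exceeds +0.25 or falls below -0.25 (bin-level
values behind a flag).

# Differential expression and enrichment

`fit_de()` is a self-contained moderated two-group test: per-gene pooled
variances are shrunk toward a prior whose degrees of freedom and scale are
estimated by matching the mean and squared coefficient of variation of the
observed variances to the moments of the implied scaled-F distribution.
This method-of-moments fit replaces the exact marginal-likelihood fit of
the reference implementation; the two agree closely in simulation (tested
against limma as an oracle) and coincide in the infinite-prior limit,
which is also exposed (`prior_df = Inf`) and tested in closed form.
Significance uses the published thresholds: BH-adjusted p < 0.05 and
|log2FC| > 0.5.

Unique subtype signatures take each subtype's significant upregulated
genes, drop genes significant-up in two or more subtypes, rank by
moderated t, and keep the top 50. These 200 genes define the subspace for
molecular distances.

`gsea_preranked()` computes the weighted Kolmogorov-Smirnov running-sum
enrichment score (hits weighted by |score|^weight). The null resamples
gene sets of equal size rather than permuting phenotypes, because
subtype-vs-rest contrasts have small groups; p-values use the
add-one permutation estimator, NES divides by the mean same-sign null
|ES|, and q is BH across sets. No gene-set collections are bundled; GMT
files are read with `read_gmt()`.

# Integration

Genes map to the cytoband containing their start coordinate (half-open).
Per gene, the DNA value of a patient is the seg_log2 of the overlapping
segment (longest-overlap on boundary ties); expression is the patient's
mean across epithelial AOIs (the pairing rule when several AOIs share one
DNA sample — a package decision). Pearson correlations with BH correction
require at least 3 matched patients and drop constant-DNA genes with a
warning. Distances are computed on stabilized expression without
z-scoring (`--zscore`-style standardization is deliberately not the
default; the distance subspace is already restricted to signature genes).

# Clinicopathological statistics

Cross-tabs, expected counts, and the textbook selection rule (Fisher's
exact test when any expected count is below 5, chi-square otherwise) are
implemented directly; the chi-square has no continuity correction, and
the r x c Fisher test uses the probability-ordering two-sided definition
(full enumeration up to a grand total of 500, seeded Monte Carlo beyond).
Because published tables do not always state the per-row choice — and the
selection is genuinely borderline for the copy-number-gain rows, where
the printed p-values match the chi-square — `associate_subtypes()` always
reports both p-values alongside the rule's selection. H-scores and Ki67
categories follow the printed definitions, with the 5% and 20% boundaries
assigned to the Intermediate class.

# Numerical choices and degenerate inputs

* Zero-variance arms: Z is defined as 0 when the sample equals the panel
  exactly, undefined (flagged, neutral) otherwise.
* All-zero genes are dropped with a warning before NMF; all-zero AOIs are
  an error in normalization (named in the message).
* Constant consensus distances return cophenetic correlation 1 with a
  warning.
* BH inputs outside [0, 1] and H-score percentages not summing to 100 are
  errors, not silent repairs.
* All randomness flows through per-stage child seeds derived from one
  global seed; every generator output is a pure function of its
  configuration.

# Problem sizes

The default verification cohort is 2,000 genes by 160 lesion AOIs (plus
45 reference AOIs), 20,000 DNA loci at 500k reads, consensus NMF over
ranks 2-6 with 100 runs each, and full aneuploidy profiles for all 160
patients; operating characteristics (arm-call sensitivity/specificity,
CBS breakpoint accuracy) use 100 simulated events each. These sizes keep
a complete pipeline run in the single-digit minutes on one core while
leaving every recovery property measurable.

# Known limitations

* The generator emulates structure, not biology: no probe-level effects,
  no spatial autocorrelation between neighboring AOIs, no stromal
  compartment expression, no subclonal copy-number mixtures.
* CBS here has no segment merging/undo step; on data with many small
  true segments it will tend to over-split relative to the reference
  implementation.
* The moderated-t prior fit assumes a unimodal variance distribution;
  strongly bimodal variance structure would be better served by the exact
  marginal-likelihood fit.
* `hg_genome()` is a coarse, approximate arm/cytoband table intended for
  scale realism only.
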