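---
title: "Methods: selecting and quantifying spinal V1 interneurons from snRNA-seq"
author: "v1atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selecting and quantifying spinal V1 interneurons from snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Spinal V1 interneurons are a diverse class of inhibitory neurons that shape
rhythmic locomotor output and limb flexion. Building a single-nucleus
transcriptomic atlas of this population poses a specific chain of analysis
problems: enriched FACS-sorted samples still carry contaminant nuclei
(glia, microglia, motor neurons, other interneuron classes); the defining
lineage marker (En1) is downregulated postnatally, so V1 identity must be
inferred by reference to an embryonic atlas rather than read off a single
gene; and the population substructure of interest — five mutually exclusive
clades marked by Foxp2, Sp8, Pou6f2, MafA/Calbindin (proxied by Chrna2 at
assignment time) and Rnf220 — must be called reproducibly in the presence
of dropout. Downstream, the questions are quantitative: does the clade
composition shift with genotype, do ages mix within clusters, do neuron
positions differ spatially, and does a perturbation change the frequency of
rhythmic motor output or joint kinematics.

`v1atlas` implements this chain as composable, individually tested
functions plus a `run_pipeline()` orchestrator, and ships a synthetic-data
generator that emulates the statistical structure of such an experiment
with known ground truth, so that every stage has a parameter-recovery test.

# Quality control

`compute_qc()` tabulates per-nucleus total UMIs, detected genes and the
mitochondrial fraction (genes prefixed `mt-` by default; an all-zero
nucleus has mitochondrial fraction 0 by convention). `filter_nuclei()`
keeps a nucleus iff it has at least 1000 UMIs, at most 2.5% mitochondrial
transcripts, and both its UMI and gene counts lie within median ± 3 MAD
within its sample. The MAD is unscaled — median(|x − median|) on the raw
counts, without the 1.4826 normal-consistency factor — because the fences
operate on heavy-tailed count data where the consistency factor has no
privileged status; the number of MADs is a parameter. The fences are
applied after the fixed cuts and are one-shot: re-filtering an already
filtered sample can in principle remove further nuclei because the fences
are recomputed from truncated data, so the pipeline applies them exactly
once. Nuclei above the upper UMI fence double as putative doublets; no
separate doublet detector is used. `filter_genes()` keeps genes detected
in at least 10 nuclei (a gene seen in exactly 10 is kept).

# Normalization, variable genes, components

`lognormalize()` is the standard per-10,000 transform,
v = ln(1 + 10⁴·c/total), in natural log (the base is a parameter). It is
exactly invariant to depth rescaling and preserves sparsity.

`select_variable_genes()` ranks genes by variance-stabilized standardized
variance: a loess trend of log10 variance on log10 mean is fit across
genes, each gene's values are standardized by the trend-expected standard
deviation with clipping at √n, and genes are ranked by the variance of the
clipped standardized values. The default returns 2000 genes. This is a
deliberate approximation of regression-based variance stabilization used
for atlas integration elsewhere; the fidelity gap is documented rather
than papered over — no gamma-Poisson regression is fit.

`run_pca()` scales variable genes to unit variance (values clipped at 10)
and computes a truncated PCA (30 components by default). `find_pc()`
selects the component count from two criteria evaluated on the percent
variance per component, expressed relative to the computed spectrum:
(A) the first k where the cumulative percentage exceeds 90 and the
individual percentage falls below 5; (B) one past the last drop greater
than 0.1 percentage points between adjacent components. The combiner is
min(A, B) — the convention of the widely used elbow-selection recipe this
function models — and both intermediate answers are returned as
attributes. If A is never met the full length is used with a warning, and
when no drop qualifies criterion B does not bind.

# Batch alignment and clustering

`align_batches()` is a contract, not an algorithm claim: each
non-reference sample is translated by the mean displacement of its mutual
nearest neighbours in the reference sample, in PC space. The tested
contract is that aligned replicates of the same condition mix better
(higher sample iLISI, smaller centroid distances) than unaligned ones;
anchor-based integration internals are out of scope and pluggable.

`cluster_nuclei()` builds a k-nearest-neighbour graph (k = 20 by default)
and runs Louvain modularity optimization at a given resolution with a
fixed seed. Labels are integers from 0 ordered by decreasing size.
A caveat stated once and tested accordingly: the resolution parameter here
is igraph's modularity scaling and is *not* numerically comparable to the
resolution values of other toolkits, where settings like 0.003 and 0.24
yield 2 and 14 clusters under a different modularity scaling. On the
generator's conditions the default resolution of 1 recovers all planted
populations with adjusted Rand index above 0.95; modularity optimization
on kNN graphs tends to oversplit small datasets, which refines but never
merges well-separated planted groups (tested as cluster purity).
Identical points are a degenerate input and collapse to one cluster.

# Negative and positive selection

`negative_selection()` iterates normalize → variable genes → PCA →
cluster, scores every cluster against contaminant marker panels
(`score_panels()`: per-panel mean expression averaged within cluster,
z-scored across clusters), removes flagged clusters, and stops when a
round removes nothing (or after `max_rounds`, default 10). A cluster is
flagged when its panel z exceeds 2 *and* its mean panel expression exceeds
an absolute floor (0.1 log-normalized units, configurable), or when its
median mitochondrial fraction breaches the QC cut. The absolute floor
matters: once contaminants are gone, z-scores alone would flag relative
outliers among clusters that barely express a panel at all. The default
panels are illustrative working panels matching the generator's
contaminant populations — a curated marker table for a real experiment
must be supplied by the analyst — and every removal is logged with its triggering rule, an
auditable substitute for manual annotation.

`transfer_labels()` performs positive selection: the reference is reduced
by PCA over shared variable genes, query nuclei are projected into that
space, and each query nucleus is scored by the Gaussian-kernel-weighted
fraction of each reference label among its 30 nearest reference cells
(per-query bandwidth = median neighbour distance). Scores form an exact
probability vector; zero-distance matches dominate (the kernel limit), and
argmax ties break lexicographically. This weighted-kNN scheme implements
the same contract as anchor-based label transfer — probabilistic label
scores — with far fewer moving parts, and is tested against ground truth.
`select_v1()` keeps a nucleus iff the argmax label is "V1" and the score
is at least 0.5.

# Clade assignment

Per-nucleus calls (`call_marker_positive()`) use strict thresholds on the
merged log-normalized matrix — Foxp2 > 2.8, Sp8 > 0.8, Pou6f2 > 2.6,
Chrna2 > 1.1 — never batch-corrected values; corrected representations are
used only for clustering. Cluster-level assignment
(`cluster_clade_zscores()` + `assign_clades()`) averages each marker over
the nuclei of a cluster, z-scores across clusters, and assigns each
cluster to the marker with positive z; with several positive z-scores the
highest wins; with none, the cluster goes to the Rnf220 clade if its
Rnf220 z is positive and is otherwise unassigned. The Rnf220 fallback is a
design choice: the fifth clade was originally found by differential
expression, not a printed threshold, and the fallback covers
Nr5a2-type clusters that carry no primary marker. Chrna2 stands in for the
MafA/Calbindin clade at assignment time; Calb1 is a display marker.
`count_coexpressing()` counts nuclei positive for two or more primary
markers; `clade_proportions()` reports per-replicate fractions (summing
to 1 exactly) with mean ± SEM.

# Compositional analysis

`compute_ilisi()` implements the local inverse Simpson's index: for each
nucleus, Gaussian weights over its 3 × perplexity nearest embedding
neighbours are entropy-tuned to the target perplexity (default 30), group
probabilities are the weighted label proportions, and the score is
1/Σp², hard-bounded in [1, number of groups]. One group returns 1
everywhere; too-few neighbours shrink the perplexity with a warning.

`normalized_genotype_ratio()` reports, per replicate,
(cluster share in genotype A)/(cluster share in genotype B); 1 is equal
representation, zero denominators yield flagged infinities, and the ratio
is invariant to either genotype's sequencing depth.

`dm_test()` is the compositional test: sample count vectors are
Dirichlet-multinomial with log α = cluster intercept + genotype effect ×
inclusion indicator, the reference cluster's effect fixed at zero
(`choose_reference()` picks an abundant cluster with the smallest
between-genotype change, then least dispersion). The spike-and-slab uses
*exact discrete* indicators updated by Metropolis flips within Gibbs,
rather than a continuous relaxation: at this model's scale (≤ 14 clusters,
4 samples) discrete flips mix well, and the inclusion probability is then
literally the posterior mean of the indicator. A joint shift proposal on
all intercepts is essential — the overall Dirichlet concentration is only
weakly identified and per-coordinate walks alone leave split-R̂ near 2;
with the scale move, R̂ stays near 1 and the fit errors out above 1.05
unless the check is disabled. Priors: effect ~ N(0, 1.5²) on the natural
log scale, inclusion prior 0.1, intercepts loosely centred on observed
log-compositions. The credible set is the largest set of clusters, ordered
by inclusion, whose mean (1 − inclusion) is at most the expected FDR
(0.05 by default). Effects are reported in log2; the 95% interval for a
cluster comes from its slab draws (the draws with the indicator on).
Defaults are 4 chains × 2000 iterations (half warmup), which resolves a
3-fold depletion of a 3% cluster in a 4 × 2000-nucleus design with
inclusion near 1 while keeping the null false-positive rate at or below
the FDR (both properties are tested, the null over 100 seeded
replicates at reduced draws).

# Differential expression

`wilcoxon_de()` is the two-sided rank-sum test per gene: exact null
distribution for small tie-free groups (both ≤ 10), otherwise the normal
approximation with tie correction and continuity correction. The exact
path is verified against an independent brute-force enumeration over all
group assignments. Fold changes use the expm1-mean convention,
log2((mean(eˣ−1)+1)/(mean(eʸ−1)+1)); significance requires Bonferroni
p < 0.05 over the genes tested *and* |log2FC| strictly greater than 0.25
(a gene at exactly 0.25 is excluded). No minimum-expression prefilter is
applied by default. `find_markers()` ranks passing genes by fold change,
one-vs-rest or pairwise; `age_degs()` applies the stated age groupings
(P0 versus the rest; P28 + P56 versus the rest) and keeps positively
enriched genes.

`pseudobulk()` sums raw counts within groups (exact, linear,
mass-conserving). `pseudobulk_de()` is a deliberately minimal NB-Wald
contract for replicated pseudo-bulk contrasts: median-of-ratios size
factors, per-gene method-of-moments dispersion pooled across conditions
and floored at 1e-8, a Wald z on the log fold change, and BH adjustment.
It is mildly anti-conservative at very small replicate counts (tested at
the null); a full shrinkage-based bulk pipeline is intentionally not
reimplemented, and the implementation is cross-checked against one on
planted effects in the test suite. `cluster_tree()` builds the
average-linkage dendrogram on Euclidean distances between cluster mean
profiles in PC space; `cluster_correlation()` computes Pearson
correlations of cluster means over all log-normalized genes — two distinct
summaries, kept distinct on purpose.

# Spatial statistics

`normalize_position()` rescales per-section coordinates to the
standardized hemisection: central canal at the origin, lateral extent
mapped to 650 μm, ventral extent to 400 μm. The ventral scale factor is
also applied to dorsal points, since only the ventral extent is
standardized. `density_grid()` wraps a 2-D Gaussian KDE
(normal-reference bandwidths, overridable). `ks2d()` is the
Fasano–Franceschini two-sample statistic: with every data point as
origin, the two samples' empirical fractions in the four open quadrants
are compared; D averages the two per-sample maxima. Identical multisets
give exactly D = 0; samples supported in disjoint quadrants give exactly
D = 1 (a Pareto-frontier point of each sample has an empty quadrant);
D is invariant to any shared affine rescaling. The p-value is by label
permutation (default 1000 reps, seeded), preferred over the asymptotic
formula at the sample sizes typical of per-animal section data; it is
bounded below by 1/(n_perm+1) and its type-I error is verified at
α = 0.05 over 500 null replicates. Sections are pooled by default.

# Physiology

`smooth_trace()` is the centered moving mean with truncated (valid-only)
edges; the study setting is a 10,000-point window, one second at the
10 kHz digitization rate. `locomotor_frequency()` mean-subtracts, takes
the plain untapered periodogram, and returns the argmax frequency
excluding DC; resolution is fs/n and a DC offset cannot change the
answer. One practical note, stated because it is easy to trip over: a
moving mean of window T nulls frequencies at exactly 1/T, so sweeps that
include 1 Hz use a shorter window (0.2 s in the tests) — the study's 1 s
window suits its ~0.4 Hz rhythms.

`joint_angle()` computes interior angles at a joint vertex from the two
arm vectors (wrist: forepaw–elbow; elbow: wrist–armpit; ankle:
hindpaw–knee; knee: ankle–groin) via the clamped arccos of the normalized
dot product — exactly invariant to rigid transforms and uniform scaling;
coincident landmarks flag the frame as NA. `select_frames()` keeps frames
where all nine landmarks reach a confidence floor (0.9) and that avoid
user-supplied exclusion intervals, the scripted stand-in for manual
annotation of turning/flipping bouts. `summarize_angles()` averages
within animal, then reports the group mean ± SEM across animals.

# The synthetic-data generator

`simulate_counts()` draws cluster-structured negative-binomial counts:
a shared heavy-tailed baseline (log-normal, sdlog 1.8) times per-population
log-normal jitter (sdlog 0.6) defines each population's expression
profile; clade markers are planted at fixed log-normalized means in their
clusters (Foxp2 3.5, Sp8 1.5, Pou6f2 3.2, Chrna2/Calb1 1.8, Rnf220 2.5,
Nr5a2 2.0) and at a fixed low background (0.05) elsewhere; contaminant
panels behave symmetrically (3.0 in their own population, 0.05
elsewhere). Mitochondrial genes carry ~1.2% of counts in every
population. Counts are NB with gene-level dispersion 0.3 (0.05 for
planted markers, which model high, reliably detected transcription
factors) scaled by per-nucleus depth (log-normal around a mean of 2,500
UMIs — a desk-scale stand-in for the study's ~6,400 — times a per-sample
depth factor). Doublets (5%) add a same-sample partner's counts; ambient
contamination (2%) removes a binomial fraction of each nucleus's counts
and replaces it with draws from the pooled profile, mirroring what
ambient-removal tools estimate without reimplementing them. A
genotype-specific depletion multiplies one cluster's sampling probability
by 2^log2FC. The default conditions are 20,000 nuclei, 10% contaminants
across five panels, two replicates at each of four ages; the
genotype-comparison conditions are 11 clusters with a rare (3%)
Pou6f2/Nr5a2-type cluster depleted 3-fold in the knockout across
2 + 2 samples of 2,000 nuclei.

Two seeds govern the generator. `seed` fixes sampling (labels, depths,
counts, doublets, ambient) bit-for-bit. `profile_seed` fixes the
expression programs themselves and defaults to a constant, so a query
dataset and a reference generated from the same configuration family
share cell-type programs — as a postnatal sample and an embryonic
reference atlas genuinely would — while remaining independent draws.
`simulate_reference()` exploits this to build a labelled reference with a
"V1" class and upsampled non-V1 classes.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: gene–gene correlation beyond cluster means, the
ambient-RNA soup's gene bias (the pooled profile is used), empty
droplets, batch effects beyond per-sample depth, spatially varying
dropout, or any read-level error process. Ambient and doublet rates are
placeholders — the study reports no realized rates.

`simulate_positions()` draws per-clade Gaussian mixtures clipped to the
standardized hemisection; `simulate_root_trace()` produces a sinusoid or
a rectified-sine-to-the-4th burst train plus white noise;
`simulate_landmarks()` places the nine tail-suspension landmarks by
forward kinematics so that recomputed joint angles equal the planted
series exactly before noise.

# Numerical choices and degenerate inputs

Strict inequalities are used everywhere a threshold is printed (marker
calls, the 0.25 fold-change rule, gene-detection ≥ 10 is the stated
boundary's complement). MAD fences keep everything when the MAD is 0.
Single-nucleus samples skip fences with a warning. A single cluster makes
cross-cluster z-scores an error; a constant trace makes the frequency
undefined (error); zero-extent sections, zero-total nuclei and zero
segment lengths are errors. arccos arguments are clamped to [−1, 1].
Bonferroni is capped at 1. The truncated PCA solver switches to exact SVD
when the requested rank is no longer small relative to the matrix.
All stochastic stages derive their seeds from one top-level seed through
`stage_seed()` (a hash of the stage name added to the base seed, kept
below 2³¹).

# Problem sizes used by the test suite

The suite exercises the full selection chain at 20,000 nuclei × 2,000
genes (the generator's default conditions), compositional recovery at
4 × 2,000 nuclei with a 100-replicate null at reduced MCMC draws,
2-D KS calibration over 500 null replicates of 50 + 50 points with 99
permutations each, frequency recovery over 50 traces of 60 s at 10 kHz,
and oracle identities over 1,000 (component rule) and 200 (rank-sum)
randomized cases. Smaller unit fixtures are constructed inline. The same
quantities are recomputed end to end by `scripts/acceptance.R`.

# Known limitations

- The shipped marker panels and the synthetic reference are working
  stand-ins, not curated marker tables or a real embryonic reference
  atlas; on real data both must be supplied.
- Variable-gene ranking approximates regression-based variance
  stabilization; anchor-based integration is replaced by a
  mutual-nearest-neighbour shift satisfying a mixing contract.
- `pseudobulk_de()` trades shrinkage for transparency and is slightly
  anti-conservative with two replicates per condition.
- Clustering resolution is igraph-scaled; resolution values quoted for
  other toolkits do not transfer numerically.
- The Dirichlet-multinomial sampler is adequate for tens of clusters and
  a handful of samples; it is not built for hundreds of cell types.
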