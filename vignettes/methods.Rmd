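---
title: "Compositional analysis of gut microbiome cohorts: models and methods"
author: "miCompass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of gut microbiome cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miCompass)
```

# Overview

`miCompass` implements a complete compositional analysis of shotgun
metagenomic gut-microbiome cohorts of the kind used in case/control IBD
studies: a case group, an internal control recruited in the same study,
and one or more external healthy cohorts. The stages are

1. **abundance estimation** — EM soft assignment of multi-mapping reads
   to reference genomes, a mapped-read QC threshold, a relative-abundance
   noise floor, and strain-to-species aggregation;
2. **compositional processing** — centred log-ratio (CLR)
   transformation, a per-group prevalence filter, and a per-subject
   replicate cap;
3. **diversity and dissimilarity** — Shannon entropy on untransformed
   relative abundances, and intrapersonal vs interpersonal Bray-Curtis
   dissimilarity profiles;
4. **signature selection** — repeated random-forest fits with a planted
   random-noise feature as an importance null;
5. **differential abundance** — per-species Mann-Whitney tests on CLR
   values, Benjamini-Hochberg correction, and a multi-control consensus
   rule with a twofold fold-change requirement;
6. **association networks** — an l1-penalised Gaussian graphical model
   with StARS penalty selection and bootstrap edge stabilisation;
7. **functional capacity** — abundance-weighted protein-family profiles
   with the same consensus testing machinery.

Every stage is validated against a synthetic-cohort generator whose
ground truth (latent precision matrix, planted fold changes, mixture
proportions) is known exactly.

# Data model

Sequencing yields only *relative* abundances: each sample is a point on
the simplex, and totals carry no information. The central container is
`MicrobiomeExperiment`, a `SummarizedExperiment` with species as rows,
samples as columns, a `"relabund"` assay whose columns sum to 1, and
per-sample subject and diagnosis-group annotations. `clrTransform()`
adds a `"clr"` assay:

$$\mathrm{CLR}(x)_j = \ln\frac{x_j}{G(x)}, \qquad
  G(x) = \Big(\prod_{j=1}^{D} x_j\Big)^{1/D},$$

so each transformed sample sums to zero. CLR values are used everywhere
downstream except Shannon entropy, which is computed on the raw
proportions in bits.

**Zero handling.** $\ln 0$ is undefined, so zeros must be resolved
before the transform. The package uses multiplicative replacement: zero
entries become a pseudo-abundance of $5\times10^{-6}$ — half the
$10^{-5}$ profiling noise floor, so replacement values always sit below
anything the floor admitted as signal — and the nonzero entries are
scaled down to preserve the unit sum. The policy and pseudo-count are
recorded in the object's metadata for provenance.

# Synthetic cohorts and what they emulate

`generateCohort()` draws latent log absolute abundances from a
multivariate Gaussian whose precision matrix $\Omega$ is sampled
sparsely (`samplePrecisionMatrix()`): off-diagonal support drawn
edge-wise, magnitudes uniform in $[0.1, 0.4]$ with random signs, and the
diagonal raised until the smallest eigenvalue reaches $0.05$. This is
the native assumption of the Gaussian graphical model used for network
inference, so the generator's support matrix is the exact estimand of
that stage.

Group effects are planted as mean shifts of $\log 2 \cdot
\mathrm{log2fc}$ on designated species; the generator refuses planted
effects below one log2 unit so that "differentially abundant" always
means at least twofold, matching the detection rule. Subject structure
is a per-subject Gaussian intercept (default sd 0.5 in log-abundance
units) shared by all of a subject's replicates, which reproduces the
empirical ordering *intrapersonal dissimilarity < interpersonal
dissimilarity*. Replicate counts per subject are drawn from a
distribution over 1–5 (the replicate cap used at profiling time).
Baseline species means are drawn with sd 1, giving realistic unevenness
(relative abundances spanning roughly $10^{-3}$ to $0.25$ at $D = 50$).
Latent abundances are exponentiated, closed to proportions, floored at
$10^{-5}$ and re-closed.

Subject identifiers are numbered in a shuffled global order. This is
deliberate: subject ids are label-encoded as classification features,
and ids numbered per group would make the encoded integers contiguous by
diagnosis — a label leak no real accession scheme produces.

The default design (`defaultCohortSpec()`) is a desk-scale analogue of
a multi-cohort study: 40 case subjects and 25 internal-control subjects
with a mean of ~2.5 replicates, 60 external subjects without replicates,
and 20 external subjects with a mean of ~3.3 replicates; group-specific
age ranges (cases skew young) and sex balance.

**What the generator does not emulate:** sequencing error and read-level
artefacts, batch and extraction-kit effects, heavy zero inflation
(compositions here are mostly dense once a species is present), strain
heterogeneity within species, and covariance structure that differs
between groups' shared baseline. Passing recovery tests therefore shows
the statistical machinery is correct under its stated model, not that
real cohorts satisfy that model.

# Abundance estimation

`emEstimate()` maximises $\prod_{\text{reads}} \sum_{g \in C_r} \pi_g
w_{rg}$ by EM: responsibilities proportional to $\pi_g w_{rg}$ over each
read's compatible set $C_r$, then $\pi \leftarrow$ mean responsibility.
Reads with identical compatibility sets are collapsed, so cost scales
with distinct patterns. Initialisation is uniform — the log-likelihood
is concave in $\pi$, so the starting point matters only in flat
directions — and iteration stops when no proportion moves by more than
$10^{-8}$ (cap 1000 iterations). Alignment weights default to uniform.

The surrounding rules are strict by construction: samples with fewer
than 250,000 mapped reads are dropped (exactly 250,000 is kept);
relative abundances strictly below $10^{-5}$ are zeroed. Rows are
re-closed after flooring — whether to renormalise is genuinely
ambiguous, but downstream CLR and diversity computations require proper
compositions, so re-closure is the package's choice. Stage order is
fixed: QC, EM, noise floor, strain aggregation, closure.

# Prevalence, replicates, dissimilarity

`prevalenceFilter()` keeps a species if it is nonzero in at least 90% of
the samples of *any* diagnosis group (union across groups), with
presence defined on the floored abundances. `capReplicates()` retains at
most five randomly chosen samples per subject under a fixed seed.
Bray-Curtis dissimilarity is

$$BCD_{ij} = 1 - \frac{2 C_{ij}}{S_i + S_j},$$

with $C_{ij}$ the summed element-wise minima. `dissimilarityProfiles()`
computes within-subject (intrapersonal) and between-subject
(interpersonal) distributions per group; interpersonal pairs are formed
*within* groups, matching the per-group presentation such profiles are
reported in.

# Signature selection

`importanceRuns()` fits `R` (default 100) random forests of 500 trees on
all samples; each run appends a fresh noise column drawn from
$N(\hat\mu, \hat\sigma^2)$ with moments pooled over all CLR entries.
Importance is mean decrease in impurity, normalised to sum to 1 per run.
`significantFeatures()` takes candidates with mean importance above the
noise mean, tests each candidate's per-run importances against the noise
importances with a two-sided Mann-Whitney test, applies
Benjamini-Hochberg across candidates, and selects at $q < 0.05$.
Forest hyperparameters beyond tree count are the `ranger` defaults;
per-run seeds derive deterministically from the master seed.
`evaluateClassifier()` reports per-class and support-weighted F1 from a
stratified 70/30 split, plus the confusion table.

**Known limitation — the noise-referenced test is liberal under a
global null.** The repeated runs refit the *same* data, so a fixed
feature's importances are strongly correlated across runs (its
finite-sample association with the labels never changes), while the
noise column is redrawn fresh every run. The Mann-Whitney test treats
both sides as independent samples, so any feature whose persistent
importance sits modestly above the noise median is flagged. In
simulations with labels independent of all features ($n = 200$,
$D = 50$), roughly 25–35% of features are selected rather than the
nominal 5%, and the effect is insensitive to the importance measure
(impurity vs permutation), tree count, or per-run subsampling. The
selection should therefore be read as a liberal screen that reliably
keeps genuinely informative features (a 2-unit CLR separation is
selected essentially always) and discards only clearly uninformative
ones, not as an FDR-controlled feature test. The package implements the
procedure as published; the calibration shortfall is reported honestly
by the test suite.

# Consensus differential abundance

Per case-vs-control comparison, `consensusDa()` runs a two-sided
Mann-Whitney test per species on CLR values and applies BH across
species *within* that comparison (each control is its own family of
tests, matching the "compared individually" design). Fold change is the
ratio of zero-replaced geometric means of relative abundance — CLR
differences are not fold changes of a single taxon, and the geometric
mean is the compositional analogue of the mean; an arithmetic-mean
variant is available. A species reaches consensus when every comparison
gives $q < 0.05$, fold $\ge 2$, and the same direction. Adding a control
can therefore only shrink the consensus set.

# Association networks

The Gaussian graphical model encodes conditional independence in the
zeros of the precision matrix. `glassoPath()` maximises

$$\log\det\Omega - \mathrm{tr}(S\Omega) - \lambda\|\Omega\|_{1,\mathrm{off}}$$

by blockwise coordinate descent (compiled, warm-started along the
path) over the empirical covariance $S$ of the CLR data — the CLR
covariance approximates the log-absolute-abundance covariance, which is
what makes precision-matrix support meaningful for compositions.
Numerical choices: 30 log-spaced penalties from $\lambda_{max}$ (the
largest absolute off-diagonal of $S$, the smallest penalty giving an
empty graph) down to $0.01\lambda_{max}$; entries with magnitude above
$10^{-8}$ count as edges, guarding against solver dust.

`starsSelect()` re-estimates the path on 20 subsamples of size
$\lfloor 10\sqrt n \rfloor$ (without replacement) and computes per-pair
instability $2\hat\theta(1-\hat\theta)$; the selected penalty is the
smallest whose running-supremum instability stays at or below
$\beta = 0.1$ — the densest graph that is still stable. These are the
defaults of the standard StARS implementation; all are configurable.

`bootstrapStabilize()` refits at the selected penalty on $r = 50$
bootstrap resamples and keeps an edge of the full-data fit only if it is
nonzero in at least $f \cdot r$ refits ($f = 0.8$; exactly $40$ of $50$
is kept, $39$ is not). Stabilisation can only remove edges. Edge sign is
the sign of the partial correlation
$-\Omega'_{ij}/\sqrt{\Omega'_{ii}\Omega'_{jj}}$ (the published networks
show negative edges without defining the convention; the
partial-correlation sign is the one with a direct interpretation as
association direction). Replicates of one subject enter estimation as
independent samples — the model assumes one Gaussian per cohort — which
is a simplification the replicate cap partially offsets.

`eigenvectorCentrality()` solves $x_i \propto \sum_j A_{ij} x_j$ on the
unsigned adjacency by power iteration on $A + I$ (same eigenvectors;
the shift guarantees convergence on bipartite graphs). Disconnected
graphs are scored on the largest component, other nodes get zero, and
the result is normalised to unit Euclidean norm. `compareNetworks()`
reports unique and shared edge sets, top-$k$ centrality overlap, the
differential-abundance composition of each network's nodes, and the
fraction of negative edges touching case-elevated species.

At the benchmark scale used in the tests ($D = 30$, true edge density
0.1, $n = 500$), the full StARS + bootstrap pipeline recovers the
generator's support with edge-F1 around 0.72 (precision near 1; the
bootstrap rule trades recall for very few false edges).

# Functional capacity

`weightFamilyProfile()` forms per-sample family abundances
$\sum_s a_s\,\mathrm{count}(s, f)$ over the prevalent species, closes
them and applies CLR across families. Weighting by CLR values
themselves is ill-posed — CLR values of sub-geometric-mean species are
negative, so "weighted abundances" could be negative — so plain relative
abundances are the default weights and the literal CLR-weight variant is
available behind a flag for comparison. Per-sample profiles (rather than
one summed profile per cohort) are required for the across-sample
Mann-Whitney test to exist at all, which settles that ambiguity.
`familyDa()` reuses the consensus machinery over families, and
`aggregateRoles()` sums consensus families by functional role.

# Pipeline, seeds, problem sizes

`runPipeline()` executes the stages in the order described, writes every
stage output as TSV/JSON plus a provenance manifest (parameters, derived
stage seeds, package version — deliberately no timestamps), and is byte
deterministic under a fixed master seed. One master seed spawns fixed
per-stage offsets so stages remain individually reproducible.

The test suite exercises the stages at sizes a single CPU handles in
minutes while keeping every estimate well-identified: EM recovery at
300,000 reads and 5 genomes; differential-abundance recovery at 100
subjects per group and $D = 50$ over 20 seeds; classifier calibration at
$n = 200$, $D = 50$, 50 importance runs over 20 seeds; network recovery
at $n = 500$, $D = 30$ over 5 seeds; and the covariance-convergence
check at $n = 2000$, $D = 10$. The acceptance script
(`scripts/acceptance.R`) reruns the pipeline from scratch at these sizes
and writes the resulting quantities as JSON.

# Known limitations

* The signature-selection null calibration issue described above.
* The generator's groups share one covariance structure; differential
  *association* (group-specific precision matrices) is emulated only
  through planted mean shifts, so cross-network comparisons on synthetic
  data mostly measure estimation noise, not planted rewiring.
* Fold changes on the relative-abundance scale are squeezed by closure:
  a 4-fold absolute effect on a species holding a large share of the
  community measures as less than 4-fold relative (and can drop below
  the twofold rule if the species dominates the sample).
* The EM stage models alignment compatibility as flat weights; scoring
  information from the aligner, when present, is consumed as optional
  weights but not generated by the simulator.
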