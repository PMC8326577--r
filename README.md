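# miCompass

Compositional analysis of shotgun-metagenomic gut microbiome cohorts:
EM-based abundance profiling, CLR processing, random-forest signature
selection, multi-control consensus differential abundance, Gaussian
graphical-model association networks, and protein-family
functional-capacity comparison — with a synthetic-cohort generator whose
ground truth validates every stage.

## Who this is for

Case/control microbiome studies (the motivating setting is IBD with one
internal control and several external healthy cohorts) face two
recurring problems: sequencing data are *compositional* — only relative
abundances are observable, so naive correlations and mean comparisons
are spurious — and single-cohort findings often fail to generalise.
`miCompass` implements an analysis that addresses both: all testing is
done on centred log-ratio (CLR) transformed data,

```
CLR(x)_j = ln( x_j / G(x) ),   G(x) = (x_1 · x_2 · … · x_D)^(1/D),
```

and a finding only counts when it holds against *every* control group
(q < 0.05 by Mann-Whitney with Benjamini-Hochberg correction, at least a
twofold difference, same direction). Association structure is estimated
with a Gaussian graphical model: the l1-penalised precision matrix

```
Ω̂(λ) = argmax  log det Ω − tr(SΩ) − λ‖Ω‖₁,off
```

over the CLR covariance S, with the penalty chosen by StARS stability
selection and edges kept only when they reappear in ≥ f·r of r = 50
bootstrap refits (f = 0.8). Node influence is eigenvector centrality,
x_i ∝ Σ_j A_ij x_j.

## Worked example

Simulate a four-group cohort (case, internal control, two external
controls; replicate structure and metadata as in the default design)
with three planted twofold effects, then run the consensus
differential-abundance test and build the case group's association
network:

```r
library(miCompass)

spec <- defaultCohortSpec(seed = 42, D = 50,
    daSpec = data.frame(species = 1:3, group = "IBD", log2fc = c(2, 2, -2)))
gen <- generateCohort(spec)
gen$experiment
#> MicrobiomeExperiment: 50 species x 285 samples
#> groups: Healthy1=60, Healthy2=69, IBD=98, nonIBD=58
#> assays: relabund
gen$truth
#> SyntheticTruth: 50 species, 112 true edges, 3 planted DA species (seed 42)

me <- clrTransform(subsetSpecies(capReplicates(gen$experiment, 5, seed = 43),
                                 prevalenceFilter(gen$experiment)))
da <- consensusDa(me, "IBD", c("nonIBD", "Healthy1", "Healthy2"))
da
#> DaResult: IBD vs {nonIBD, Healthy1, Healthy2}: 3 consensus species
#> (2 elevated, 1 depleted)
head(subset(da$perComparison, species == "sp001"), 3)
#>     species  control    U            p            q     fold direction code
#> 1     sp001   nonIBD 4223 4.141704e-07 1.030993e-05 3.219266  elevated  ***
#> 51    sp001 Healthy1 4596 3.009785e-09 1.504893e-07 3.902978  elevated  ***
#> 101   sp001 Healthy2 4987 1.808111e-07 3.013519e-06 3.164832  elevated  ***

x <- t(clrValues(me)[, groupLabels(me) == "IBD"])
sel <- starsSelect(x, seed = 44)
net <- buildNetwork(bootstrapStabilize(x, sel$lambda, seed = 45))
net
#> AssociationNetwork: 50 nodes, 77 edges (50 negative)
round(head(sort(eigenvectorCentrality(net), decreasing = TRUE), 3), 3)
#> sp005 sp046 sp023
#> 0.338 0.337 0.334
```

The consensus table reads exactly as intended: `sp001` (planted at +2
log2 units in the case group) is significant against all three controls
with folds above 2 on the relative-abundance scale, so it is reported as
a consensus species elevated in IBD. The measured folds (~3.2–3.9 rather
than 4) show the compositional squeeze of closure. All three consensus
calls are the three planted species — nothing else clears the
every-control, twofold, same-direction bar.

`runPipeline(pipelineConfig(...), outDir)` executes the whole analysis
(diversity and dissimilarity profiles, signature selection, consensus
DA, per-group networks, functional capacity) and writes a deterministic,
timestamp-free result bundle; a thin command-line wrapper is available
at `inst/scripts/micompass.R`.

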