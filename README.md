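# MetaboCoNet

Integrative analysis of tumor metabolomics (1D ¹H-NMR) and bulk gene
expression through a weighted co-expression network. The package is aimed at
systems-biology groups who profile the same cohort with both assays and want
to know *which metabolites travel with which transcriptional programs* —
e.g. in glioblastoma, where metabolic state (lactate, choline compounds,
creatine, glycine) tracks expression subtypes.

## What it computes

1. **Metabolite quantification.** Spectra are calibrated to the lactate
   methyl resonance at 1.310 ppm, then fit by constrained template
   regression: minimize ‖y − (Σₘ cₘ Tₘ(δ−Δₘ) + poly(δ))‖₂ with cₘ ≥ 0,
   per-metabolite shift search on a grid, polynomial baseline, and a
   relative-residual QC gate. Intensities are normalized per sample by DNA
   concentration, then by a median-matching step.
2. **Co-expression network.** Pearson correlations are soft-thresholded
   (aᵢⱼ = |rᵢⱼ|^β, β chosen by scale-free fit), combined into the
   topological overlap matrix
   TOMᵢⱼ = (Σᵤ aᵢᵤaᵤⱼ + aᵢⱼ) / (min(kᵢ,kⱼ) + 1 − aᵢⱼ),
   and modules are cut from the average-linkage dendrogram of 1 − TOM.
   Module eigengenes (first PCs), kME (gene–eigengene correlation) and GS
   (gene–metabolite correlation) summarize the result.
3. **Integration.** Eigengenes are correlated with metabolites (exact t
   p-values, Benjamini–Hochberg FDR); modules and metabolites are jointly
   meta-clustered on their association-strength profiles ("Cluster of
   Clusters"); each meta-cluster's **key metabolite** maximizes the summed
   |r| to its modules; the bipartite module/gene–metabolite network is
   exported as a weighted edge list with hub flags.
4. **Enrichment.** Module genes ranked by normalized kME feed a
   permutation pre-ranked GSEA (weighted Kolmogorov running-sum ES,
   random-set null, BH FDR); a single-sample rank statistic converts a
   gene × sample matrix into a set × sample matrix.
5. **Cohort analyses.** Resampling consensus clustering with CDF/delta-area
   k selection, a random-forest subtype classifier with per-class
   sensitivity/specificity, Kaplan–Meier curves, log-rank tests and Cox
   hazard ratios.
6. **Synthetic cohorts.** A first-class generator plants co-expression
   modules (latent factors, configurable loadings), metabolites correlated
   with chosen modules at a target r, template-mixture spectra at a chosen
   SNR, subtype labels and exponential survival — so every stage is
   validated against known ground truth.

## Worked example

Simulate a cohort with four planted modules, bind one metabolite to each at
r = 0.8, build the network and integrate:

```r
library(MetaboCoNet)

cfg <- simulationConfig(
  nSamples = 60, nModules = 4, genesPerModule = 40, nBackgroundGenes = 300,
  metaboliteSpec = data.frame(
    metabolite = c("lactate", "creatine", "glycine", "choline"),
    module = c(1, 2, 3, 4), r = 0.8),
  seed = 7)
sim  <- simulateExpression(cfg)
mets <- simulateMetabolites(sim$factors, cfg$metaboliteSpec, seed = 8)

net <- buildNetwork(sim$expression, networkConfig())
net
#> CoexpressionNetwork: 460 genes, beta = 6, 4 modules (298 unassigned)

cm <- correlateModulesMetabolites(eigengenes(net), mets$metabolites)
round(cm@r, 2)
#>     lactate creatine glycine choline
#> ME1    0.79    -0.11    0.04   -0.15
#> ME2   -0.05     0.74    0.18    0.04
#> ME3   -0.02     0.15    0.72   -0.17
#> ME4    0.02    -0.22   -0.20    0.83

mc <- clusterOfClusters(cm, k = 4)
keyMetabolites(mc, cm)
#>   cluster metabolite     score
#> 1       1    lactate 0.7881193
#> 2       2   creatine 0.7362344
#> 3       3    glycine 0.7203413
#> 4       4    choline 0.8344525
```

All four detected modules recover their planted factor (the diagonal of the
correlation matrix sits near the planted r = 0.8), each metabolite
meta-clusters with its module, and the key metabolite of every cluster is
the planted one; its score is the summed |r| to the cluster's modules.

The whole workflow — NMR fitting, normalization, network, integration,
enrichment, consensus clustering, survival — also runs end-to-end from one
configuration via `runFullPipeline()` (YAML or list), writing every
intermediate table plus a JSON run report, deterministically for a fixed
seed.

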