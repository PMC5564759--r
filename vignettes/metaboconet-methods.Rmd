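---
title: "MetaboCoNet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaboCoNet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboCoNet)
```

MetaboCoNet integrates two tumor-cohort assays — metabolite intensities
quantified from 1D ^1^H-NMR spectra and bulk gene expression — through a
weighted co-expression network. This vignette explains each model, the
parameters that matter, and the choices made where the design was genuinely
open. Everything stated here is computed by the package's test suite or the
acceptance script; no external data are required.

## Metabolite quantification from 1D spectra

A spectrum is a pair (ppm axis, intensity). Because spectrometer frequency
referencing drifts, the axis is first **calibrated**: the maximum-intensity
point inside a window around the lactate methyl resonance is shifted onto
the 1.310 ppm reference (`calibrateToLactate()`). A window without a strict
apex is an error; tied maxima resolve to the smallest |offset|.

Quantification is a **constrained template regression**
(`fitSpectrum()`). Each metabolite m has a static template
$T_m(\delta) = \sum_p a_{mp}\, L(\delta; c_{mp}, w_{mp})$ — a mixture of
unit-area Lorentzian (or Gaussian) lines with fixed centers $c$, relative
areas $a$ (summing to 1) and full widths at half maximum $w$; multiplet fine
structure is encoded in the peak list rather than modelled from coupling
constants. The fit minimizes

$$\Big\lVert y - \Big(\textstyle\sum_m c_m\, T_m(\delta - \Delta_m)
  + \mathrm{poly}(\delta)\Big)\Big\rVert_2,
  \qquad c_m \ge 0,\; |\Delta_m| \le \texttt{maxShift},$$

by nonnegative least squares for the concentrations at every candidate
shift, with one pass of per-metabolite coordinate search over the shift grid
in library order (ties toward the smaller |shift|, so the objective is
non-increasing and the result deterministic). The polynomial baseline
(default degree 3) is unconstrained in sign, implemented as paired
positive/negative columns inside the NNLS. This is a deliberately
deterministic, desk-scale estimator — a stand-in for Bayesian spectral
deconvolution, not a reimplementation of it.

Fit quality is the relative residual
$\lVert y-\hat y\rVert_2 / \lVert y\rVert_2$; a spectrum passes QC at
$\le$ `qcThreshold` (default **0.25**). Note the residual is computed over
the whole axis, where noise accumulates across the flat baseline: on the
default 0.5–4.5 ppm grid a peak signal-to-noise ratio of about 50 gives a
relative residual near 0.33 (fails QC) while SNR ≳ 100 passes. Concentration
*recovery* is far more forgiving than the gate: at SNR 50 all concentrations
are typically recovered within 10%.

Key parameters (ppm units throughout): `maxShift` 0.01, `shiftGridStep`
0.001, `baselineDegree` 3, `qcThreshold` 0.25. The shipped template library
covers lactate, creatine, glycine, choline, phosphocholine and
myo-inositol with literature chemical shifts; the lactate methyl doublet's
taller line sits exactly on the 1.310 ppm calibration reference.

## Two-step normalization

`normalizeDNA()` divides each sample's raw intensities by that sample's DNA
concentration, balancing tissue amount per extract. `normalizeMedian()` then
rescales every column to a common median: column $j$ becomes
$(x/\mathrm{med}_j)\cdot r$ with $r$ the median of all column medians, so
all medians coincide exactly afterwards. A consequence of the data-driven
reference: multiplying one raw column by a positive constant is an exact
fixed point of the composed normalization *when the rescaling does not move
the median-of-medians* (always true for the extreme-median columns); a
rescaling that changes the reference rescales all columns by the new
reference, i.e. invariance holds up to that global factor.

## Weighted co-expression network

Pearson correlation on gene rows (pairwise-complete over samples; constant
genes dropped with a warning) is soft-thresholded into an adjacency:
unsigned $a_{ij} = |r_{ij}|^\beta$ (default), signed
$((1+r_{ij})/2)^\beta$. The power is chosen by scale-free fit: connectivity
$k_i = \sum_{j\ne i} a_{ij}$ is binned, $\log_{10} p(k)$ regressed on
$\log_{10} k$, and the fit index is the $R^2$ (negated for a positive
slope); the smallest candidate reaching `targetR2` wins, otherwise the
best-fitting candidate with a warning.

**Why candidates start at 6 and the target is 0.85.** On cohorts with
planted modules at realistic loadings the fit index plateaus around
0.85–0.95 from power ~5 onward, fluctuating a few hundredths between
generator seeds — so no fit threshold alone pins a stable power, while
module recovery itself is essentially perfect for any $\beta \in [6, 12]$.
The defaults therefore follow the customary floor for unsigned networks at
cohort sample sizes (40+ samples → power 6) and accept the plateau at 0.85.
Both are ordinary configuration for other data.

The topological overlap matrix combines direct adjacency with shared
neighbourhood:

$$\mathrm{TOM}_{ij} = \frac{\sum_{u\ne i,j} a_{iu}a_{uj} + a_{ij}}
  {\min(k_i,k_j) + 1 - a_{ij}},\qquad \mathrm{TOM}_{ii}=1 .$$

Modules come from average-linkage clustering of $1-\mathrm{TOM}$ with a
**static cut** (default height 0.99, minimum size 20); clusters below the
minimum are left unassigned (label 0) and modules are numbered by
decreasing size. Dynamic tree-cut variants, module merging and block-wise
decomposition are out of scope.

Each module is summarized by its **eigengene** — the first principal
component of the row-standardized module submatrix, as per-sample scores
scaled to sd 1 and oriented so the mean correlation with the module's genes
is positive (a canonical orientation; PCA signs are otherwise arbitrary).
Gene-level statistics: **kME** (module membership) is the correlation of a
gene with every module's eigengene; **GS** (gene significance) is the
correlation of a gene with each metabolite over the *intersection* of
samples present in both assays (the two assays rarely cover identical
patients; at least 3 shared samples are required, and the overlap size is
recorded).

## Module–metabolite integration

`correlateModulesMetabolites()` computes Pearson r over shared samples,
two-sided p-values from the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df, and Benjamini–Hochberg
adjustment across the whole module × metabolite matrix.

The **"Cluster of Clusters"** places modules and metabolites in one space.
Each module is embedded as its *association-strength profile* — the vector
of |r| across metabolites — and each metabolite as its |r| profile across
modules. Similarity is the Pearson correlation of those absolute profiles
(module–module, metabolite–metabolite) and the direct |r| for
module–metabolite pairs; entities are clustered by average linkage on
1 − similarity and cut to k clusters (default 4; automatic mode maximizes
the mean silhouette over k ∈ 2..8). Absolute profiles are essential for two
reasons: the embedding must not depend on the arbitrary sign of an
eigengene, and *signed* profiles of two modules with distinct
single-metabolite signatures are strongly anti-correlated, which a naive
|correlation-of-signed-profiles| similarity would invert into high
similarity and merge exactly the modules that should separate.

The **key metabolite** of a meta-cluster maximizes
$\sum_{\text{modules in cluster}} |r(\text{module}, \text{metabolite})|$,
ties broken lexicographically with a warning; metabolite-free clusters are
reported keyless. `exportNetwork()` emits the bipartite edge list
(|r| ≥ threshold, default 0.5, optionally joined by gene–metabolite GS
edges), weighted node degrees, and hub flags above the 0.9 score quantile.

## Connectivity-ranked enrichment

For a module, genes are ranked by kME normalized by the module's maximum
|kME| (top gene = 1; ties sort lexicographically). `prerankedGSEA()` runs
the weighted Kolmogorov running sum: hits add
$|s|^{p}/\sum_{\text{hits}}|s|^{p}$ (default weight $p=1$; $p=0$ gives the
classic KS form), misses subtract $1/(N-|S|)$, and the enrichment score is
the extremum of largest magnitude. The permutation null draws `nPerm`
random same-size gene sets from the ranked universe (pre-ranked mode has no
phenotypes to permute); the two-sided p-value uses the
$(1+\#\{|ES_\pi|\ge|ES|\})/(n_{perm}+1)$ convention so it is never zero and
valid at finite permutations, NES divides ES by the mean |permuted ES| of
the same sign, and FDR across sets is Benjamini–Hochberg.

`perSampleEnrichment()` converts a gene × sample matrix into a set × sample
matrix with a single-sample rank statistic: within each sample the score is
the integral of the difference between the rank-weighted ECDF of set genes
(weight rank^0.25) and the ECDF of non-set genes along the
decreasing-expression ordering. It is a rank statistic — invariant to any
monotone per-sample transformation — and a deliberate, documented stand-in
for kernel-CDF set-variation scores.

## Cohort-level analyses

`consensusCluster()` implements the resampling consensus scheme: at each of
`reps` repetitions (default 100) a fraction (default 0.8) of samples is
drawn, clustered by average-linkage/Euclidean hierarchical clustering, and
co-membership counts are normalized by co-sampling counts per k ∈ 2..kmax.
Stability is the area under the consensus CDF, computed as the
left-continuous step integral over [0, 1] (a binary consensus with
proportion $p_0$ of zeros has area $p_0$; a right-endpoint sum would make
every binary consensus area 1 and destroy k selection). The selected k is
the argmax of the relative area increase over k ≥ 3 (k = 2 when kmax = 2) —
an explicit rule in place of visual CDF inspection. Final labels cluster
1 − consensus.

Subtype classification is a bagged-tree ensemble (random forest) over genes
as features — ordinary supervised plumbing, evaluated by per-class and
macro sensitivity/specificity from the confusion matrix. Published
headline accuracies of such classifiers depend on their specific training
cohorts and are not comparable targets for synthetic data.

Survival: the Kaplan–Meier product-limit estimator and the log-rank test
(observed − expected with hypergeometric variance, $\chi^2$ on
groups − 1 df) are implemented directly so their closed forms are testable
against hand calculations; the Cox hazard ratio is delegated to the
`survival` package's partial-likelihood fit (cross-checked in tests against
`survdiff` for the log-rank path).

## The synthetic cohort generator

`simulateExpression()` plants K independent standard-normal latent factors
$E_m$ over samples; a module gene is
$x_g = u_g E_m + \sqrt{1-u_g^2}\,\varepsilon$ with loading $u_g$ uniform on
`loadingRange`, background genes are pure noise, and rows are standardized
*after* noise injection so loadings are exactly gene–factor correlations.
`simulateMetabolites()` reuses the *same* factor values:
$y = r E_k + \sqrt{1-r^2}\,\varepsilon$, guaranteeing the cross-omic signal
the integration stage must find. Spectra are noisy template mixtures with
known concentrations, shifts and SNR; survival is exponential with
group-specific hazards and independent exponential censoring tuned to the
requested censored fraction. Every generator runs in its own seeded RNG
stream and leaves the global RNG untouched.

Reference conditions used throughout validation: 6 modules × 50 genes, 700
background genes, 60 samples, loadings 0.6–0.95 (real within-module
correlation strength is rarely reported; these are a one-time choice
exposed in the config), metabolites bound at r = 0.8. Validation problem
sizes (e.g. 50-seed integration recovery, 20-seed SNR-50 fitting, a
24-sample end-to-end determinism cohort) are the package's chosen
compromise between statistical resolution and a test suite that runs in
minutes.

What the generator deliberately does **not** emulate — and hence what
passing tests do not certify on real data: overlapping/correlated biological
modules (factors are independent to make recovery measurable), batch and
array probe-level artifacts, heavy-tailed expression noise, realistic NMR
baseline drift beyond a low-order polynomial, J-coupling lineshape
distortions, peak-width variation between samples, and non-exponential
hazards.

## Numerical conventions and degenerate inputs

- Deterministic tie-breaks everywhere: shift search toward the smaller
  |shift|; gene ranking and key metabolites lexicographic; calibration ties
  toward the smaller |offset|.
- Degenerate inputs fail loudly: all-zero or non-finite spectra, windows
  outside the axis, flat calibration windows, constant genes (dropped with
  a warning), < 3 shared samples, zero-median columns, groups without
  events, k larger than the entity count.
- Correlations use pairwise-complete observations; `NA` is the missing-value
  encoding in all TSV formats; matrices are written with 17 significant
  digits so pipelines round-trip byte-identically.
- `runFullPipeline()` propagates one seed to every stochastic stage and
  aborts with the failing stage's name while preserving earlier outputs.

## Known limitations

Template regression assumes the library spans the spectrum; unmodelled
metabolites bias concentrations of overlapping neighbours. The static
dendrogram cut is the simplest defensible module-detection rule and is
sensitive to extreme soft powers (the default power range avoids that
regime). Meta-clustering on association strength treats anti-correlated
metabolites as associated, which is intended but worth knowing. The
per-sample enrichment statistic is not numerically comparable to kernel-CDF
implementations, only rank-equivalent in its orderings.
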