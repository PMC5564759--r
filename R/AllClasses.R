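#' @import methods
NULL

#' One-dimensional NMR spectrum
#'
#' A 1D \eqn{^1}H-NMR spectrum as a pair of equal-length vectors: the chemical
#' shift axis in ppm and the corresponding intensities. The axis is always
#' stored ascending; constructors accept descending input (the common
#' instrument convention) and reorder both vectors.
#'
#' @slot ppm strictly increasing numeric vector of chemical shifts (ppm).
#' @slot intensity numeric vector of intensities, same length as \code{ppm}.
#' @slot sampleId single character identifier for the sample.
#'
#' @seealso [readSpectrum()], [calibrateToLactate()], [fitSpectrum()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(ppm = "numeric", intensity = "numeric",
                 sampleId = "character"),
  prototype(sampleId = NA_character_))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2 && any(diff(object@ppm) <= 0))
    msg <- c(msg, "ppm axis must be strictly monotone increasing")
  if (length(object@sampleId) != 1)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param ppm numeric chemical-shift axis (ppm), strictly monotone; a
#'   descending axis is accepted and stored ascending.
#' @param intensity numeric intensities matching \code{ppm}.
#' @param sampleId optional sample identifier.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(c(4, 3, 2, 1), c(0, 1, 2, 3), "s1")
#' ppm(s)  # ascending
#' @export
Spectrum <- function(ppm, intensity, sampleId = NA_character_) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) >= 2 && all(diff(ppm) < 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  new("Spectrum", ppm = ppm, intensity = intensity,
      sampleId = as.character(sampleId))
}

#' Metabolite peak template
#'
#' Parametric template for one metabolite: a static list of resonance peaks
#' (multiplet fine structure is encoded in the peak list, not modelled), each
#' with a center in ppm, a relative area (areas sum to 1) and a full width at
#' half maximum. The lineshape is Lorentzian or Gaussian.
#'
#' @slot name metabolite identifier.
#' @slot lineshape one of \code{"lorentzian"}, \code{"gaussian"}.
#' @slot peaks data.frame with columns \code{center}, \code{relative_area},
#'   \code{linewidth} (all numeric; linewidth is FWHM in ppm).
#' @exportClass MetaboliteTemplate
setClass("MetaboliteTemplate",
  representation(name = "character", lineshape = "character",
                 peaks = "data.frame"))

setValidity("MetaboliteTemplate", function(object) {
  msg <- character()
  need <- c("center", "relative_area", "linewidth")
  if (!all(need %in% names(object@peaks)))
    msg <- c(msg, "peaks needs columns center, relative_area, linewidth")
  else {
    if (any(object@peaks$linewidth <= 0))
      msg <- c(msg, "linewidths must be positive")
    if (any(object@peaks$relative_area <= 0))
      msg <- c(msg, "relative areas must be positive")
    if (abs(sum(object@peaks$relative_area) - 1) > 1e-6)
      msg <- c(msg, "relative areas must sum to 1")
  }
  if (!object@lineshape %in% c("lorentzian", "gaussian"))
    msg <- c(msg, "lineshape must be 'lorentzian' or 'gaussian'")
  if (length(msg)) msg else TRUE
})

#' Library of metabolite templates
#'
#' @slot templates named list of [MetaboliteTemplate-class] objects.
#' @seealso [readTemplateLibrary()], [defaultTemplateLibrary()]
#' @exportClass TemplateLibrary
setClass("TemplateLibrary", representation(templates = "list"))

setValidity("TemplateLibrary", function(object) {
  msg <- character()
  if (!length(object@templates))
    msg <- c(msg, "library must contain at least one template")
  if (!all(vapply(object@templates, is, logical(1), "MetaboliteTemplate")))
    msg <- c(msg, "all elements must be MetaboliteTemplate objects")
  nm <- vapply(object@templates, function(t) t@name, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, "duplicate metabolite names in library")
  if (length(msg)) msg else TRUE
})

#' Result of fitting a spectrum against a template library
#'
#' @slot intensities named nonnegative numeric, one entry per metabolite
#'   (arbitrary spectral units).
#' @slot shifts named numeric, fitted per-metabolite chemical-shift offsets
#'   (ppm).
#' @slot baselineCoeffs numeric polynomial coefficients of the fitted baseline
#'   (constant term first, on the rescaled ppm axis).
#' @slot relativeResidual L2 norm of the residual divided by the L2 norm of
#'   the observed spectrum.
#' @slot passedQC logical; TRUE when relativeResidual is at or below the
#'   configured quality threshold.
#' @slot fitted numeric fitted spectrum on the observed ppm grid.
#' @slot sampleId sample identifier carried over from the spectrum.
#' @exportClass SpectrumFit
setClass("SpectrumFit",
  representation(intensities = "numeric", shifts = "numeric",
                 baselineCoeffs = "numeric", relativeResidual = "numeric",
                 passedQC = "logical", fitted = "numeric",
                 sampleId = "character"))

setValidity("SpectrumFit", function(object) {
  msg <- character()
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (object@relativeResidual < 0)
    msg <- c(msg, "relativeResidual must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Metabolite-by-sample intensity matrix with a normalization stage
#'
#' @slot values metabolites x samples numeric matrix with dimnames.
#' @slot stage one of \code{"raw"}, \code{"dna_normalized"},
#'   \code{"median_normalized"}. Raw intensities must be nonnegative.
#' @exportClass MetaboliteMatrix
setClass("MetaboliteMatrix",
  representation(values = "matrix", stage = "character"))

setValidity("MetaboliteMatrix", function(object) {
  msg <- character()
  if (!object@stage %in% c("raw", "dna_normalized", "median_normalized"))
    msg <- c(msg, "unknown normalization stage")
  if (identical(object@stage, "raw") &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "raw intensities must be nonnegative")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "values must carry metabolite and sample names")
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboliteMatrix
#' @param values metabolites x samples numeric matrix with dimnames.
#' @param stage normalization stage label.
#' @return A [MetaboliteMatrix-class].
#' @export
MetaboliteMatrix <- function(values, stage = "raw") {
  new("MetaboliteMatrix", values = as.matrix(values), stage = stage)
}

#' Weighted co-expression network state
#'
#' Holds every artifact of the network stage: the chosen soft power and its
#' scale-free fit table, adjacency and topological overlap matrices, the
#' module partition (0 = unassigned), module eigengenes, eigengene-based
#' connectivity (kME) and, when metabolites were supplied, gene significance.
#'
#' @slot beta chosen soft-thresholding power.
#' @slot fitTable data.frame of candidate powers and scale-free fit indices.
#' @slot adjacency gene x gene weighted adjacency in [0,1].
#' @slot tom gene x gene topological overlap matrix in [0,1].
#' @slot moduleLabels named integer vector, gene -> module id (0 unassigned).
#' @slot eigengenes module x sample matrix of eigengene profiles (sd 1).
#' @slot kme gene x module matrix of gene-eigengene correlations.
#' @slot gs gene x metabolite matrix of gene significance (may be 0 x 0).
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(beta = "numeric", fitTable = "data.frame",
                 adjacency = "matrix", tom = "matrix",
                 moduleLabels = "integer", eigengenes = "matrix",
                 kme = "matrix", gs = "matrix"))

#' Module-metabolite correlation result
#'
#' @slot r module x metabolite Pearson correlation matrix.
#' @slot p matched matrix of two-sided p-values from the exact t transform.
#' @slot padj matched matrix after Benjamini-Hochberg adjustment across the
#'   whole matrix.
#' @slot nOverlap number of shared samples used.
#' @exportClass ModuleMetaboliteCorrelation
setClass("ModuleMetaboliteCorrelation",
  representation(r = "matrix", p = "matrix", padj = "matrix",
                 nOverlap = "integer"))

setValidity("ModuleMetaboliteCorrelation", function(object) {
  msg <- character()
  if (!identical(dim(object@r), dim(object@p)) ||
      !identical(dim(object@r), dim(object@padj)))
    msg <- c(msg, "r, p and padj must share dimensions")
  if (any(object@padj < object@p - 1e-12, na.rm = TRUE))
    msg <- c(msg, "adjusted p-values cannot be smaller than raw p-values")
  if (length(msg)) msg else TRUE
})

#' Joint meta-clustering of modules and metabolites ("Cluster of Clusters")
#'
#' @slot labels data.frame with columns \code{entity}, \code{type}
#'   (\code{"module"} or \code{"metabolite"}) and \code{cluster}.
#' @slot nClusters number of meta-clusters.
#' @slot tree the average-linkage \code{hclust} merge history.
#' @exportClass MetaClustering
setClass("MetaClustering",
  representation(labels = "data.frame", nClusters = "integer",
                 tree = "ANY"))

setValidity("MetaClustering", function(object) {
  msg <- character()
  if (!all(c("entity", "type", "cluster") %in% names(object@labels)))
    msg <- c(msg, "labels needs entity, type, cluster columns")
  else if (anyDuplicated(paste(object@labels$entity, object@labels$type)))
    msg <- c(msg, "every entity must be assigned exactly one cluster")
  if (length(msg)) msg else TRUE
})

#' Bipartite module/gene-metabolite association network
#'
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{weight} (signed correlation, |weight| <= 1) and \code{type}.
#' @slot nodeScores named numeric, weighted degree (sum of |weight|) per node.
#' @slot hubs character vector of node ids above the hub quantile.
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(edges = "data.frame", nodeScores = "numeric",
                 hubs = "character"))

setValidity("BipartiteNetwork", function(object) {
  msg <- character()
  if (nrow(object@edges) && any(abs(object@edges$weight) > 1 + 1e-12))
    msg <- c(msg, "edge weights are correlations and must lie in [-1,1]")
  if (!all(object@hubs %in% names(object@nodeScores)))
    msg <- c(msg, "hubs must be a subset of scored nodes")
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result (resampling-based)
#'
#' @slot consensus named list of per-k sample x sample consensus matrices.
#' @slot cdfArea named numeric, area under the consensus CDF per k.
#' @slot deltaArea named numeric, relative increase in CDF area per k.
#' @slot bestK selected number of clusters.
#' @slot labels samples x k matrix of final cluster labels per candidate k.
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(consensus = "list", cdfArea = "numeric",
                 deltaArea = "numeric", bestK = "integer",
                 labels = "matrix"))

#' Synthetic multi-omic cohort with known ground truth
#'
#' @slot expression genes x samples matrix, rows standardized.
#' @slot moduleLabels named integer, gene -> planted module (0 background).
#' @slot factors module x sample matrix of latent module factors.
#' @slot metabolites metabolites x samples matrix.
#' @slot associations data.frame (metabolite, module, r) of planted links.
#' @slot survival data.frame (sample, time, event, group).
#' @slot subtypes named character, sample -> planted subtype label.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(expression = "matrix", moduleLabels = "integer",
                 factors = "matrix", metabolites = "matrix",
                 associations = "data.frame", survival = "data.frame",
                 subtypes = "character"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (length(object@moduleLabels) != nrow(object@expression))
    msg <- c(msg, "one module label per gene required")
  if (ncol(object@metabolites) &&
      ncol(object@metabolites) != ncol(object@expression))
    msg <- c(msg, "expression and metabolites must share samples")
  if (length(msg)) msg else TRUE
})
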