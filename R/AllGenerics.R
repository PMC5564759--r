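#' Accessors for MetaboCoNet classes
#'
#' Small accessor family: \code{ppm()} and \code{intensity()} for spectra,
#' \code{values()} and \code{stage()} for metabolite matrices,
#' \code{moduleLabels()}, \code{eigengenes()} and \code{kme()} for networks,
#' \code{consensusMatrix()} and \code{bestK()} for consensus results.
#'
#' @param object an object of the matching class.
#' @param k candidate cluster number for \code{consensusMatrix}.
#' @return The slot contents (vector, matrix or scalar as documented per
#'   class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("stage", function(object) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setGeneric("kme", function(object) standardGeneric("kme"))
#' @rdname accessors
#' @export
setGeneric("geneSignif", function(object) standardGeneric("geneSignif"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix",
           function(object, k) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("bestK", function(object) standardGeneric("bestK"))
#' @rdname accessors
#' @export
setGeneric("metaLabels", function(object) standardGeneric("metaLabels"))
#' @rdname accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname accessors
setMethod("ppm", "Spectrum", function(object) object@ppm)
#' @rdname accessors
setMethod("intensity", "Spectrum", function(object) object@intensity)
#' @rdname accessors
setMethod("values", "MetaboliteMatrix", function(object) object@values)
#' @rdname accessors
setMethod("stage", "MetaboliteMatrix", function(object) object@stage)
#' @rdname accessors
setMethod("moduleLabels", "CoexpressionNetwork",
          function(object) object@moduleLabels)
#' @rdname accessors
setMethod("moduleLabels", "SyntheticCohort",
          function(object) object@moduleLabels)
#' @rdname accessors
setMethod("eigengenes", "CoexpressionNetwork",
          function(object) object@eigengenes)
#' @rdname accessors
setMethod("kme", "CoexpressionNetwork", function(object) object@kme)
#' @rdname accessors
setMethod("geneSignif", "CoexpressionNetwork", function(object) object@gs)
#' @rdname accessors
setMethod("consensusMatrix", "ConsensusResult", function(object, k) {
  key <- as.character(k)
  if (!key %in% names(object@consensus))
    stop("no consensus matrix stored for k = ", k)
  object@consensus[[key]]
})
#' @rdname accessors
setMethod("bestK", "ConsensusResult", function(object) object@bestK)
#' @rdname accessors
setMethod("metaLabels", "MetaClustering", function(object) object@labels)
#' @rdname accessors
setMethod("edges", "BipartiteNetwork", function(object) object@edges)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", if (!is.na(object@sampleId)) object@sampleId else "",
      "\n  points:", length(object@ppm))
  if (length(object@ppm))
    cat(sprintf("  ppm range: [%.4f, %.4f]", min(object@ppm),
                max(object@ppm)))
  cat("\n")
})

setMethod("show", "TemplateLibrary", function(object) {
  nm <- vapply(object@templates, function(t) t@name, character(1))
  cat("TemplateLibrary with", length(nm), "metabolites:\n ",
      paste(nm, collapse = ", "), "\n")
})

setMethod("show", "SpectrumFit", function(object) {
  cat("SpectrumFit",
      if (!is.na(object@sampleId)) object@sampleId else "", "\n")
  cat(sprintf("  relative residual: %.4g (QC %s)\n",
              object@relativeResidual,
              if (object@passedQC) "passed" else "failed"))
  print(round(object@intensities, 4))
})

setMethod("show", "MetaboliteMatrix", function(object) {
  cat(sprintf("MetaboliteMatrix: %d metabolites x %d samples, stage '%s'\n",
              nrow(object@values), ncol(object@values), object@stage))
})

setMethod("show", "CoexpressionNetwork", function(object) {
  nmod <- sum(unique(object@moduleLabels) != 0)
  cat(sprintf(
    "CoexpressionNetwork: %d genes, beta = %g, %d modules (%d unassigned)\n",
    length(object@moduleLabels), object@beta, nmod,
    sum(object@moduleLabels == 0)))
})

setMethod("show", "ModuleMetaboliteCorrelation", function(object) {
  cat(sprintf(
    "ModuleMetaboliteCorrelation: %d modules x %d metabolites (n = %d)\n",
    nrow(object@r), ncol(object@r), object@nOverlap))
})

setMethod("show", "MetaClustering", function(object) {
  cat(sprintf("MetaClustering: %d entities in %d clusters\n",
              nrow(object@labels), object@nClusters))
  print(table(object@labels$cluster, object@labels$type))
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf("BipartiteNetwork: %d edges, %d nodes, %d hubs\n",
              nrow(object@edges), length(object@nodeScores),
              length(object@hubs)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k in {%s}, best k = %d\n",
              paste(names(object@consensus), collapse = ", "),
              object@bestK))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d genes x %d samples, %d planted modules, %d metabolites\n",
    nrow(object@expression), ncol(object@expression),
    length(setdiff(unique(object@moduleLabels), 0L)),
    nrow(object@metabolites)))
})
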