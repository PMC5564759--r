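#' Write a synthetic cohort to disk
#'
#' Emits expression.tsv and metabolites.tsv (genes/metabolites x samples),
#' survival.tsv, truth.json (module labels, planted associations, subtype
#' labels) and, when requested, spectra/<sample>.tsv simulated from the
#' template library using the cohort's metabolite values as concentrations
#' (shifted to be positive).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @param spectra logical; also write per-sample simulated spectra.
#' @param library template library for spectrum simulation.
#' @param snr signal-to-noise of the simulated spectra.
#' @param seed integer seed for spectrum noise.
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir, spectra = FALSE,
                        library = defaultTemplateLibrary(), snr = 150,
                        seed = 1) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMatrixTSV(cohort@expression, file.path(dir, "expression.tsv"),
                 idColumn = "gene")
  # latent metabolite levels are z-scale; exported intensities are shifted
  # positive (correlations are shift-invariant)
  conc <- cohort@metabolites
  if (nrow(conc))
    conc <- conc - min(conc) + 0.5
  if (nrow(conc))
    writeMatrixTSV(conc, file.path(dir, "metabolites.tsv"),
                   idColumn = "metabolite")
  writeSurvivalTable(cohort@survival, file.path(dir, "survival.tsv"))
  jsonlite::write_json(
    list(moduleLabels = as.list(cohort@moduleLabels),
         associations = cohort@associations,
         subtypes = as.list(cohort@subtypes)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (spectra && nrow(cohort@metabolites)) {
    specDir <- file.path(dir, "spectra")
    dir.create(specDir, showWarnings = FALSE)
    libNames <- vapply(library@templates, function(t) t@name,
                       character(1))
    mets <- intersect(rownames(conc), libNames)
    if (!length(mets))
      stop("no cohort metabolite matches the template library")
    conc <- conc[mets, , drop = FALSE]
    for (j in seq_len(ncol(conc))) {
      sid <- colnames(conc)[j]
      sim <- simulateSpectrum(conc[, j], library, snr = snr,
                              seed = seed + j, sampleId = sid)
      writeSpectrum(sim$spectrum, file.path(specDir,
                                            paste0(sid, ".tsv")))
    }
  }
  invisible(dir)
}

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or a named list. Recognized fields:
#' \code{expression} (TSV path, required), \code{metabolites} (TSV path) or
#' \code{spectra} (directory of spectrum TSVs) with \code{templates}
#' (JSON path, default library when omitted) and \code{dna} (TSV path:
#' sample, concentration), \code{gmt} (gene set file), \code{survival}
#' (TSV path), \code{outdir} (required), \code{seed}, plus optional
#' parameter blocks \code{network}, \code{fit}, \code{integration}
#' (\code{k}, \code{edgeThreshold}, \code{hubQuantile}), \code{gsea}
#' (\code{weightP}, \code{nPerm}), \code{consensus} (\code{kmax},
#' \code{reps}, \code{fraction}).
#'
#' @param config list or YAML path.
#' @return validated config list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  if (is.null(config$expression))
    stop("config error: 'expression' input is required")
  if (is.null(config$outdir))
    stop("config error: 'outdir' is required")
  if (is.null(config$seed))
    config$seed <- 1L
  if (is.null(config$metabolites) && is.null(config$spectra))
    stop("config error: provide 'metabolites' or 'spectra'")
  for (f in c("expression", "metabolites", "spectra", "templates",
              "dna", "gmt", "survival")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config error: ", f, " path '", config[[f]],
           "' does not exist")
  }
  class(config) <- "pipeline_config"
  config
}

#' Run the full integrative pipeline
#'
#' Executes the stages in workflow order: metabolite quantification from
#' spectra (calibration, template fit, QC) when spectra are supplied,
#' two-step normalization (DNA concentration, then median), co-expression
#' network with module detection, module-metabolite integration
#' (correlations, meta-clusters, key metabolites, bipartite edges),
#' per-module pre-ranked enrichment when a GMT is supplied, consensus
#' clustering of samples, and survival tests when a survival table is
#' supplied. Every intermediate table is written under \code{outdir}
#' together with a JSON run report. A stage failure aborts with the stage
#' name; earlier outputs are preserved.
#'
#' @param config a [pipelineConfig()] input (list or YAML path).
#' @return the run report (named list), invisibly; also written as
#'   \code{report.json}.
#' @export
runFullPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, stages = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  expr <- stage("read-expression",
                readMatrixTSV(cfg$expression, "expression"))

  ## metabolite quantification / normalization -------------------------
  if (!is.null(cfg$spectra)) {
    fitStage <- stage("fit-nmr", {
      lib <- if (!is.null(cfg$templates))
        readTemplateLibrary(cfg$templates) else defaultTemplateLibrary()
      fitCfg <- do.call(fitConfig, cfg$fit %||% list())
      files <- sort(list.files(cfg$spectra, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files))
        stop("no spectra found under '", cfg$spectra, "'")
      spectra <- lapply(files, readSpectrum)
      quantifySpectra(spectra, lib, fitCfg)
    })
    met <- fitStage$matrix
    report$qcExcluded <- fitStage$excluded
  } else {
    met <- stage("read-metabolites",
      MetaboliteMatrix(pmax(readMatrixTSV(cfg$metabolites,
                                          "metabolites"), 0), "raw"))
  }
  met <- stage("normalize", {
    if (!is.null(cfg$dna)) {
      dna <- utils::read.table(cfg$dna, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      met <- normalizeDNA(met, stats::setNames(dna[[2]], dna[[1]]))
    }
    normalizeMedian(met)
  })
  writeMatrixTSV(values(met),
                 file.path(cfg$outdir, "metabolites_normalized.tsv"),
                 idColumn = "metabolite")

  ## network ------------------------------------------------------------
  net <- stage("network", {
    netCfg <- do.call(networkConfig, cfg$network %||% list())
    buildNetwork(expr, netCfg, metabolites = met)
  })
  writeMatrixTSV(eigengenes(net), file.path(cfg$outdir, "eigengenes.tsv"),
                 idColumn = "module")
  writeMatrixTSV(kme(net), file.path(cfg$outdir, "kme.tsv"),
                 idColumn = "gene")
  if (ncol(geneSignif(net)))
    writeMatrixTSV(geneSignif(net), file.path(cfg$outdir, "gs.tsv"),
                   idColumn = "gene")
  utils::write.table(
    data.frame(gene = names(moduleLabels(net)),
               module = moduleLabels(net)),
    file.path(cfg$outdir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report$beta <- net@beta
  report$nModules <- length(setdiff(unique(moduleLabels(net)), 0L))
  report$nUnassigned <- sum(moduleLabels(net) == 0)

  ## integration --------------------------------------------------------
  integ <- stage("integrate", {
    icfg <- cfg$integration %||% list()
    cm <- correlateModulesMetabolites(eigengenes(net), met)
    mc <- clusterOfClusters(cm, k = icfg$k %||% 4)
    keys <- keyMetabolites(mc, cm)
    bn <- exportNetwork(cm, gs = geneSignif(net),
                        threshold = icfg$edgeThreshold %||% 0.5,
                        hubQuantile = icfg$hubQuantile %||% 0.9)
    list(cm = cm, mc = mc, keys = keys, bn = bn)
  })
  writeMatrixTSV(integ$cm@r, file.path(cfg$outdir, "corr.tsv"),
                 idColumn = "module")
  writeMatrixTSV(integ$cm@padj, file.path(cfg$outdir, "pvals_adj.tsv"),
                 idColumn = "module")
  utils::write.table(metaLabels(integ$mc),
                     file.path(cfg$outdir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(integ$keys,
                     file.path(cfg$outdir, "key_metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeEdgeList(integ$bn, file.path(cfg$outdir, "network_edges.tsv"))
  report$nMetaClusters <- integ$mc@nClusters
  report$keyMetabolites <- stats::setNames(
    as.list(integ$keys$metabolite), paste0("cluster", integ$keys$cluster))

  ## enrichment ---------------------------------------------------------
  if (!is.null(cfg$gmt)) {
    gsea <- stage("gsea", {
      gcfg <- cfg$gsea %||% list()
      gmt <- readGMT(cfg$gmt)
      mods <- rownames(eigengenes(net))
      res <- lapply(mods, function(mm) {
        ranked <- rankByConnectivity(kme(net), mm, moduleLabels(net))
        # testable sets: at least one member inside, not the whole module
        keep <- vapply(gmt$sets, function(s) {
          ov <- sum(names(ranked) %in% s)
          ov >= 1 && ov < length(ranked)
        }, logical(1))
        if (!any(keep))
          return(NULL)
        out <- prerankedGSEA(ranked, gmt$sets[keep],
                             weightP = gcfg$weightP %||% 1,
                             nPerm = gcfg$nPerm %||% 1000,
                             seed = cfg$seed)
        cbind(module = mm, out)
      })
      do.call(rbind, res)
    })
    if (!is.null(gsea) && nrow(gsea)) {
      gsea$negLog10FDR <- -log10(pmax(gsea$fdr, 1e-300))
      utils::write.table(
        gsea[, c("module", "set", "size", "es", "nes", "p", "fdr",
                 "negLog10FDR")],
        file.path(cfg$outdir, "gsea.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    report$nEnrichmentTests <- if (is.null(gsea)) 0L else nrow(gsea)
  }

  ## sample-level clustering -------------------------------------------
  cons <- stage("cluster", {
    ccfg <- cfg$consensus %||% list()
    consensusCluster(t(expr), kmax = ccfg$kmax %||% 10,
                     reps = ccfg$reps %||% 100,
                     subsampleFraction = ccfg$fraction %||% 0.8,
                     seed = cfg$seed)
  })
  utils::write.table(
    data.frame(sample = rownames(cons@labels),
               cluster = cons@labels[, as.character(bestK(cons))]),
    file.path(cfg$outdir, "consensus_clusters.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  report$consensusBestK <- bestK(cons)

  ## survival -----------------------------------------------------------
  if (!is.null(cfg$survival)) {
    sv <- stage("survival", {
      tab <- readSurvivalTable(cfg$survival)
      km <- kmEstimate(tab)
      lr <- logrankTest(tab)
      hr <- if (length(unique(tab$group)) == 2) coxHR(tab) else NULL
      list(km = km, lr = lr, hr = hr)
    })
    utils::write.table(sv$km, file.path(cfg$outdir, "km.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- list(logrank = sv$lr[c("chisq", "df", "p")])
    if (!is.null(sv$hr)) tests$cox <- sv$hr
    jsonlite::write_json(tests, file.path(cfg$outdir, "tests.json"),
                         auto_unbox = TRUE, digits = NA)
    report$logrankP <- sv$lr$p
    if (!is.null(sv$hr)) report$coxHR <- sv$hr$hr
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
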