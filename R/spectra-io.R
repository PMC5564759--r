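#' Read a 1D spectrum from a two-column text file
#'
#' Expects whitespace- or tab-separated rows of (ppm, intensity). A single
#' non-numeric header line is tolerated and skipped. A descending ppm axis is
#' reordered to ascending. Malformed rows abort with the offending line
#' number.
#'
#' @param path file path.
#' @param sampleId identifier to store; defaults to the file name without
#'   extension.
#' @return A [Spectrum-class].
#' @export
readSpectrum <- function(path, sampleId = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep))
    stop("parse error: '", path, "' contains no data")
  toks <- strsplit(trimws(lines[keep]), "[\t ]+")
  first <- suppressWarnings(as.numeric(toks[[1]]))
  if (anyNA(first)) {   # header line
    keep <- keep[-1]
    toks <- toks[-1]
    if (!length(keep))
      stop("parse error: '", path, "' contains no data rows")
  }
  n <- length(toks)
  ppm <- numeric(n)
  val <- numeric(n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (length(v) != 2 || anyNA(v))
      stop("parse error at line ", keep[i], " of '", path,
           "': expected two numeric fields")
    ppm[i] <- v[1]
    val[i] <- v[2]
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  Spectrum(ppm, val, sampleId)
}

#' Write a spectrum as a two-column TSV
#'
#' Values are written with 17 significant digits so that
#' \code{readSpectrum(writeSpectrum(s))} round-trips to full double
#' precision.
#'
#' @param spectrum a [Spectrum-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  writeLines(c("ppm\tintensity",
               sprintf("%.17g\t%.17g", spectrum@ppm, spectrum@intensity)),
             path)
  invisible(path)
}

#' Read a metabolite template library from JSON
#'
#' The library is a JSON array of
#' \code{{name, lineshape, peaks: [{center, relative_area, linewidth}]}}
#' records; linewidths are full widths at half maximum in ppm and relative
#' areas sum to 1 within each metabolite.
#'
#' @param path JSON file path.
#' @return A [TemplateLibrary-class].
#' @seealso [defaultTemplateLibrary()]
#' @export
readTemplateLibrary <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  tpls <- lapply(raw, function(rec) {
    peaks <- do.call(rbind, lapply(rec$peaks, function(p)
      data.frame(center = p$center, relative_area = p$relative_area,
                 linewidth = p$linewidth)))
    new("MetaboliteTemplate", name = rec$name,
        lineshape = rec$lineshape, peaks = peaks)
  })
  names(tpls) <- vapply(tpls, function(t) t@name, character(1))
  new("TemplateLibrary", templates = tpls)
}

#' Built-in template library
#'
#' Templates for six metabolites routinely quantified in tumor extracts
#' (lactate, creatine, glycine, choline, phosphocholine, myo-inositol), with
#' literature chemical shifts and static multiplet structure. The lactate
#' methyl doublet apex sits at the 1.310 ppm calibration reference.
#'
#' @return A [TemplateLibrary-class].
#' @export
defaultTemplateLibrary <- function() {
  readTemplateLibrary(system.file("extdata", "metabolite_templates.json",
                                  package = "MetaboCoNet", mustWork = TRUE))
}

#' Evaluate a template's lineshape mixture on a ppm axis
#'
#' Unit-concentration intensity profile: each peak contributes a unit-area
#' Lorentzian or Gaussian scaled by its relative area, so the template
#' integrates to 1 over an unbounded axis.
#'
#' @param template a [MetaboliteTemplate-class].
#' @param x numeric ppm positions.
#' @return numeric intensities at \code{x}.
#' @export
evaluateTemplate <- function(template, x) {
  out <- numeric(length(x))
  for (i in seq_len(nrow(template@peaks))) {
    c0 <- template@peaks$center[i]
    w <- template@peaks$linewidth[i]
    a <- template@peaks$relative_area[i]
    if (template@lineshape == "lorentzian") {
      hw <- w / 2
      out <- out + a * (hw / pi) / ((x - c0)^2 + hw^2)
    } else {
      s <- w / (2 * sqrt(2 * log(2)))
      out <- out + a * stats::dnorm(x, mean = c0, sd = s)
    }
  }
  out
}
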