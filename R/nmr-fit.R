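#' Fitting configuration for spectral template regression
#'
#' @param maxShift largest per-metabolite chemical-shift offset searched,
#'   in ppm.
#' @param shiftGridStep grid resolution of the shift search, in ppm.
#' @param baselineDegree degree of the polynomial baseline (coefficients
#'   unconstrained in sign); 0 gives a constant offset, negative disables
#'   the baseline.
#' @param qcThreshold largest relative residual accepted as a usable fit.
#' @return list of class \code{fit_config}.
#' @export
fitConfig <- function(maxShift = 0.01, shiftGridStep = 0.001,
                      baselineDegree = 3, qcThreshold = 0.25) {
  if (maxShift < 0 || shiftGridStep <= 0)
    stop("invalid config: maxShift must be >= 0 and shiftGridStep > 0")
  structure(list(maxShift = maxShift, shiftGridStep = shiftGridStep,
                 baselineDegree = as.integer(baselineDegree),
                 qcThreshold = qcThreshold),
            class = "fit_config")
}

#' Calibrate a spectrum's ppm axis to the lactate reference
#'
#' Locates the maximum-intensity point within a search window around the
#' lactate methyl resonance and shifts the entire axis so that apex sits at
#' the reference (1.310 ppm by convention). A window with no strict apex
#' (flat intensity) is a calibration error; among tied maxima the one
#' requiring the smallest |offset| wins.
#'
#' @param spectrum a [Spectrum-class].
#' @param reference target position of the apex, ppm.
#' @param window length-2 ppm interval to search; must contain the reference
#'   and intersect the axis.
#' @return list with \code{spectrum} (calibrated) and \code{offset}
#'   (\code{reference - located apex}, ppm).
#' @export
calibrateToLactate <- function(spectrum, reference = 1.310,
                               window = c(1.20, 1.42)) {
  stopifnot(is(spectrum, "Spectrum"))
  if (reference < window[1] || reference > window[2])
    stop("calibration error: window must contain the reference")
  idx <- which(spectrum@ppm >= window[1] & spectrum@ppm <= window[2])
  if (!length(idx))
    stop("calibration error: window lies outside the ppm axis")
  v <- spectrum@intensity[idx]
  if (diff(range(v)) == 0)
    stop("calibration error: no unique apex in the search window")
  cand <- idx[v == max(v)]
  offs <- reference - spectrum@ppm[cand]
  best <- cand[which.min(abs(offs))]
  offset <- reference - spectrum@ppm[best]
  out <- Spectrum(spectrum@ppm + offset, spectrum@intensity,
                  spectrum@sampleId)
  list(spectrum = out, offset = offset)
}

# Nonnegative least squares on the template columns with a sign-free
# polynomial baseline (encoded as +/- column pairs).  Returns coefficients
# and the residual norm.
.nnlsSolve <- function(y, tplCols, baseCols) {
  X <- cbind(tplCols, baseCols, -baseCols)
  fit <- pracma::lsqnonneg(X, y)
  coef <- fit$x
  nT <- ncol(tplCols)
  nB <- if (is.null(baseCols)) 0 else ncol(baseCols)
  base <- if (nB) coef[nT + seq_len(nB)] - coef[nT + nB + seq_len(nB)]
          else numeric(0)
  fitted <- as.numeric(X %*% coef)
  list(intensities = coef[seq_len(nT)], baseline = base,
       fitted = fitted, resnorm = sqrt(sum((y - fitted)^2)))
}

#' Fit a spectrum by constrained template regression
#'
#' Minimizes \eqn{\lVert y - (\sum_m c_m T_m(\delta-\Delta_m) +
#' \mathrm{poly}(\delta))\rVert_2} subject to \eqn{c_m \ge 0}. Concentrations
#' are solved by nonnegative least squares; each metabolite's shift
#' \eqn{\Delta_m} is optimized by one pass of coordinate search over the grid
#' \code{seq(-maxShift, maxShift, shiftGridStep)} in library order, with ties
#' broken toward the smaller |shift|, so the objective is non-increasing.
#' The polynomial baseline is unconstrained in sign. A fit passes QC when
#' its relative residual (residual L2 norm over observed L2 norm) is at or
#' below \code{qcThreshold}.
#'
#' @param spectrum a [Spectrum-class] (calibrate first; see
#'   [calibrateToLactate()]).
#' @param library a [TemplateLibrary-class]; templates whose peaks all fall
#'   outside the spectrum's range are dropped with a warning and reported at
#'   zero intensity.
#' @param config a [fitConfig()].
#' @return A [SpectrumFit-class].
#' @examples
#' lib <- defaultTemplateLibrary()
#' sim <- simulateSpectrum(c(lactate = 2, glycine = 0.5), lib, snr = NULL)
#' fit <- fitSpectrum(sim$spectrum, lib, fitConfig(maxShift = 0))
#' fit@intensities[c("lactate", "glycine")]
#' @export
fitSpectrum <- function(spectrum, library, config = fitConfig()) {
  stopifnot(is(spectrum, "Spectrum"), is(library, "TemplateLibrary"))
  y <- spectrum@intensity
  x <- spectrum@ppm
  if (any(!is.finite(y)) || any(!is.finite(x)))
    stop("data error: spectrum contains non-finite values")
  if (all(y == 0))
    stop("degenerate input: all-zero spectrum")
  nm <- vapply(library@templates, function(t) t@name, character(1))
  inRange <- vapply(library@templates, function(t)
    any(t@peaks$center >= min(x) - config$maxShift &
        t@peaks$center <= max(x) + config$maxShift), logical(1))
  if (!any(inRange))
    stop("data error: no template overlaps the spectrum's ppm range")
  if (!all(inRange))
    warning("templates outside the spectral range reported at zero: ",
            paste(nm[!inRange], collapse = ", "))
  active <- which(inRange)

  baseCols <- NULL
  if (config$baselineDegree >= 0) {
    t01 <- 2 * (x - min(x)) / max(max(x) - min(x), .Machine$double.eps) - 1
    baseCols <- outer(t01, 0:config$baselineDegree, `^`)
  }
  tplAt <- function(i, delta)
    evaluateTemplate(library@templates[[i]], x - delta)

  deltas <- stats::setNames(rep(0, length(active)), nm[active])
  cols <- vapply(active, tplAt, numeric(length(x)), delta = 0)
  cols <- matrix(cols, ncol = length(active))
  best <- .nnlsSolve(y, cols, baseCols)

  if (config$maxShift > 0) {
    grid <- seq(-config$maxShift, config$maxShift,
                by = config$shiftGridStep)
    grid <- grid[order(abs(grid), grid)]   # tie-break toward smaller |shift|
    for (j in seq_along(active)) {
      for (d in grid) {
        if (d == deltas[j]) next
        trial <- cols
        trial[, j] <- tplAt(active[j], d)
        res <- .nnlsSolve(y, trial, baseCols)
        if (res$resnorm < best$resnorm) {
          best <- res
          deltas[j] <- d
          cols <- trial
        }
      }
    }
  }

  intensities <- stats::setNames(rep(0, length(nm)), nm)
  intensities[nm[active]] <- best$intensities
  shifts <- stats::setNames(rep(0, length(nm)), nm)
  shifts[names(deltas)] <- deltas
  relRes <- best$resnorm / sqrt(sum(y^2))
  new("SpectrumFit", intensities = intensities, shifts = shifts,
      baselineCoeffs = best$baseline, relativeResidual = relRes,
      passedQC = relRes <= config$qcThreshold, fitted = best$fitted,
      sampleId = spectrum@sampleId)
}

#' Quantify a set of spectra into a raw metabolite matrix
#'
#' Calibrates (optionally), fits every spectrum against the library and
#' assembles the QC-passing fits into a raw metabolites-by-samples matrix;
#' failing spectra are excluded and reported, mirroring the exclusion of
#' unfittable spectra in routine practice.
#'
#' @param spectra list of [Spectrum-class] objects with unique sample ids.
#' @param library a [TemplateLibrary-class].
#' @param config a [fitConfig()].
#' @param calibrate logical; apply [calibrateToLactate()] first.
#' @return list with \code{matrix} (a raw-stage [MetaboliteMatrix-class]),
#'   \code{fits} (all [SpectrumFit-class] objects) and \code{excluded}
#'   (sample ids failing QC).
#' @export
quantifySpectra <- function(spectra, library, config = fitConfig(),
                            calibrate = TRUE) {
  ids <- vapply(spectra, function(s) s@sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample id among spectra: ", ids[duplicated(ids)][1])
  fits <- lapply(spectra, function(s) {
    if (calibrate)
      s <- calibrateToLactate(s)$spectrum
    fitSpectrum(s, library, config)
  })
  names(fits) <- ids
  ok <- vapply(fits, function(f) f@passedQC, logical(1))
  if (!any(ok))
    stop("no spectrum passed quality control")
  vals <- vapply(fits[ok], function(f) f@intensities,
                 numeric(length(fits[[1]]@intensities)))
  mat <- matrix(vals, ncol = sum(ok),
                dimnames = list(names(fits[[1]]@intensities), ids[ok]))
  list(matrix = MetaboliteMatrix(mat, "raw"), fits = fits,
       excluded = ids[!ok])
}
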