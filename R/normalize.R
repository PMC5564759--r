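#' DNA-concentration normalization (step 1)
#'
#' Divides each sample's raw metabolite intensities by that sample's DNA
#' concentration, balancing the amount of tissue behind each extract.
#'
#' @param m a raw-stage [MetaboliteMatrix-class].
#' @param dnaConc named positive numeric, sample -> DNA concentration; every
#'   column of \code{m} must be covered.
#' @return A [MetaboliteMatrix-class] at stage \code{"dna_normalized"}.
#' @examples
#' m <- MetaboliteMatrix(matrix(c(10, 20), 2, 1,
#'   dimnames = list(c("a", "b"), "S1")))
#' values(normalizeDNA(m, c(S1 = 2)))
#' @export
normalizeDNA <- function(m, dnaConc) {
  stopifnot(is(m, "MetaboliteMatrix"))
  if (m@stage != "raw")
    stop("normalization error: DNA normalization applies to raw intensities")
  smp <- colnames(m@values)
  missing <- setdiff(smp, names(dnaConc))
  if (length(missing))
    stop("normalization error: no DNA concentration for sample(s) ",
         paste(missing, collapse = ", "))
  conc <- dnaConc[smp]
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("normalization error: DNA concentrations must be positive")
  new("MetaboliteMatrix",
      values = sweep(m@values, 2, conc, `/`),
      stage = "dna_normalized")
}

#' Median-based normalization (step 2)
#'
#' Rescales every sample so all column medians coincide: column j is mapped
#' to \code{(x / median_j) * reference}, where the reference is the median of
#' all column medians. A single column (reference equals its own median) and
#' identical columns are left unchanged.
#'
#' @param m a [MetaboliteMatrix-class] (raw or DNA-normalized).
#' @return A [MetaboliteMatrix-class] at stage \code{"median_normalized"}.
#' @export
normalizeMedian <- function(m) {
  stopifnot(is(m, "MetaboliteMatrix"))
  meds <- apply(m@values, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(meds)) || any(meds <= 0))
    stop("normalization error: every sample needs a positive median")
  ref <- stats::median(meds)
  # (x / med) * ref keeps the median element itself exactly at ref
  out <- sweep(m@values, 2, meds, `/`) * ref
  new("MetaboliteMatrix", values = out, stage = "median_normalized")
}
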