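#' Configuration for the synthetic cohort generator
#'
#' Defines the planted structure of a simulated cohort: independent latent
#' module factors, genes loading on one factor each, background noise genes,
#' and metabolites tied to chosen module factors at a target correlation.
#' Defaults describe the reference cohort used throughout the package's
#' validation: 6 modules of 50 genes, 700 background genes, 60 samples,
#' loadings drawn uniformly from [0.6, 0.95].
#'
#' @param nSamples number of samples (>= 3).
#' @param nModules number of planted co-expression modules.
#' @param genesPerModule genes per module.
#' @param nBackgroundGenes pure-noise genes carrying no module signal.
#' @param loadingRange length-2 numeric in (0, 1]; per-gene loadings are drawn
#'   uniformly from this interval. Because rows are standardized after noise
#'   injection, a loading is the population correlation between the gene and
#'   its module factor.
#' @param metaboliteSpec data.frame with columns \code{metabolite},
#'   \code{module} (target module index, NA for a pure-noise metabolite) and
#'   \code{r} (target correlation, |r| < 1, or exactly 1 in the noiseless
#'   limit), or NULL for no metabolites.
#' @param noiseSd standard deviation of the noise of background genes
#'   (module-gene noise is standard normal so loadings stay correlations).
#' @param seed integer seed for the generator's private RNG stream.
#' @return A validated list of class \code{simulation_config}.
#' @examples
#' cfg <- simulationConfig(nSamples = 20, nModules = 2, genesPerModule = 10,
#'                         nBackgroundGenes = 30, seed = 1)
#' @export
simulationConfig <- function(nSamples = 60, nModules = 6,
                             genesPerModule = 50, nBackgroundGenes = 700,
                             loadingRange = c(0.6, 0.95),
                             metaboliteSpec = NULL, noiseSd = 1,
                             seed = 1) {
  nSamples <- assertCount(nSamples, "nSamples")
  if (nSamples < 3)
    stop("invalid config: nSamples must be at least 3")
  nModules <- assertCount(nModules, "nModules")
  genesPerModule <- assertCount(genesPerModule, "genesPerModule")
  if (!is.numeric(nBackgroundGenes) || nBackgroundGenes < 0 ||
      nBackgroundGenes != round(nBackgroundGenes))
    stop("invalid config: nBackgroundGenes must be a nonnegative integer")
  if (length(loadingRange) != 2 || any(loadingRange <= 0) ||
      any(loadingRange > 1) || loadingRange[1] > loadingRange[2])
    stop("invalid config: loadingRange must be an interval within (0, 1]")
  if (!is.numeric(noiseSd) || noiseSd <= 0)
    stop("invalid config: noiseSd must be positive")
  if (!is.null(metaboliteSpec)) {
    if (!all(c("metabolite", "module", "r") %in% names(metaboliteSpec)))
      stop("invalid config: metaboliteSpec needs metabolite, module, r")
    if (any(abs(metaboliteSpec$r) > 1, na.rm = TRUE))
      stop("invalid config: |r| must not exceed 1")
    bad <- !is.na(metaboliteSpec$module) &
      (metaboliteSpec$module < 1 | metaboliteSpec$module > nModules)
    if (any(bad))
      stop("invalid config: metabolite targets a nonexistent module")
  }
  structure(list(nSamples = nSamples, nModules = nModules,
                 genesPerModule = genesPerModule,
                 nBackgroundGenes = as.integer(nBackgroundGenes),
                 loadingRange = as.numeric(loadingRange),
                 metaboliteSpec = metaboliteSpec,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate expression with planted co-expression modules
#'
#' Each module m has an independent standard-normal latent factor
#' \eqn{E_m} across samples. A gene g of module m is
#' \eqn{x_g = u_g E_m + \sqrt{1-u_g^2}\,\epsilon} with loading \eqn{u_g}
#' uniform on \code{loadingRange} and \eqn{\epsilon} standard normal;
#' background genes are pure noise. Rows are standardized to mean 0, sd 1
#' after noise injection, so loadings act as gene-factor correlations.
#'
#' @param config a [simulationConfig()] object.
#' @return list with \code{expression} (genes x samples matrix),
#'   \code{moduleLabels} (named integer, 0 = background) and \code{factors}
#'   (module x sample matrix of the latent factors, for reuse by
#'   [simulateMetabolites()]).
#' @examples
#' sim <- simulateExpression(simulationConfig(nSamples = 12, nModules = 2,
#'   genesPerModule = 5, nBackgroundGenes = 5, seed = 7))
#' dim(sim$expression)
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withSeed(config$seed, {
    n <- config$nSamples
    K <- config$nModules
    factors <- matrix(stats::rnorm(K * n), nrow = K,
                      dimnames = list(paste0("M", seq_len(K)),
                                      paste0("S", seq_len(n))))
    nModGenes <- K * config$genesPerModule
    nGenes <- nModGenes + config$nBackgroundGenes
    labels <- c(rep(seq_len(K), each = config$genesPerModule),
                rep(0L, config$nBackgroundGenes))
    geneIds <- character(nGenes)
    geneIds[labels > 0] <- sprintf("M%d_g%03d", labels[labels > 0],
      sequence(rep(config$genesPerModule, K)))
    geneIds[labels == 0] <- sprintf("BG_g%04d",
      seq_len(config$nBackgroundGenes))
    u <- stats::runif(nModGenes, config$loadingRange[1],
                      config$loadingRange[2])
    expr <- matrix(0, nGenes, n, dimnames = list(geneIds, colnames(factors)))
    if (nModGenes) {
      eps <- matrix(stats::rnorm(nModGenes * n), nModGenes, n)
      expr[seq_len(nModGenes), ] <-
        u * factors[labels[seq_len(nModGenes)], , drop = FALSE] +
        sqrt(1 - u^2) * eps
    }
    if (config$nBackgroundGenes)
      expr[labels == 0, ] <- matrix(
        stats::rnorm(config$nBackgroundGenes * n, sd = config$noiseSd),
        config$nBackgroundGenes, n)
    expr <- standardizeRows(expr)
    names(labels) <- geneIds
    list(expression = expr, moduleLabels = labels, factors = factors)
  })
}

#' Simulate metabolites correlated with module factors
#'
#' Reuses the very same per-sample factor values as the expression simulation,
#' guaranteeing the planted cross-omic correlation the integration stage must
#' recover: metabolite j targeting module k at correlation r is
#' \eqn{y_j = r E_k + \sqrt{1-r^2}\,\epsilon}; unassociated metabolites are
#' pure standard-normal noise.
#'
#' @param factors module x sample matrix (from [simulateExpression()]).
#' @param metaboliteSpec data.frame (metabolite, module, r); NA module means
#'   unassociated.
#' @param seed integer seed.
#' @return list with \code{metabolites} (metabolite x sample matrix) and
#'   \code{associations} (the planted spec as a data.frame).
#' @export
simulateMetabolites <- function(factors, metaboliteSpec, seed = 1) {
  factors <- as.matrix(factors)
  if (any(abs(metaboliteSpec$r) > 1, na.rm = TRUE) ||
      any(is.na(metaboliteSpec$r) & !is.na(metaboliteSpec$module)))
    stop("invalid config: target correlations must satisfy |r| <= 1")
  if (any(!is.na(metaboliteSpec$module) &
          (metaboliteSpec$module < 1 |
           metaboliteSpec$module > nrow(factors))))
    stop("invalid config: target module does not exist")
  n <- ncol(factors)
  withSeed(seed, {
    met <- matrix(0, nrow(metaboliteSpec), n,
                  dimnames = list(metaboliteSpec$metabolite,
                                  colnames(factors)))
    for (j in seq_len(nrow(metaboliteSpec))) {
      k <- metaboliteSpec$module[j]
      r <- metaboliteSpec$r[j]
      if (is.na(k)) {
        met[j, ] <- stats::rnorm(n)
      } else {
        met[j, ] <- r * factors[k, ] +
          sqrt(1 - r^2) * stats::rnorm(n)
      }
    }
    list(metabolites = met, associations = metaboliteSpec)
  })
}

#' Simulate a 1D NMR spectrum from template concentrations
#'
#' Builds \eqn{y(\delta) = \sum_m c_m T_m(\delta - \Delta_m)} on a regular
#' ppm grid, with per-metabolite shifts drawn uniformly in
#' \code{c(-1, 1) * shiftJitter} and white Gaussian noise scaled so the
#' clean-spectrum maximum divided by the noise sd equals \code{snr}.
#'
#' @param concentrations named nonnegative numeric; names must exist in the
#'   library.
#' @param library a [TemplateLibrary-class].
#' @param snr peak signal-to-noise ratio, or NULL for a noiseless spectrum.
#' @param shiftJitter maximum |shift| in ppm (uniform); 0 for none.
#' @param seed integer seed.
#' @param grid ppm axis on which to evaluate (ascending regular grid).
#' @param sampleId identifier stored in the returned spectrum.
#' @return list with \code{spectrum} (a [Spectrum-class]), \code{shifts}
#'   (named numeric, the true per-metabolite offsets) and \code{noiseSd}.
#' @export
simulateSpectrum <- function(concentrations, library, snr = NULL,
                             shiftJitter = 0, seed = 1,
                             grid = seq(0.5, 4.5, by = 0.001),
                             sampleId = NA_character_) {
  stopifnot(is(library, "TemplateLibrary"))
  if (any(concentrations < 0))
    stop("invalid config: concentrations must be nonnegative")
  libNames <- vapply(library@templates, function(t) t@name, character(1))
  if (!all(names(concentrations) %in% libNames))
    stop("invalid config: unknown metabolite(s) ",
         paste(setdiff(names(concentrations), libNames), collapse = ", "))
  withSeed(seed, {
    shifts <- stats::setNames(
      if (shiftJitter > 0)
        stats::runif(length(concentrations), -shiftJitter, shiftJitter)
      else rep(0, length(concentrations)),
      names(concentrations))
    clean <- numeric(length(grid))
    for (m in names(concentrations)) {
      tpl <- library@templates[[match(m, libNames)]]
      clean <- clean + concentrations[[m]] *
        evaluateTemplate(tpl, grid - shifts[[m]])
    }
    noiseSd <- 0
    y <- clean
    if (!is.null(snr)) {
      if (snr <= 0) stop("invalid config: snr must be positive")
      noiseSd <- max(clean) / snr
      y <- clean + stats::rnorm(length(grid), sd = noiseSd)
    }
    list(spectrum = Spectrum(grid, y, sampleId), shifts = shifts,
         noiseSd = noiseSd)
  })
}

#' Simulate exponential survival with group-specific hazards
#'
#' Event times are exponential with the group's hazard; censoring times are
#' independent exponential with rate chosen so the expected censored fraction
#' equals \code{censorRate}. The observed time is the minimum of the two and
#' the event flag is 1 when the event came first.
#'
#' @param groups named character/factor, sample -> group label.
#' @param hazardByGroup named positive numeric, hazard per group (1/month).
#' @param censorRate expected censored fraction in [0, 1).
#' @param seed integer seed.
#' @return data.frame with columns sample, time, event, group.
#' @export
simulateSurvival <- function(groups, hazardByGroup, censorRate = 0,
                             seed = 1) {
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!all(groups %in% names(hazardByGroup)))
    stop("invalid config: unknown group label(s) ",
         paste(setdiff(groups, names(hazardByGroup)), collapse = ", "))
  if (any(hazardByGroup <= 0))
    stop("invalid config: hazards must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("invalid config: censorRate must lie in [0, 1)")
  withSeed(seed, {
    lam <- hazardByGroup[groups]
    eventTime <- stats::rexp(length(groups), rate = lam)
    if (censorRate > 0) {
      lamC <- lam * censorRate / (1 - censorRate)
      censTime <- stats::rexp(length(groups), rate = lamC)
    } else {
      censTime <- rep(Inf, length(groups))
    }
    data.frame(
      sample = if (!is.null(names(groups))) names(groups)
               else paste0("S", seq_along(groups)),
      time = pmin(eventTime, censTime),
      event = as.integer(eventTime <= censTime),
      group = unname(groups),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper tying the generators together: expression with planted
#' modules, metabolites bound to the same latent factors, a two-group
#' survival table (groups split by the first module factor's sign as a crude
#' "subtype"), and subtype labels for classifier exercises.
#'
#' @param config a [simulationConfig()]; its \code{metaboliteSpec} drives the
#'   metabolite block (may be NULL).
#' @param hazardByGroup named hazards for the survival table (default: group
#'   "high" has twice the hazard of "low").
#' @param censorRate expected censored fraction.
#' @return A [SyntheticCohort-class] object.
#' @examples
#' cfg <- simulationConfig(nSamples = 12, nModules = 2, genesPerModule = 5,
#'   nBackgroundGenes = 5,
#'   metaboliteSpec = data.frame(metabolite = "lactate", module = 1, r = 0.8),
#'   seed = 3)
#' simulateCohort(cfg)
#' @export
simulateCohort <- function(config,
                           hazardByGroup = c(low = 0.04, high = 0.08),
                           censorRate = 0.3) {
  sim <- simulateExpression(config)
  if (!is.null(config$metaboliteSpec)) {
    mets <- simulateMetabolites(sim$factors, config$metaboliteSpec,
                                seed = config$seed + 1L)
    metMat <- mets$metabolites
    assoc <- mets$associations
  } else {
    metMat <- matrix(numeric(0), 0, ncol(sim$expression),
                     dimnames = list(character(0),
                                     colnames(sim$expression)))
    assoc <- data.frame(metabolite = character(0), module = integer(0),
                        r = numeric(0))
  }
  groups <- stats::setNames(
    ifelse(sim$factors[1, ] > 0, "high", "low"),
    colnames(sim$expression))
  surv <- simulateSurvival(groups, hazardByGroup, censorRate,
                           seed = config$seed + 2L)
  new("SyntheticCohort", expression = sim$expression,
      moduleLabels = sim$moduleLabels, factors = sim$factors,
      metabolites = metMat, associations = assoc, survival = surv,
      subtypes = groups)
}

#' Simulate a labelled subtype cohort with mean-shifted marker genes
#'
#' For classifier training/evaluation: each subtype has its own block of
#' marker genes shifted by \code{shift} standard deviations in samples of
#' that subtype; all other genes are standard noise.
#'
#' @param nPerClass samples per subtype.
#' @param classes character vector of subtype labels.
#' @param markersPerClass marker genes per subtype.
#' @param nNoiseGenes additional unshifted genes.
#' @param shift mean shift (in sd units) of a subtype's markers.
#' @param seed integer seed.
#' @return list with \code{expression} (genes x samples) and \code{labels}
#'   (named character).
#' @export
simulateSubtypeCohort <- function(nPerClass = 50,
                                  classes = c("proneural", "neural",
                                              "classical", "mesenchymal"),
                                  markersPerClass = 40, nNoiseGenes = 200,
                                  shift = 2, seed = 1) {
  withSeed(seed, {
    n <- nPerClass * length(classes)
    labels <- rep(classes, each = nPerClass)
    nGenes <- markersPerClass * length(classes) + nNoiseGenes
    expr <- matrix(stats::rnorm(nGenes * n), nGenes, n)
    rn <- c(sprintf("%s_mk%02d", rep(classes, each = markersPerClass),
                    sequence(rep(markersPerClass, length(classes)))),
            sprintf("noise_g%03d", seq_len(nNoiseGenes)))
    dimnames(expr) <- list(rn, paste0("S", seq_len(n)))
    for (ci in seq_along(classes)) {
      rows <- (ci - 1) * markersPerClass + seq_len(markersPerClass)
      cols <- labels == classes[ci]
      expr[rows, cols] <- expr[rows, cols] + shift
    }
    list(expression = expr,
         labels = stats::setNames(labels, colnames(expr)))
  })
}
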