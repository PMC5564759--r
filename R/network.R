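#' Network construction configuration
#'
#' The default power candidates start at 6, the customary floor for unsigned
#' networks built on cohorts of 40+ samples; the scale-free fit index of
#' planted-module data plateaus around 0.85-0.95 from that point on, so the
#' default acceptance target is 0.85 and the smallest adequate power wins.
#'
#' @param powerCandidates ascending candidate soft-thresholding powers.
#' @param targetR2 scale-free fit index required to accept a power.
#' @param networkSign \code{"unsigned"} (|cor|^beta) or \code{"signed"}
#'   (((1+cor)/2)^beta).
#' @param minModuleSize smallest cluster kept as a module.
#' @param cutHeight static dendrogram cut height on the 1 - TOM scale.
#' @param nKBins number of connectivity bins for the scale-free regression.
#' @return list of class \code{network_config}.
#' @export
networkConfig <- function(powerCandidates = c(6, 7, 8, 9, 10, 12),
                          targetR2 = 0.85, networkSign = "unsigned",
                          minModuleSize = 20, cutHeight = 0.99,
                          nKBins = 10) {
  if (!length(powerCandidates) || any(powerCandidates <= 0))
    stop("invalid config: powerCandidates must be positive")
  if (is.unsorted(powerCandidates))
    stop("invalid config: powerCandidates must be ascending")
  if (!networkSign %in% c("unsigned", "signed"))
    stop("invalid config: networkSign must be 'unsigned' or 'signed'")
  if (targetR2 <= 0 || targetR2 > 1)
    stop("invalid config: targetR2 must lie in (0, 1]")
  if (cutHeight <= 0 || cutHeight > 1)
    stop("invalid config: cutHeight must lie in (0, 1]")
  structure(list(powerCandidates = powerCandidates, targetR2 = targetR2,
                 networkSign = networkSign,
                 minModuleSize = as.integer(minModuleSize),
                 cutHeight = cutHeight, nKBins = as.integer(nKBins)),
            class = "network_config")
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlations are computed across samples with pairwise-complete
#' observations. Genes with zero variance cannot be correlated and are
#' removed with a warning.
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @return symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(expr) {
  expr <- asNamedMatrix(expr, "expression matrix")
  if (ncol(expr) < 3)
    stop("at least 3 samples are required")
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  if (any(v == 0 | !is.finite(v))) {
    bad <- rownames(expr)[v == 0 | !is.finite(v)]
    warning("removing ", length(bad), " constant gene(s): ",
            paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ...")
    expr <- expr[!(rownames(expr) %in% bad), , drop = FALSE]
  }
  cc <- stats::cor(t(expr), use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' Weighted adjacency from correlations
#'
#' Unsigned: \eqn{a_{ij} = |r_{ij}|^\beta}; signed:
#' \eqn{a_{ij} = ((1+r_{ij})/2)^\beta}. The diagonal is set to 1.
#'
#' @param cor gene x gene correlation matrix.
#' @param beta positive soft-thresholding power.
#' @param networkSign \code{"unsigned"} or \code{"signed"}.
#' @return adjacency matrix with entries in [0, 1].
#' @export
adjacencyMatrix <- function(cor, beta, networkSign = "unsigned") {
  if (beta <= 0)
    stop("beta must be positive")
  a <- switch(networkSign,
              unsigned = abs(cor)^beta,
              signed = ((1 + cor) / 2)^beta,
              stop("networkSign must be 'unsigned' or 'signed'"))
  diag(a) <- 1
  a
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For every candidate power the weighted connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} is computed, \eqn{\log_{10} k} is
#' binned, and \eqn{\log_{10} p(k)} is regressed on the bin means of
#' \eqn{\log_{10} k}. The scale-free fit index is the regression R-squared,
#' signed negative when the slope is positive. The smallest candidate
#' reaching \code{targetR2} is returned; if none does, the best-fitting
#' candidate is returned with a warning.
#'
#' @param cor gene x gene correlation matrix.
#' @param config a [networkConfig()].
#' @return list with \code{beta} and \code{fitTable} (power, fit, slope,
#'   meanK, medianK, maxK).
#' @export
pickSoftThreshold <- function(cor, config = networkConfig()) {
  rows <- lapply(config$powerCandidates, function(p) {
    a <- adjacencyMatrix(cor, p, config$networkSign)
    k <- rowSums(a) - 1
    if (all(k <= 0))
      stop("degenerate network: all connectivities are zero")
    data.frame(power = p, fit = .scaleFreeFit(k, config$nKBins)$fit,
               slope = .scaleFreeFit(k, config$nKBins)$slope,
               meanK = mean(k), medianK = stats::median(k), maxK = max(k))
  })
  fitTable <- do.call(rbind, rows)
  ok <- which(fitTable$fit >= config$targetR2)
  if (length(ok)) {
    beta <- fitTable$power[ok[1]]
  } else {
    beta <- fitTable$power[which.max(fitTable$fit)]
    warning(sprintf(
      "no candidate reached scale-free fit %.2f; using power %g (fit %.3f)",
      config$targetR2, beta, max(fitTable$fit)))
  }
  list(beta = beta, fitTable = fitTable)
}

# Scale-free topology fit: bin k, regress log10 p(k) on log10 mean(k).
.scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2)
    return(list(fit = 0, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 2)
    return(list(fit = 0, slope = NA_real_))
  lx <- log10(dk[keep])
  ly <- log10(pk[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(fit = if (!is.na(slope) && slope > 0) -r2 else r2, slope = slope)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}, \quad
#'       k_i = \sum_{u \ne i} a_{iu},}
#' with unit diagonal. Input must be a symmetric adjacency in [0, 1] with
#' unit diagonal.
#'
#' @param adjacency gene x gene adjacency matrix.
#' @return TOM matrix, symmetric with entries in [0, 1].
#' @export
topologicalOverlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("contract violation: adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("contract violation: adjacency entries must lie in [0, 1]")
  k <- rowSums(a) - 1
  shared <- a %*% a - a        # (A^2)_ij - a_ij = sum_{u != i,j} + a_ij
  denom <- outer(k, k, pmin) + 1 - a
  tom <- shared / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' Genes are clustered on the topological-overlap dissimilarity with
#' average linkage and the dendrogram is cut at a fixed height. Clusters
#' below the minimum size are relabelled 0 (unassigned); surviving modules
#' are numbered by decreasing size starting at 1.
#'
#' @param tom topological overlap matrix.
#' @param config a [networkConfig()] (uses \code{cutHeight} and
#'   \code{minModuleSize}).
#' @return named integer vector gene -> module id (0 = unassigned).
#' @export
detectModules <- function(tom, config = networkConfig()) {
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, h = config$cutHeight)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$minModuleSize]
  labels <- rep(0L, length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord))
      labels[raw == as.integer(ord[i])] <- i
  }
  if (!any(labels != 0))
    warning("empty partition: no cluster reached the minimum module size")
  stats::setNames(as.integer(labels), rownames(as.matrix(tom)))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' row-standardized submatrix, expressed as per-sample scores scaled to
#' standard deviation 1, with the sign oriented so the mean correlation with
#' the module's genes is positive. A single-gene module's eigengene is that
#' standardized gene.
#'
#' @param expr genes x samples matrix.
#' @param moduleLabels named integer gene -> module (0 entries are ignored).
#' @return module x sample matrix, rows named \code{ME<id>}.
#' @export
moduleEigengene <- function(expr, moduleLabels) {
  expr <- asNamedMatrix(expr, "expression matrix")
  mods <- sort(setdiff(unique(moduleLabels), 0L))
  if (!length(mods))
    stop("no modules to summarize")
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(paste0("ME", mods), colnames(expr)))
  for (i in seq_along(mods)) {
    genes <- names(moduleLabels)[moduleLabels == mods[i]]
    sub <- standardizeRows(expr[genes, , drop = FALSE])
    if (length(genes) == 1) {
      e <- as.numeric(sub)
    } else {
      sv <- svd(sub, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    e <- e / stats::sd(e)
    if (mean(stats::cor(t(sub), e)) < 0)
      e <- -e
    out[i, ] <- e
  }
  out
}

#' Gene significance: gene-metabolite correlation
#'
#' Pearson correlation of every gene with every metabolite over the
#' intersection of samples present in both assays (pairwise-complete within
#' that intersection). The overlap size is attached as attribute
#' \code{"nOverlap"}.
#'
#' @param expr genes x samples matrix.
#' @param metabolites metabolites x samples matrix (or
#'   [MetaboliteMatrix-class]).
#' @return genes x metabolites correlation matrix.
#' @export
geneSignificance <- function(expr, metabolites) {
  if (is(metabolites, "MetaboliteMatrix"))
    metabolites <- values(metabolites)
  expr <- asNamedMatrix(expr, "expression matrix")
  metabolites <- asNamedMatrix(metabolites, "metabolite matrix")
  shared <- intersect(colnames(expr), colnames(metabolites))
  if (length(shared) < 3)
    stop("insufficient overlap: only ", length(shared),
         " shared sample(s); at least 3 required")
  gs <- stats::cor(t(expr[, shared, drop = FALSE]),
                   t(metabolites[, shared, drop = FALSE]),
                   use = "pairwise.complete.obs")
  attr(gs, "nOverlap") <- length(shared)
  gs
}

#' Module membership (kME): gene-eigengene correlation
#'
#' Correlation of every gene with every module eigengene, i.e. including
#' modules the gene does not belong to.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes module x sample matrix (from [moduleEigengene()]).
#' @return genes x modules correlation matrix.
#' @export
moduleMembership <- function(expr, eigengenes) {
  expr <- asNamedMatrix(expr, "expression matrix")
  eigengenes <- asNamedMatrix(eigengenes, "eigengene matrix")
  shared <- intersect(colnames(expr), colnames(eigengenes))
  if (length(shared) < 3)
    stop("insufficient overlap between expression and eigengene samples")
  stats::cor(t(expr[, shared, drop = FALSE]),
             t(eigengenes[, shared, drop = FALSE]),
             use = "pairwise.complete.obs")
}

#' Build the full co-expression network
#'
#' Runs correlation, soft-threshold selection, adjacency, topological
#' overlap, module detection, eigengenes and kME in sequence; when a
#' metabolite matrix is supplied, gene significance is added.
#'
#' @param expr genes x samples matrix.
#' @param config a [networkConfig()].
#' @param metabolites optional metabolites x samples matrix or
#'   [MetaboliteMatrix-class] for gene significance.
#' @param beta optional fixed power, skipping selection.
#' @return A [CoexpressionNetwork-class].
#' @examples
#' sim <- simulateExpression(simulationConfig(nSamples = 30, nModules = 2,
#'   genesPerModule = 25, nBackgroundGenes = 50, seed = 5))
#' net <- buildNetwork(sim$expression,
#'   networkConfig(minModuleSize = 10, powerCandidates = c(4, 6)))
#' table(moduleLabels(net))
#' @export
buildNetwork <- function(expr, config = networkConfig(),
                         metabolites = NULL, beta = NULL) {
  expr <- asNamedMatrix(expr, "expression matrix")
  cc <- correlationMatrix(expr)
  expr <- expr[rownames(cc), , drop = FALSE]  # constant genes dropped
  if (is.null(beta)) {
    pick <- pickSoftThreshold(cc, config)
    beta <- pick$beta
    fitTable <- pick$fitTable
  } else {
    fitTable <- data.frame(power = beta, fit = NA_real_,
                           slope = NA_real_, meanK = NA_real_,
                           medianK = NA_real_, maxK = NA_real_)
  }
  adj <- adjacencyMatrix(cc, beta, config$networkSign)
  tom <- topologicalOverlap(adj)
  labels <- detectModules(tom, config)
  me <- moduleEigengene(expr, labels)
  kmeMat <- moduleMembership(expr, me)
  gsMat <- if (!is.null(metabolites))
    geneSignificance(expr, metabolites)
  else matrix(numeric(0), nrow(expr), 0,
              dimnames = list(rownames(expr), character(0)))
  new("CoexpressionNetwork", beta = beta, fitTable = fitTable,
      adjacency = adj, tom = tom, moduleLabels = labels,
      eigengenes = me, kme = kmeMat, gs = gsMat)
}
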