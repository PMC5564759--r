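#' Consensus clustering by resampling
#'
#' Monti-style consensus: samples are repeatedly subsampled, clustered by
#' average-linkage hierarchical clustering on Euclidean distance, and
#' co-membership counts are normalized by co-sampling counts to give a
#' per-k consensus matrix. Stability is summarized by the area under the
#' consensus CDF and its relative increase (delta area); the selected k is
#' the delta-area argmax over k >= 3 (k = 2 when kmax is 2). Final labels
#' per k come from clustering 1 - consensus.
#'
#' @param x samples x features numeric matrix.
#' @param kmax largest candidate cluster number (>= 2).
#' @param reps number of resampling repetitions (>= 10).
#' @param subsampleFraction fraction of samples drawn per repetition,
#'   in (0, 1].
#' @param seed integer seed.
#' @param linkage linkage of the base clusterer.
#' @return A [ConsensusResult-class].
#' @examples
#' x <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 6), 10))
#' rownames(x) <- paste0("S", 1:20)
#' bestK(consensusCluster(x, kmax = 4, reps = 20, seed = 1))
#' @export
consensusCluster <- function(x, kmax = 10, reps = 100,
                             subsampleFraction = 0.8, seed = 1,
                             linkage = "average") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(rownames(x)))
    rownames(x) <- paste0("S", seq_len(n))
  if (kmax < 2 || kmax > n)
    stop("invalid config: kmax must lie in [2, n]")
  if (reps < 10)
    stop("invalid config: at least 10 repetitions required")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("invalid config: subsampleFraction must lie in (0, 1]")
  ks <- 2:kmax
  nSub <- max(2, ceiling(subsampleFraction * n))
  withSeed(seed, {
    coSample <- matrix(0, n, n)
    coCluster <- lapply(ks, function(k) matrix(0, n, n))
    names(coCluster) <- as.character(ks)
    for (rep in seq_len(reps)) {
      idx <- if (nSub == n) seq_len(n) else sort(sample.int(n, nSub))
      coSample[idx, idx] <- coSample[idx, idx] + 1
      hc <- stats::hclust(stats::dist(x[idx, , drop = FALSE]),
                          method = linkage)
      cuts <- stats::cutree(hc, k = ks)
      if (length(ks) == 1)
        cuts <- matrix(cuts, ncol = 1)
      for (ki in seq_along(ks)) {
        lab <- cuts[, ki]
        same <- outer(lab, lab, `==`)
        coCluster[[ki]][idx, idx] <- coCluster[[ki]][idx, idx] + same
      }
    }
    if (any(coSample[upper.tri(coSample)] == 0))
      stop("coverage error: some sample pairs were never co-sampled; ",
           "increase reps or subsampleFraction")
    consensus <- lapply(coCluster, function(m) {
      cm <- m / coSample
      diag(cm) <- 1
      dimnames(cm) <- list(rownames(x), rownames(x))
      cm
    })
    cdfArea <- vapply(consensus, .consensusCdfArea, numeric(1))
    deltaArea <- numeric(length(ks))
    names(deltaArea) <- as.character(ks)
    deltaArea[1] <- cdfArea[1]
    if (length(ks) > 1)
      deltaArea[-1] <- diff(cdfArea) / cdfArea[-length(cdfArea)]
    bestK <- if (kmax >= 3) {
      cand <- ks[ks >= 3]
      cand[which.max(deltaArea[as.character(cand)])]
    } else 2L
    labels <- vapply(seq_along(ks), function(ki) {
      stats::cutree(stats::hclust(stats::as.dist(1 - consensus[[ki]]),
                                  method = linkage), k = ks[ki])
    }, integer(n))
    dimnames(labels) <- list(rownames(x), as.character(ks))
    new("ConsensusResult", consensus = consensus, cdfArea = cdfArea,
        deltaArea = deltaArea, bestK = as.integer(bestK),
        labels = labels)
  })
}

# Area under the empirical CDF of the upper-triangular consensus entries,
# integrated over [0, 1] (left-continuous step integral).
.consensusCdfArea <- function(cm) {
  v <- cm[upper.tri(cm)]
  xs <- sort(unique(c(v, 1)))
  cdf <- stats::ecdf(v)
  sum(diff(xs) * cdf(xs[-length(xs)]))
}

#' Agglomerative clustering of samples
#'
#' Thin deterministic wrapper over \code{hclust}/\code{cutree} with
#' validated linkage and distance names.
#'
#' @param x samples x features matrix.
#' @param k number of clusters.
#' @param linkage one of the \code{hclust} methods (default
#'   \code{"average"}).
#' @param distance a \code{dist} method (default \code{"euclidean"}) or
#'   \code{"correlation"} for 1 - Pearson between samples.
#' @return named integer vector of cluster labels.
#' @export
hierarchicalCluster <- function(x, k, linkage = "average",
                                distance = "euclidean") {
  x <- as.matrix(x)
  if (k > nrow(x))
    stop("k exceeds the number of samples")
  okLink <- c("average", "complete", "single", "ward.D", "ward.D2",
              "mcquitty", "median", "centroid")
  if (!linkage %in% okLink)
    stop("config error: unknown linkage '", linkage, "'")
  d <- if (identical(distance, "correlation"))
    stats::as.dist(1 - stats::cor(t(x)))
  else stats::dist(x, method = distance)
  stats::cutree(stats::hclust(d, method = linkage), k = k)
}

#' Train a subtype classifier
#'
#' Bagged-tree ensemble (random forest) on genes-as-features; the training
#' matrix is genes x samples with a label per sample. Every class needs at
#' least 5 training samples.
#'
#' @param trainExpr genes x samples matrix.
#' @param trainLabels character/factor labels, one per training sample.
#' @param seed integer seed.
#' @param ntree number of trees.
#' @return fitted classifier (a \code{randomForest} object).
#' @export
trainSubtypeClassifier <- function(trainExpr, trainLabels, seed = 1,
                                   ntree = 500) {
  trainExpr <- asNamedMatrix(trainExpr, "training matrix")
  trainLabels <- factor(trainLabels)
  if (nlevels(trainLabels) < 2)
    stop("config error: at least 2 classes required")
  if (any(table(trainLabels) < 5))
    stop("config error: every class needs at least 5 training samples")
  withSeed(seed,
    randomForest::randomForest(x = t(trainExpr), y = trainLabels,
                               ntree = ntree))
}

#' Predict subtypes with a trained classifier
#'
#' @param classifier object from [trainSubtypeClassifier()].
#' @param expr genes x samples matrix with the training genes present.
#' @return named character vector of predicted labels.
#' @export
predictSubtypes <- function(classifier, expr) {
  expr <- asNamedMatrix(expr, "expression matrix")
  pred <- stats::predict(classifier, newdata = t(expr))
  stats::setNames(as.character(pred), colnames(expr))
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' @param predicted predicted labels.
#' @param truth true labels, same length/ordering.
#' @return list with \code{confusion} (truth x predicted table),
#'   \code{perClass} (data.frame class, sensitivity, specificity) and
#'   macro averages \code{macroSensitivity}, \code{macroSpecificity}.
#' @export
evaluateClassifier <- function(predicted, truth) {
  lev <- sort(unique(c(as.character(predicted), as.character(truth))))
  cmat <- table(factor(truth, lev), factor(predicted, lev),
                dnn = c("truth", "predicted"))
  perClass <- do.call(rbind, lapply(lev, function(cl) {
    tp <- cmat[cl, cl]
    fn <- sum(cmat[cl, ]) - tp
    fp <- sum(cmat[, cl]) - tp
    tn <- sum(cmat) - tp - fn - fp
    data.frame(class = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(confusion = cmat, perClass = perClass,
       macroSensitivity = mean(perClass$sensitivity, na.rm = TRUE),
       macroSpecificity = mean(perClass$specificity, na.rm = TRUE))
}
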