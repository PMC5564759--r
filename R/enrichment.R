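#' Read a gene set collection in GMT format
#'
#' Tab-separated lines: set name, description, then one or more gene ids.
#' Duplicate genes within a set are collapsed with a warning; a line with
#' fewer than three fields is a parse error reported with its line number.
#'
#' @param path GMT file path.
#' @return list with \code{sets} (named list of character vectors) and
#'   \code{descriptions} (named character).
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop("parse error at line ", i, " of '", path,
           "': expected name, description and at least one gene")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", f[1], "' collapsed")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  if (!length(sets))
    stop("parse error: '", path, "' contains no gene sets")
  list(sets = sets, descriptions = desc)
}

#' Write a gene set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character descriptions.
#' @return The path, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Weighted Kolmogorov running sum for one set over a ranking already sorted
# in decreasing order. Returns the signed extremum and the running sum.
.gseaRunningSum <- function(statSorted, isHit, weightP) {
  N <- length(statSorted)
  nh <- sum(isHit)
  w <- abs(statSorted)^weightP
  inc <- numeric(N)
  inc[isHit] <- w[isHit] / sum(w[isHit])
  inc[!isHit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  es <- rs[which.max(abs(rs))]
  list(es = es, running = rs)
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' Genes are ordered by decreasing statistic (ties by gene id). The running
#' sum gains \eqn{|s|^{p}/\sum_{hits}|s|^{p}} at set members and loses
#' \eqn{1/(N-|S|)} elsewhere; the enrichment score (ES) is the extremum of
#' largest magnitude. The null is \code{nPerm} random gene sets of the same
#' size drawn from the ranked universe; the two-sided p-value is
#' \eqn{(1 + \#\{|ES_{perm}| \ge |ES|\})/(n_{perm}+1)} and NES divides ES by
#' the mean |permuted ES| of the same sign. With several sets, FDR is
#' Benjamini-Hochberg across their empirical p-values.
#'
#' @param ranked named numeric, gene -> ranking statistic.
#' @param sets a single character vector of genes, or a named list of them.
#' @param weightP weighting exponent of the running sum (0 = classic
#'   Kolmogorov-Smirnov; default 1).
#' @param nPerm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per set: set, size, es, nes, p, fdr,
#'   leadingEdge (comma-separated).
#' @examples
#' stats <- setNames(c(3, 2, 1, 0.5), c("a", "b", "c", "d"))
#' prerankedGSEA(stats, list(top = "a"), weightP = 0, nPerm = 100, seed = 1)
#' @export
prerankedGSEA <- function(ranked, sets, weightP = 1, nPerm = 1000,
                          seed = 1) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop("ranked statistics must carry unique gene names")
  if (!is.list(sets))
    sets <- list(set = sets)
  ord <- order(-ranked, names(ranked))
  stat <- as.numeric(ranked[ord])
  genes <- names(ranked)[ord]
  N <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], genes)
    if (!length(members))
      stop("no gene of set '", nm, "' appears in the ranking")
    if (length(members) >= N)
      stop("undefined misses: set '", nm, "' covers the whole universe")
    isHit <- genes %in% members
    run <- .gseaRunningSum(stat, isHit, weightP)
    peak <- which.max(abs(run$running))
    le <- if (run$es >= 0) genes[seq_len(peak)][isHit[seq_len(peak)]]
          else genes[peak:N][isHit[peak:N]]
    list(name = nm, size = length(members), es = run$es,
         leadingEdge = le, nHit = sum(isHit))
  })
  perms <- withSeed(seed, {
    lapply(rows, function(rw) {
      vapply(seq_len(nPerm), function(i) {
        hit <- logical(N)
        hit[sample.int(N, rw$nHit)] <- TRUE
        .gseaRunningSum(stat, hit, weightP)$es
      }, numeric(1))
    })
  })
  res <- do.call(rbind, Map(function(rw, pe) {
    p <- (1 + sum(abs(pe) >= abs(rw$es))) / (nPerm + 1)
    sameSign <- pe[sign(pe) == sign(rw$es)]
    nes <- if (length(sameSign)) rw$es / mean(abs(sameSign)) else NA_real_
    data.frame(set = rw$name, size = rw$size, es = rw$es, nes = nes,
               p = p, leadingEdge = paste(rw$leadingEdge, collapse = ","),
               stringsAsFactors = FALSE)
  }, rows, perms))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res[, c("set", "size", "es", "nes", "p", "fdr", "leadingEdge")]
}

#' Rank a module's genes by normalized intramodule connectivity
#'
#' The ranking statistic of a gene is its kME to the module divided by the
#' largest |kME| within the module, so the top gene scores 1. Returned
#' sorted decreasing with ties broken by gene id.
#'
#' @param kme genes x modules kME matrix.
#' @param module module column name (e.g. \code{"ME1"}).
#' @param moduleLabels named integer gene -> module id restricting the
#'   ranking to the module's own genes.
#' @return named numeric, sorted decreasing.
#' @export
rankByConnectivity <- function(kme, module, moduleLabels) {
  kme <- asNamedMatrix(kme, "kME matrix")
  if (!module %in% colnames(kme))
    stop("unknown module '", module, "'")
  id <- as.integer(sub("^ME", "", module))
  genes <- names(moduleLabels)[moduleLabels == id]
  genes <- intersect(genes, rownames(kme))
  if (!length(genes))
    stop("module '", module, "' is empty")
  v <- kme[genes, module]
  v <- v / max(abs(v))
  v[order(-v, names(v))]
}

#' Per-sample gene set enrichment matrix
#'
#' Single-sample rank-based scores: within each sample, genes are ranked by
#' expression; the score of a set is the integral of the difference between
#' the weighted ECDF of set-gene ranks (weight = rank^alpha) and the ECDF of
#' non-set genes, accumulated along the sample's decreasing-expression
#' ordering. This transforms a gene-by-sample matrix into a set-by-sample
#' matrix. Scores depend on ranks only, so any monotone transformation of a
#' sample leaves them unchanged.
#'
#' @param expr genes x samples matrix.
#' @param sets named list of character gene vectors.
#' @param alpha rank-weighting exponent (0.25 by convention).
#' @return sets x samples numeric matrix; a set with no gene in the matrix
#'   yields a zero row with a warning.
#' @export
perSampleEnrichment <- function(expr, sets, alpha = 0.25) {
  expr <- asNamedMatrix(expr, "expression matrix")
  N <- nrow(expr)
  out <- matrix(0, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (si in seq_along(sets)) {
    members <- intersect(sets[[si]], rownames(expr))
    if (!length(members)) {
      warning("set '", names(sets)[si],
              "' shares no gene with the matrix; scored 0")
      next
    }
    isHit <- rownames(expr) %in% members
    for (j in seq_len(ncol(expr))) {
      rk <- rank(expr[, j], ties.method = "average")
      ord <- order(-rk)
      hitOrd <- isHit[ord]
      w <- rk[ord]^alpha
      stepHit <- ifelse(hitOrd, w, 0)
      pHit <- cumsum(stepHit) / sum(stepHit)
      pMiss <- cumsum(!hitOrd) / (N - sum(isHit))
      out[si, j] <- sum(pHit - pMiss)
    }
  }
  out
}
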