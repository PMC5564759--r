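#' Correlate module eigengenes with metabolites
#'
#' Pearson correlation over the samples shared by both assays, with exact
#' two-sided p-values from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom and Benjamini-Hochberg adjustment across the whole
#' module x metabolite matrix.
#'
#' @param eigengenes module x sample matrix.
#' @param metabolites metabolites x samples matrix or
#'   [MetaboliteMatrix-class].
#' @return A [ModuleMetaboliteCorrelation-class].
#' @export
correlateModulesMetabolites <- function(eigengenes, metabolites) {
  if (is(metabolites, "MetaboliteMatrix"))
    metabolites <- values(metabolites)
  eigengenes <- asNamedMatrix(eigengenes, "eigengene matrix")
  metabolites <- asNamedMatrix(metabolites, "metabolite matrix")
  shared <- intersect(colnames(eigengenes), colnames(metabolites))
  if (length(shared) < 3)
    stop("insufficient overlap: ", length(shared),
         " shared sample(s); at least 3 required")
  n <- length(shared)
  r <- stats::cor(t(eigengenes[, shared, drop = FALSE]),
                  t(metabolites[, shared, drop = FALSE]),
                  use = "pairwise.complete.obs")
  p <- correlationPValue(r, n)
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  new("ModuleMetaboliteCorrelation", r = r, p = p, padj = padj,
      nOverlap = as.integer(n))
}

#' Two-sided p-value of a Pearson correlation
#'
#' Exact t transform: \eqn{t = r\sqrt{(n-2)/(1-r^2)}} referred to the t
#' distribution with n - 2 degrees of freedom. |r| = 1 maps to p = 0.
#'
#' @param r correlation(s), numeric or matrix.
#' @param n sample size (> 2).
#' @return p-values with the shape of \code{r}.
#' @export
correlationPValue <- function(r, n) {
  if (n <= 2)
    stop("n must exceed 2")
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p
}

#' Joint meta-clustering of modules and metabolites ("Cluster of Clusters")
#'
#' Each module is represented by its association-strength profile (absolute
#' correlation) across metabolites and each metabolite by its profile across
#' modules. A joint similarity is assembled from Pearson correlations of
#' those profiles (module-module via metabolite profiles,
#' metabolite-metabolite via module profiles) and the direct absolute
#' correlation for module-metabolite pairs. Working on absolute profiles
#' makes the result invariant to the arbitrary sign of any eigengene.
#' Entities are clustered by average linkage on 1 - similarity and the tree
#' is cut to k clusters (automatic mode: the k in 2..8 with the largest
#' mean silhouette width).
#'
#' @param cm a [ModuleMetaboliteCorrelation-class].
#' @param k number of meta-clusters, or \code{"auto"}.
#' @return A [MetaClustering-class].
#' @export
clusterOfClusters <- function(cm, k = 4) {
  stopifnot(is(cm, "ModuleMetaboliteCorrelation"))
  r <- cm@r
  nMod <- nrow(r)
  nMet <- ncol(r)
  nEnt <- nMod + nMet
  if (is.numeric(k) && k > nEnt)
    stop("invalid config: k exceeds the number of entities (", nEnt, ")")
  a <- abs(r)   # association strength; invariant to eigengene sign
  sim <- matrix(NA_real_, nEnt, nEnt)
  ids <- c(rownames(r), colnames(r))
  types <- c(rep("module", nMod), rep("metabolite", nMet))
  dimnames(sim) <- list(ids, ids)
  if (nMod > 1)
    sim[seq_len(nMod), seq_len(nMod)] <- stats::cor(t(a))
  if (nMet > 1)
    sim[nMod + seq_len(nMet), nMod + seq_len(nMet)] <- stats::cor(a)
  sim[seq_len(nMod), nMod + seq_len(nMet)] <- a
  sim[nMod + seq_len(nMet), seq_len(nMod)] <- t(a)
  diag(sim) <- 1
  sim[is.na(sim)] <- 0   # degenerate constant profiles
  d <- stats::as.dist(1 - (sim + t(sim)) / 2)
  tree <- stats::hclust(d, method = "average")
  if (identical(k, "auto")) {
    ks <- 2:min(8, nEnt - 1)
    sil <- vapply(ks, function(kk) {
      lab <- stats::cutree(tree, k = kk)
      mean(cluster::silhouette(lab, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  lab <- stats::cutree(tree, k = k)
  new("MetaClustering",
      labels = data.frame(entity = ids, type = types,
                          cluster = as.integer(lab),
                          stringsAsFactors = FALSE),
      nClusters = as.integer(k), tree = tree)
}

#' Key metabolite of each meta-cluster
#'
#' Within every meta-cluster, each metabolite is scored by the sum of its
#' absolute correlations with the modules of the same cluster; the key
#' metabolite is the top scorer (ties broken lexicographically with a
#' warning). Clusters without a metabolite are reported keyless (NA).
#'
#' @param mc a [MetaClustering-class].
#' @param cm the matching [ModuleMetaboliteCorrelation-class].
#' @return data.frame with columns cluster, metabolite, score.
#' @export
keyMetabolites <- function(mc, cm) {
  stopifnot(is(mc, "MetaClustering"),
            is(cm, "ModuleMetaboliteCorrelation"))
  lab <- mc@labels
  out <- lapply(sort(unique(lab$cluster)), function(cl) {
    mets <- lab$entity[lab$cluster == cl & lab$type == "metabolite"]
    mods <- lab$entity[lab$cluster == cl & lab$type == "module"]
    if (!length(mets))
      return(data.frame(cluster = cl, metabolite = NA_character_,
                        score = NA_real_))
    score <- if (length(mods))
      colSums(abs(cm@r[mods, mets, drop = FALSE]))
    else stats::setNames(rep(0, length(mets)), mets)
    top <- max(score)
    winners <- sort(names(score)[score == top])
    if (length(winners) > 1)
      warning("tie for key metabolite in cluster ", cl,
              "; choosing lexicographically: ", winners[1])
    data.frame(cluster = cl, metabolite = winners[1], score = top)
  })
  do.call(rbind, out)
}

#' Export the bipartite module/gene-metabolite network
#'
#' Edges are all module-metabolite pairs whose |correlation| reaches the
#' threshold, optionally augmented with gene-metabolite edges from the gene
#' significance table. A node's score is its weighted degree (sum of
#' |weight| over incident edges); nodes above the hub quantile of scores
#' are flagged as hubs.
#'
#' @param cm a [ModuleMetaboliteCorrelation-class].
#' @param gs optional genes x metabolites gene-significance matrix.
#' @param threshold |correlation| cutoff in [0, 1].
#' @param hubQuantile quantile of node scores above which a node is a hub.
#' @return A [BipartiteNetwork-class].
#' @export
exportNetwork <- function(cm, gs = NULL, threshold = 0.5,
                          hubQuantile = 0.9) {
  stopifnot(is(cm, "ModuleMetaboliteCorrelation"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  edgeOf <- function(mat, type) {
    hit <- which(abs(mat) >= threshold, arr.ind = TRUE)
    if (!nrow(hit))
      return(NULL)
    data.frame(source = rownames(mat)[hit[, 1]],
               target = colnames(mat)[hit[, 2]],
               weight = mat[hit], type = type,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edgeOf(cm@r, "module-metabolite"),
                 if (!is.null(gs)) edgeOf(as.matrix(gs), "gene-metabolite"))
  if (is.null(edges) || !nrow(edges)) {
    warning("threshold ", threshold, " produced an empty network")
    return(new("BipartiteNetwork",
               edges = data.frame(source = character(0),
                                  target = character(0),
                                  weight = numeric(0),
                                  type = character(0)),
               nodeScores = stats::setNames(numeric(0), character(0)),
               hubs = character(0)))
  }
  nodes <- unique(c(edges$source, edges$target))
  scores <- vapply(nodes, function(nd)
    sum(abs(edges$weight[edges$source == nd | edges$target == nd])),
    numeric(1))
  cut <- stats::quantile(scores, hubQuantile)
  hubs <- names(scores)[scores > cut]
  new("BipartiteNetwork", edges = edges, nodeScores = scores, hubs = hubs)
}
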