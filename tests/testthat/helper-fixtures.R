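# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Reference planted cohort (6 modules x 50 genes, 700 background, n = 60,
# loadings 0.6-0.95) and the network built on it with package defaults.
referenceNetwork <- function() {
  if (is.null(.fixtures$refNet)) {
    sim <- simulateExpression(simulationConfig(seed = 42))
    net <- buildNetwork(sim$expression, networkConfig())
    .fixtures$refNet <- list(sim = sim, net = net)
  }
  .fixtures$refNet
}

# Map each planted module to the detected module holding most of its genes.
plantedToDetected <- function(planted, detected) {
  vapply(sort(setdiff(unique(planted), 0L)), function(m) {
    tt <- table(detected[planted == m & detected != 0])
    if (!length(tt)) return(NA_integer_)
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
}

# Double-loop TOM oracle, straight from the defining formula.
tomOracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Random symmetric adjacency with unit diagonal, entries in [0, 1].
randomAdjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

randomExprMatrix <- function(nGenes, nSamples, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
         dimnames = list(paste0("g", seq_len(nGenes)),
                         paste0("S", seq_len(nSamples))))
}

# Small planted cohort for the integration stage: eigengenes from true
# labels plus metabolites bound to the same factors.
integrationFixture <- function(spec, seed, nModules = max(spec$module),
                               genesPerModule = 30) {
  cfg <- simulationConfig(nSamples = 60, nModules = nModules,
                          genesPerModule = genesPerModule,
                          nBackgroundGenes = 0, metaboliteSpec = spec,
                          seed = seed)
  sim <- simulateExpression(cfg)
  me <- moduleEigengene(sim$expression, sim$moduleLabels)
  mets <- simulateMetabolites(sim$factors, spec, seed = seed + 10000)
  list(me = me, metabolites = mets$metabolites)
}
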