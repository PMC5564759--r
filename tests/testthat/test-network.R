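test_that("correlation matrix matches a double-loop Pearson oracle", {
  x <- randomExprMatrix(5, 4, seed = 31)
  cc <- correlationMatrix(x)
  oracle <- diag(5)
  for (i in 1:5) for (j in 1:5)
    if (i != j) oracle[i, j] <- cor(x[i, ], x[j, ])
  dimnames(oracle) <- dimnames(cc)
  expect_equal(cc, oracle, tolerance = 1e-12)

  # duplicated gene and negated gene
  y <- rbind(x, dup = x[1, ], neg = -x[1, ])
  cc2 <- correlationMatrix(y)
  expect_equal(cc2["g1", "dup"], 1, tolerance = 1e-12)
  expect_equal(cc2["g1", "neg"], -1, tolerance = 1e-12)

  # constant genes flagged and removed
  z <- rbind(x, flat = rep(2, 4))
  expect_warning(cc3 <- correlationMatrix(z), "constant gene")
  expect_false("flat" %in% rownames(cc3))
})

test_that("adjacency follows the soft-threshold transforms", {
  cc <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(adjacencyMatrix(cc, 6)[1, 2], 0.5^6)
  ccn <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(adjacencyMatrix(ccn, 6)[1, 2], 0.5^6)       # unsigned parity
  ccm <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(adjacencyMatrix(ccm, 3, "signed")[1, 2], 0) # signed kill
  expect_error(adjacencyMatrix(cc, 0), "positive")

  # raising beta weakly sparsifies off-diagonal entries
  set.seed(8)
  r <- correlationMatrix(randomExprMatrix(10, 12, seed = 8))
  a2 <- adjacencyMatrix(r, 2); a6 <- adjacencyMatrix(r, 6)
  off <- upper.tri(r)
  expect_true(all(a6[off] <= a2[off] + 1e-15))
})

test_that("soft threshold selection follows the scale-free fit rule", {
  ref <- referenceNetwork()
  pick <- pickSoftThreshold(correlationMatrix(ref$sim$expression),
                            networkConfig())
  expect_true(is.finite(pick$beta))
  ok <- subset(pick$fitTable, power <= 12 & fit >= 0.8)
  expect_gt(nrow(ok), 0)

  # single candidate: forced choice with warning
  cc <- correlationMatrix(randomExprMatrix(20, 10, seed = 2))
  expect_warning(
    one <- pickSoftThreshold(cc, networkConfig(powerCandidates = 6,
                                               targetR2 = 0.99)),
    "no candidate")
  expect_equal(one$beta, 6)

  expect_error(pickSoftThreshold(diag(10)), "degenerate network")
})

test_that("topological overlap matches formula and brute-force oracle", {
  # hand-evaluated 3-gene case
  a <- matrix(c(1, 0.8, 0.4,
                0.8, 1, 0.2,
                0.4, 0.2, 1), 3, byrow = TRUE)
  tom <- topologicalOverlap(a)
  expect_equal(tom[1, 2], 0.88 / 1.2, tolerance = 1e-12)

  # zero off-diagonal adjacency -> zero off-diagonal TOM
  z <- diag(4)
  expect_true(all(topologicalOverlap(z)[upper.tri(z)] == 0))

  # clique adjacency -> all-ones TOM
  one <- matrix(1, 5, 5)
  expect_true(all(topologicalOverlap(one) == 1))

  # random adjacency vs double-loop oracle; range and symmetry
  a20 <- randomAdjacency(20, seed = 5)
  t20 <- topologicalOverlap(a20)
  expect_lt(max(abs(t20 - tomOracle(a20))), 1e-10)
  expect_true(isSymmetric(unname(t20), tol = 1e-12))
  expect_true(all(t20 >= 0 & t20 <= 1 + 1e-12))

  asym <- a20; asym[1, 2] <- 0
  expect_error(topologicalOverlap(asym), "symmetric")
})

test_that("module detection recovers block structure and handles edge cases", {
  # two perfect blocks
  tom <- matrix(0.05, 10, 10,
                dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
  tom[1:5, 1:5] <- 0.9
  tom[6:10, 6:10] <- 0.9
  diag(tom) <- 1
  lab <- detectModules(tom, networkConfig(minModuleSize = 3,
                                          cutHeight = 0.5))
  expect_identical(length(unique(lab[lab != 0])), 2L)
  expect_identical(length(unique(lab[1:5])), 1L)
  expect_identical(length(unique(lab[6:10])), 1L)

  # cut below all merge heights: everything unassigned with a warning
  expect_warning(
    lab0 <- detectModules(tom, networkConfig(minModuleSize = 3,
                                             cutHeight = 0.01)),
    "empty partition")
  expect_true(all(lab0 == 0))
})

test_that("module eigengenes summarize and orient correctly", {
  # identical genes: eigengene correlates 1 with each
  x <- matrix(rep(sin(1:20), 4), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("S", 1:20)))
  x <- x + matrix(rnorm(80, sd = 1e-8), 4)
  lab <- setNames(rep(1L, 4), rownames(x))
  me <- moduleEigengene(x, lab)
  expect_gt(min(cor(me[1, ], t(x))), 1 - 1e-6)

  # flipping all module genes flips the eigengene
  meFlip <- moduleEigengene(-x, lab)
  expect_equal(meFlip[1, ], -me[1, ], tolerance = 1e-8)

  # single-gene module equals that standardized gene
  g <- randomExprMatrix(1, 15, seed = 3)
  me1 <- moduleEigengene(g, setNames(1L, "g1"))
  expect_equal(unname(me1[1, ]), as.numeric(scale(g[1, ])),
               tolerance = 1e-12)

  # planted module: eigengene tracks the latent factor
  ref <- referenceNetwork()
  sim <- ref$sim
  meTrue <- moduleEigengene(sim$expression, sim$moduleLabels)
  for (m in 1:6)
    expect_gte(abs(cor(meTrue[paste0("ME", m), ], sim$factors[m, ])), 0.9)

  # first-PC optimality: projection variance equals the top singular share
  sub <- sim$expression[sim$moduleLabels == 1, ][1:10, ]
  stdSub <- t(scale(t(sub)))
  sv <- svd(stdSub)
  e <- moduleEigengene(sub, setNames(rep(1L, 10), rownames(sub)))[1, ]
  expect_equal(abs(cor(e, sv$v[, 1])), 1, tolerance = 1e-9)
})

test_that("gene significance uses the sample intersection", {
  x <- randomExprMatrix(4, 10, seed = 6)
  met <- matrix(x[2, 1:8], 1, dimnames = list("m", colnames(x)[1:8]))
  gs <- geneSignificance(x, met)
  expect_equal(gs["g2", "m"], 1, tolerance = 1e-12)
  expect_identical(attr(gs, "nOverlap"), 8L)

  met2 <- matrix(rnorm(2), 1, dimnames = list("m", colnames(x)[1:2]))
  expect_error(geneSignificance(x, met2), "insufficient overlap")

  # independent metabolite: |GS| < 0.5 essentially always at n = 60
  big <- randomExprMatrix(50, 60, seed = 7)
  set.seed(17)
  nullMet <- matrix(rnorm(60), 1, dimnames = list("m", colnames(big)))
  expect_gte(mean(abs(geneSignificance(big, nullMet)) < 0.5), 0.99)
})

test_that("module membership equals per-pair correlation", {
  x <- randomExprMatrix(10, 20, seed = 9)
  lab <- setNames(rep(1:2, each = 5), rownames(x))
  me <- moduleEigengene(x, lab)
  km <- moduleMembership(x, me)
  for (g in rownames(x)) for (m in rownames(me))
    expect_equal(km[g, m], cor(x[g, ], me[m, ]), tolerance = 1e-12)

  # gene identical to an eigengene scores kME = 1
  x2 <- rbind(x, e1 = me[1, ])
  km2 <- moduleMembership(x2, me)
  expect_equal(km2["e1", "ME1"], 1, tolerance = 1e-12)
})

test_that("planted modules are recovered by the full network pipeline", {
  ref <- referenceNetwork()
  det <- moduleLabels(ref$net)
  planted <- ref$sim$moduleLabels[names(det)]
  assigned <- det != 0
  ari <- mclust::adjustedRandIndex(det[assigned], planted[assigned])
  expect_gte(ari, 0.8)
})
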