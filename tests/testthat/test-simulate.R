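test_that("expression generator plants standardized, recoverable modules", {
  cfg <- simulationConfig(nSamples = 40, nModules = 3, genesPerModule = 20,
                          nBackgroundGenes = 60, seed = 11)
  sim <- simulateExpression(cfg)
  expect_identical(dim(sim$expression), c(120L, 40L))
  expect_lt(max(abs(rowMeans(sim$expression))), 1e-9)
  expect_lt(max(abs(apply(sim$expression, 1, sd) - 1)), 1e-9)
  expect_identical(sum(sim$moduleLabels == 0), 60L)

  # planted structure recoverable: within-module correlation dominates
  cc <- cor(t(sim$expression))
  within <- mean(abs(cc[sim$moduleLabels == 1, sim$moduleLabels == 1]))
  cross <- mean(abs(cc[sim$moduleLabels == 1, sim$moduleLabels == 0]))
  expect_gt(within, cross)

  # each module gene correlates best with its own factor
  own <- sapply(which(sim$moduleLabels > 0), function(g) {
    r <- abs(cor(sim$expression[g, ], t(sim$factors)))
    which.max(r) == sim$moduleLabels[g]
  })
  expect_gt(mean(own), 0.95)
})

test_that("degenerate loading range makes module genes equal their factor", {
  cfg <- simulationConfig(nSamples = 10, nModules = 1, genesPerModule = 4,
                          nBackgroundGenes = 0, loadingRange = c(1, 1),
                          seed = 2)
  sim <- simulateExpression(cfg)
  cc <- cor(t(sim$expression))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)
})

test_that("generators are deterministic and seed-sensitive", {
  cfg <- simulationConfig(nSamples = 10, nModules = 2, genesPerModule = 5,
                          nBackgroundGenes = 5, seed = 7)
  expect_identical(simulateExpression(cfg), simulateExpression(cfg))
  cfg2 <- simulationConfig(nSamples = 10, nModules = 2, genesPerModule = 5,
                           nBackgroundGenes = 5, seed = 8)
  expect_false(identical(simulateExpression(cfg)$expression,
                         simulateExpression(cfg2)$expression))
  # no global RNG leak
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateExpression(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulationConfig(nSamples = 2), "at least 3")
  expect_error(simulationConfig(nModules = 0), "positive integer")
  expect_error(simulationConfig(loadingRange = c(0, 0.5)), "loadingRange")
  expect_error(simulationConfig(
    metaboliteSpec = data.frame(metabolite = "m", module = 1, r = 1.2)),
    "exceed 1")
  expect_error(simulationConfig(
    nModules = 2,
    metaboliteSpec = data.frame(metabolite = "m", module = 5, r = 0.5)),
    "nonexistent module")
})

test_that("metabolite generator hits its target correlations", {
  cfg <- simulationConfig(nSamples = 60, nModules = 2, genesPerModule = 5,
                          nBackgroundGenes = 0, seed = 5)
  sim <- simulateExpression(cfg)

  # exact limit: r = 1 reproduces the factor
  spec1 <- data.frame(metabolite = "m", module = 1, r = 1)
  m1 <- simulateMetabolites(sim$factors, spec1, seed = 1)
  expect_equal(cor(m1$metabolites["m", ], sim$factors[1, ]), 1,
               tolerance = 1e-12)

  # r = 0.8: empirical correlation within the Fisher-z band for n = 60
  spec <- data.frame(metabolite = "m", module = 1, r = 0.8)
  hits <- vapply(1:100, function(s) {
    m <- simulateMetabolites(sim$factors, spec, seed = s)
    r <- cor(m$metabolites["m", ], sim$factors[1, ])
    r >= 0.6 && r <= 0.95
  }, logical(1))
  expect_gte(sum(hits), 95)

  # r = 0 (unassociated): |cor| < 0.5 essentially always
  spec0 <- data.frame(metabolite = "m", module = NA, r = 0)
  null <- vapply(1:100, function(s) {
    m <- simulateMetabolites(sim$factors, spec0, seed = s + 500)
    abs(cor(m$metabolites["m", ], sim$factors[1, ])) < 0.5
  }, logical(1))
  expect_gte(sum(null), 99)

  expect_error(
    simulateMetabolites(sim$factors,
                        data.frame(metabolite = "m", module = 1, r = 1.01)),
    "invalid config")
})

test_that("spectrum generator matches the weighted template sum", {
  lib <- defaultTemplateLibrary()
  conc <- c(lactate = 2, glycine = 0.5)
  sim <- simulateSpectrum(conc, lib, snr = NULL, shiftJitter = 0, seed = 1)
  x <- ppm(sim$spectrum)
  manual <- 2 * evaluateTemplate(lib@templates[["lactate"]], x) +
    0.5 * evaluateTemplate(lib@templates[["glycine"]], x)
  expect_equal(intensity(sim$spectrum), manual, tolerance = 1e-12)

  one <- simulateSpectrum(c(glycine = 1), lib, snr = NULL, seed = 1)
  tplMax <- max(evaluateTemplate(lib@templates[["glycine"]],
                                 ppm(one$spectrum)))
  expect_equal(max(intensity(one$spectrum)), tplMax, tolerance = 1e-12)

  expect_error(simulateSpectrum(c(glycine = -1), lib), "nonnegative")
  expect_error(simulateSpectrum(c(unknown = 1), lib), "unknown metabolite")
})

test_that("injected spectral noise is recovered by oracle reconstruction", {
  lib <- defaultTemplateLibrary()
  conc <- c(lactate = 2, creatine = 1, glycine = 0.8, choline = 0.6,
            `myo-inositol` = 1.2)
  sim <- simulateSpectrum(conc, lib, snr = 50, shiftJitter = 0.005,
                          seed = 21)
  x <- ppm(sim$spectrum)
  clean <- Reduce(`+`, lapply(names(conc), function(m)
    conc[[m]] * evaluateTemplate(lib@templates[[m]], x - sim$shifts[[m]])))
  resid <- intensity(sim$spectrum) - clean
  expect_lt(abs(sd(resid) - sim$noiseSd) / sim$noiseSd, 0.2)
})

test_that("survival generator honours hazards and censoring", {
  groups <- setNames(rep(c("A", "B"), each = 200), paste0("S", 1:400))

  # no censoring: every subject has an event
  s0 <- simulateSurvival(groups, c(A = 0.05, B = 0.05), censorRate = 0,
                         seed = 1)
  expect_true(all(s0$event == 1))

  # identical hazards: log-rank statistic small on average
  chis <- vapply(1:20, function(s) {
    tab <- simulateSurvival(groups, c(A = 0.05, B = 0.05),
                            censorRate = 0.2, seed = s)
    logrankTest(tab)$chisq
  }, numeric(1))
  expect_lt(mean(chis), 3)   # E[chi-square_1] = 1 under the null

  expect_error(simulateSurvival(groups, c(A = 0.05), censorRate = 0),
               "unknown group")
  expect_error(simulateSurvival(groups, c(A = 0.05, B = -1)), "positive")
})

test_that("simulateCohort assembles a consistent object", {
  cfg <- simulationConfig(
    nSamples = 12, nModules = 2, genesPerModule = 5, nBackgroundGenes = 5,
    metaboliteSpec = data.frame(metabolite = "lactate", module = 1,
                                r = 0.8),
    seed = 3)
  co <- simulateCohort(cfg)
  expect_s4_class(co, "SyntheticCohort")
  expect_identical(colnames(co@expression), colnames(co@metabolites))
  expect_setequal(co@survival$sample, colnames(co@expression))
  expect_true(validObject(co))
})
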