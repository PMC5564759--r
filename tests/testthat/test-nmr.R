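test_that("spectrum files round-trip and malformed input is located", {
  p <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("1.310 5.0", "1.311 4.9"), p)
  s <- readSpectrum(p)
  expect_length(ppm(s), 2)
  expect_equal(intensity(s), c(5.0, 4.9))

  # descending axis is stored ascending with intensities reordered
  writeLines(c("3.0 1", "2.0 2", "1.0 3"), p)
  s <- readSpectrum(p)
  expect_equal(ppm(s), c(1, 2, 3))
  expect_equal(intensity(s), c(3, 2, 1))

  writeLines(character(0), p)
  expect_error(readSpectrum(p), "parse error")

  writeLines(c("ppm\tintensity", "1.0\t2.0", "1.1\tx"), p)
  expect_error(readSpectrum(p), "line 3")

  set.seed(4)
  s0 <- Spectrum(sort(runif(50, 0, 5)), rnorm(50), "rt")
  writeSpectrum(s0, p)
  s1 <- readSpectrum(p)
  expect_equal(ppm(s1), ppm(s0), tolerance = 1e-12)
  expect_equal(intensity(s1), intensity(s0), tolerance = 1e-12)
})

test_that("lactate calibration shifts the apex to the reference", {
  lib <- defaultTemplateLibrary()
  base <- simulateSpectrum(c(lactate = 1), lib, snr = NULL, seed = 1)$spectrum
  step <- diff(ppm(base))[1]

  # apex moved to 1.330: offset must be -0.020 within one grid step
  shifted <- Spectrum(ppm(base) + 0.020, intensity(base))
  cal <- calibrateToLactate(shifted)
  expect_lt(abs(cal$offset - (-0.020)), step + 1e-12)
  apex <- ppm(cal$spectrum)[which.max(intensity(cal$spectrum))]
  expect_lt(abs(apex - 1.310), step + 1e-12)

  # apex already on reference: offset 0
  cal0 <- calibrateToLactate(base)
  expect_equal(cal0$offset, 0)

  flat <- Spectrum(seq(1, 2, by = 0.01), rep(1, 101))
  expect_error(calibrateToLactate(flat), "no unique apex")
  expect_error(calibrateToLactate(base, window = c(8, 9)),
               "calibration error")
})

test_that("noiseless mixtures are recovered exactly", {
  lib <- defaultTemplateLibrary()
  sim <- simulateSpectrum(c(lactate = 2, creatine = 0.5), lib, snr = NULL,
                          seed = 1)
  fit <- fitSpectrum(sim$spectrum, lib, fitConfig(maxShift = 0))
  expect_lt(abs(fit@intensities[["lactate"]] - 2) / 2, 1e-6)
  expect_lt(abs(fit@intensities[["creatine"]] - 0.5) / 0.5, 1e-6)
  expect_lt(fit@relativeResidual, 1e-8)
  expect_true(fit@passedQC)
  expect_true(all(fit@intensities >= 0))
})

test_that("noisy mixtures are recovered within tolerance", {
  lib <- defaultTemplateLibrary()
  conc <- c(lactate = 2, creatine = 1, glycine = 0.8, choline = 0.6,
            `myo-inositol` = 1.2)
  sim <- simulateSpectrum(conc, lib, snr = 50, seed = 3)
  fit <- fitSpectrum(sim$spectrum, lib,
                     fitConfig(maxShift = 0.004, shiftGridStep = 0.002))
  rel <- abs(fit@intensities[names(conc)] - conc) / conc
  expect_true(all(rel < 0.1))
})

test_that("a planted chemical shift is recovered on the search grid", {
  lib <- defaultTemplateLibrary()
  x <- seq(0.5, 4.5, by = 0.001)
  y <- evaluateTemplate(lib@templates[["glycine"]], x - 0.008)
  fit <- fitSpectrum(Spectrum(x, y), lib,
                     fitConfig(maxShift = 0.01, shiftGridStep = 0.001))
  expect_lt(abs(fit@shifts[["glycine"]] - 0.008), 0.001 + 1e-12)
})

test_that("degenerate spectra are rejected", {
  lib <- defaultTemplateLibrary()
  x <- seq(0.5, 4.5, by = 0.01)
  expect_error(fitSpectrum(Spectrum(x, rep(0, length(x))), lib),
               "degenerate")
  expect_error(fitSpectrum(Spectrum(x, c(NA, rep(1, length(x) - 1))), lib),
               "data error")
  far <- Spectrum(seq(8, 9, by = 0.01), rep(1, 101))
  expect_error(fitSpectrum(far, lib), "no template overlaps")
})

test_that("quantifySpectra excludes spectra failing quality control", {
  lib <- defaultTemplateLibrary()
  good <- simulateSpectrum(c(lactate = 2, glycine = 1), lib, snr = 400,
                           seed = 1, sampleId = "good")$spectrum
  set.seed(9)
  junk <- Spectrum(ppm(good), abs(rnorm(length(ppm(good)))), "junk")
  q <- quantifySpectra(list(good, junk), lib,
                       fitConfig(maxShift = 0), calibrate = FALSE)
  expect_identical(q$excluded, "junk")
  expect_identical(colnames(values(q$matrix)), "good")
  expect_identical(stage(q$matrix), "raw")
})

test_that("DNA normalization divides by per-sample concentration", {
  m <- MetaboliteMatrix(matrix(c(10, 20, 6, 8), 2,
                               dimnames = list(c("a", "b"),
                                               c("S1", "S2"))))
  out <- normalizeDNA(m, c(S1 = 2, S2 = 1))
  expect_equal(values(out)[, "S1"], c(a = 5, b = 10))
  expect_equal(values(out)[, "S2"], c(a = 6, b = 8))
  expect_identical(stage(out), "dna_normalized")

  # unit concentrations are the identity
  id <- normalizeDNA(m, c(S1 = 1, S2 = 1))
  expect_equal(values(id), values(m))

  expect_error(normalizeDNA(m, c(S1 = 0, S2 = 1)), "positive")
  expect_error(normalizeDNA(m, c(S1 = 2)), "no DNA concentration")
})

test_that("median normalization equalizes column medians", {
  m <- MetaboliteMatrix(matrix(c(1, 2, 3, 2, 4, 6), 3,
                               dimnames = list(c("a", "b", "c"),
                                               c("S1", "S2"))))
  out <- normalizeMedian(m)
  meds <- apply(values(out), 2, median)
  expect_identical(unname(meds[1]), unname(meds[2]))
  expect_equal(unname(meds), c(3, 3))  # reference = median(2, 4) = 3

  # identical columns and single columns are fixed points
  same <- MetaboliteMatrix(matrix(c(1, 2, 3, 1, 2, 3), 3,
                                  dimnames = list(letters[1:3],
                                                  c("S1", "S2"))))
  expect_equal(values(normalizeMedian(same)), values(same))
  single <- MetaboliteMatrix(matrix(1:3, 3,
                                    dimnames = list(letters[1:3], "S1")))
  expect_equal(values(normalizeMedian(single)), values(single))

  zero <- MetaboliteMatrix(matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("S1", "S2"))))
  expect_error(normalizeMedian(zero), "positive median")
})

test_that("composed normalization is scale-equivariant per column", {
  set.seed(12)
  raw <- matrix(abs(rnorm(15, 10)), 5,
                dimnames = list(paste0("m", 1:5), paste0("S", 1:3)))
  dna <- c(S1 = 1.5, S2 = 0.7, S3 = 2.2)
  pipelineOf <- function(x)
    values(normalizeMedian(normalizeDNA(MetaboliteMatrix(x), dna)))
  ref <- pipelineOf(raw)
  # rescale the column with the largest DNA-normalized median; the
  # median-of-medians reference is unchanged, so the output is too
  meds <- apply(sweep(raw, 2, dna, `/`), 2, median)
  hi <- which.max(meds)
  scaled <- raw
  scaled[, hi] <- scaled[, hi] * 37.5
  expect_equal(pipelineOf(scaled), ref, tolerance = 1e-12)
})
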