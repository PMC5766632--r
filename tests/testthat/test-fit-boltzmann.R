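test_that("noiseless Boltzmann curves are recovered to 1e-6", {
  cases <- list(c(v12 = -51.8, k = 11.5), c(v12 = -43.7, k = 10.1),
                c(v12 = -66.2, k = 7.0))
  for (cs in cases) {
    p <- PhenoParams("x", inactV12 = cs[["v12"]], inactSlope = cs[["k"]])
    fit <- fitBoltzmann(genPhenoSeries(p, "ssi", ssiGrid()))
    expect_equal(midpoint(fit), cs[["v12"]], tolerance = 1e-6)
    expect_equal(slopeFactor(fit), cs[["k"]], tolerance = 1e-6)
    expect_lt(residualRMS(fit), 1e-8)
  }
})

test_that("the effective valence follows z = RT/(F k) with delta-method SE", {
  p <- PhenoParams("x", inactV12 = -43.7, inactSlope = 10.1)
  fit <- fitBoltzmann(genPhenoSeries(p, "ssi", ssiGrid(),
                                     temperature = 291.15))
  expect_equal(effectiveValence(fit), 2.484, tolerance = 1e-3)
  ## identity by construction, asserted
  expect_equal(effectiveValence(fit) * slopeFactor(fit),
               rtfMillivolts(291.15), tolerance = 1e-12)
  ## with the slope fixed in mV, the derived valence scales with RT
  fitWarm <- fitBoltzmann(genPhenoSeries(p, "ssi", ssiGrid()),
                          temperature = 310)
  expect_equal(effectiveValence(fitWarm) / effectiveValence(fit),
               310 / 291.15, tolerance = 1e-9)
})

test_that("non-identifiable series are rejected", {
  flat <- new("PeakSeries", constructId = "flat", protocolKind = "ssi",
              x = ssiGrid(),
              y = matrix(0.5, 1, length(ssiGrid())), temperature = 291.15)
  expect_error(fitBoltzmann(flat), "identifiable")
  few <- genPhenoSeries(wtPheno(), "ssi", c(-60, -50, -40, -30))
  expect_error(fitBoltzmann(few), "5 distinct")
})

test_that("the estimator is unbiased over repeated noisy replicates of the
           wild-type scenario", {
  p <- wtPheno()
  base <- genPhenoSeries(p, "ssi", ssiGrid())
  v12s <- vapply(1:200, function(i) {
    noisy <- addNoise(base, sigma = 0.02, nReplicates = 7, seed = 1000 + i)
    midpoint(fitBoltzmann(noisy))
  }, numeric(1))
  expect_lt(abs(mean(v12s) - (-43.7)), 0.3)
})

test_that("fit tables carry construct ids, group sizes and the valence", {
  fits <- list(wt = fitBoltzmann(genPhenoSeries(wtPheno(), "ssi", ssiGrid())))
  ft <- fitTable(fits, n = 8L)
  expect_identical(ft$constructId, "wt")
  expect_identical(ft$n, 8L)
  expect_equal(ft$z * ft$slope, rtfMillivolts(ft$temperature),
               tolerance = 1e-12)
})
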