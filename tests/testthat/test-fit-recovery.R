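test_that("noiseless two-exponential recovery is recovered exactly", {
  p <- wtPheno()
  ser <- genPhenoSeries(p, "recovery", recGrid1s(), recoveryClass = "p1s")
  fit <- fitRecovery(ser, 2)
  expect_equal(fit@amplitudes, c(0.70, 0.30), tolerance = 1e-6)
  expect_equal(fit@tau, c(486.5, 2588.1), tolerance = 1e-6)
  expect_equal(fit@offset, 1, tolerance = 1e-6)
  expect_lt(residualRMS(fit), 1e-8)
})

test_that("noiseless three-exponential recovery is recovered exactly with
           ascending time constants", {
  ser <- genPhenoSeries(wtPheno(), "recovery", recGrid100())
  fit <- fitRecovery(ser, 3)
  expect_equal(fit@amplitudes, c(0.50, 0.25, 0.25), tolerance = 1e-6)
  expect_equal(fit@tau, c(0.8, 231.8, 1667.8), tolerance = 1e-6)
  expect_false(is.unsorted(fit@tau))
  ## shipped wild-type amplitudes sum to complete recovery
  expect_equal(sum(fit@amplitudes), 1.00, tolerance = 1e-6)
})

test_that("over-parameterized fits collapse an amplitude or flag tau
           degeneracy", {
  p <- PhenoParams("mono", recovery = list(
    p100ms = data.frame(amplitude = 0.8, tau = 50)))
  ser <- genPhenoSeries(p, "recovery", recGrid100())
  fit <- fitRecovery(ser, 2)
  expect_true(min(fit@amplitudes) < 1e-3 ||
                "tau_degenerate" %in% fitFlags(fit) ||
                "amplitude_collapsed" %in% fitFlags(fit))
  expect_lt(residualRMS(fit), 1e-6)
})

test_that("noisy triple-exponential data recover the generating components
           within the calibrated tolerances", {
  ser <- genPhenoSeries(wtPheno(), "recovery", recGrid100())
  noisy <- addNoise(ser, sigma = 0.01, nReplicates = 6, seed = 21)
  fit <- fitRecovery(noisy, 3)
  expect_true(all(abs(fit@amplitudes - c(0.50, 0.25, 0.25)) <= 0.05))
  expect_true(all(abs(fit@tau / c(0.8, 231.8, 1667.8) - 1) <= 0.20))
})

test_that("guards reject unusable interval grids", {
  ser <- genPhenoSeries(wtPheno(), "recovery", seq(10, 100, by = 10))
  expect_error(fitRecovery(ser, 3), "3 decades")
})
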