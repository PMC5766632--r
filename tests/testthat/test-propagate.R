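test_that("a scheme with all rates zero has frozen dynamics", {
  sc <- twoStateScheme(kOn = 0, kOff = 0)
  p0 <- c(0.3, 0.7)
  tr <- propagateScheme(sc, ssiProtocol(conditioningVoltages = c(-80, -40),
                                        sampleInterval = 1),
                        initialOccupancy = p0)
  for (sweep in tr) {
    expect_true(all(abs(sweep$occupancy[, 1] - 0.3) < 1e-12))
    expect_true(all(abs(sweep$occupancy[, 2] - 0.7) < 1e-12))
  }
})

test_that("two-state relaxation matches the closed form", {
  kOn <- 2; kOff <- 0.5
  sc <- twoStateScheme(kOn = kOn, kOff = kOff)
  proto <- VoltageProtocol(data.frame(voltage = NA_real_, duration = 5),
                           sweptSegment = 1L, sweepValues = -20,
                           sweepDimension = "voltage", sampleInterval = 0.05)
  tr <- propagateScheme(sc, proto, initialOccupancy = c(1, 0))
  t <- tr[[1]]$time
  pInf <- kOn / (kOn + kOff)
  tau <- 1 / (kOn + kOff)
  expect_equal(tr[[1]]$occupancy[, "O"], pInf * (1 - exp(-t / tau)),
               tolerance = 1e-9)
})

test_that("matrix-exponential propagation matches a fine-step integrator on
           the five-state chain under the recovery protocol", {
  sc <- defaultGatingScheme()
  proto <- recoveryProtocol(intervals = 2, prepulseMs = 100, testMs = 5,
                            sampleInterval = 0.05)
  tr <- propagateScheme(sc, proto)
  rk <- integrateSchemeRK4(sc, proto, sweepValue = 2, step = 1e-3)
  expect_equal(dim(tr[[1]]$occupancy), dim(rk$occupancy))
  expect_lt(max(abs(tr[[1]]$occupancy - rk$occupancy)), 1e-6)
})

test_that("occupancy is conserved through every propagation step", {
  sc <- defaultGatingScheme()
  tr <- propagateScheme(sc, ssiProtocol(
    conditioningVoltages = seq(-100, -20, by = 20), sampleInterval = 0.1))
  for (sweep in tr)
    expect_lt(max(abs(rowSums(sweep$occupancy) - 1)), 1e-9)
})

test_that("initial occupancy must be a probability vector", {
  sc <- twoStateScheme()
  proto <- ssiProtocol(conditioningVoltages = -40)
  expect_error(propagateScheme(sc, proto, initialOccupancy = c(0.5, 0.4)),
               "sum to 1")
})
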