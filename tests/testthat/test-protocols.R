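test_that("protocol constructors build valid objects with one swept segment", {
  p <- ssiProtocol()
  expect_s4_class(p, "VoltageProtocol")
  expect_identical(protocolKind(p), "ssi")
  expect_identical(p@sweepDimension, "voltage")
  expect_true(all(diff(p@sweepValues) > 0))

  r <- recoveryProtocol(prepulseMs = 1000)
  expect_identical(r@sweepDimension, "duration")
  expect_equal(r@segments$duration[1], 1000)

  a <- activationProtocol()
  expect_identical(a@sweptSegment, 1L)
  expect_equal(range(a@sweepValues), c(-100, 70))
})

test_that("protocol validity rejects malformed sweeps and segments", {
  expect_error(ssiProtocol(conditioningVoltages = c(-80, -80, -60)),
               "monotone")
  expect_error(ssiProtocol(conditioningVoltages = numeric()), "non-empty")
  expect_error(ssiProtocol(conditioningMs = -5), "positive")
  expect_error(recoveryProtocol(intervals = c(0, 1, 2)), "positive")
  expect_error(VoltageProtocol(data.frame(voltage = -20, duration = 10),
                               sweptSegment = 3L, sweepValues = 1:3,
                               sweepDimension = "duration"),
               "swept segment")
})

test_that("gating scheme validity enforces labels, rates and subsets", {
  sc <- twoStateScheme()
  expect_s4_class(sc, "GatingScheme")
  expect_error(GatingScheme(c("A", "A"), "A",
                            data.frame(from = "A", to = "A", amplitude = 1,
                                       vsens = 10, sign = 0)),
               "unique")
  expect_error(GatingScheme(c("A", "B"), "Z",
                            data.frame(from = "A", to = "B", amplitude = 1,
                                       vsens = 10, sign = 0)),
               "conductingState")
  expect_error(GatingScheme(c("A", "B"), "A",
                            data.frame(from = "A", to = "B", amplitude = -1,
                                       vsens = 10, sign = 0)),
               "non-negative")
  expect_error(GatingScheme(c("A", "B"), "A",
                            data.frame(from = "A", to = "B", amplitude = 1,
                                       vsens = 10, sign = 1),
                            slowStates = "B"),
               "subset")
})

test_that("rate matrix rows sum to zero and rates stay non-negative over the
           physiological voltage range", {
  sc <- defaultGatingScheme()
  for (V in seq(-140, 70, by = 30)) {
    Q <- rateMatrix(sc, V)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    offDiag <- Q[row(Q) != col(Q)]
    expect_true(all(offDiag >= 0))
  }
})

test_that("non-finite rates are rejected naming the transition", {
  sc <- GatingScheme(c("A", "B"), "A",
                     data.frame(from = "A", to = "B", amplitude = 1e308,
                                vsens = 10, sign = 1))
  expect_error(rateMatrix(sc, 70), "A->B")
})

test_that("stationary occupancy is a probability vector fixed by the dynamics", {
  sc <- defaultGatingScheme()
  p <- stationaryOccupancy(sc, -120)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_lt(max(abs(p %*% rateMatrix(sc, -120))), 1e-12)
})
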