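test_that("peak extraction returns the signed extremum after the blank
           window", {
  t <- seq(0, 10, by = 0.05)
  expect_equal(extractPeak(data.frame(time = t, current = 0)), 0)

  spike <- ifelse(abs(t - 1) < 0.025, -1.2, 0)
  expect_equal(extractPeak(data.frame(time = t, current = spike)), -1.2)

  ## activation-decay trace: peak located by an exhaustive scan
  cur <- -1.2 * (1 - exp(-t / 0.25)) * exp(-t / 1.5)
  keep <- t > 0.3
  oracle <- cur[keep][which.max(abs(cur[keep]))]
  expect_equal(extractPeak(data.frame(time = t, current = cur)), oracle)
})

test_that("peak extraction is invariant to order-preserving re-timing
           outside the blank window", {
  t <- seq(0, 10, by = 0.05)
  cur <- -1.2 * (1 - exp(-t / 0.25)) * exp(-t / 1.5)
  warped <- 0.3 + (t - 0.3)^1.3 / 9.7^0.3  # monotone warp fixing t = 0.3
  keep <- t > 0.3
  expect_equal(
    extractPeak(data.frame(time = warped[keep], current = cur[keep])),
    extractPeak(data.frame(time = t, current = cur)))
})

test_that("peak extraction errors name the sweep", {
  expect_error(extractPeak(data.frame(time = 0.1, current = 1),
                           blankMs = 0.3, sweepId = "sweep 7"),
               "sweep 7")
  expect_error(extractPeak(data.frame(time = c(1, 1), current = c(0, 0)),
                           sweepId = "sweep 9"),
               "sweep 9")
})

test_that("normalization follows the requested mode and rejects a zero
           reference", {
  s <- normalizeSeries(c(-2, -1), x = c(-120, -60), mode = "max")
  expect_equal(unname(peakMatrix(s)[1, ]), c(1, 0.5))

  s2 <- normalizeSeries(c(-3, -3, -3), x = c(-120, -90, -60), mode = "max")
  expect_equal(unname(peakMatrix(s2)[1, ]), c(1, 1, 1))

  expect_error(normalizeSeries(c(0, -1), x = c(-120, -60),
                               mode = "reference_x"), "zero")
})

test_that("normalization is scale invariant and preserves the generating
           availability shape", {
  v <- ssiGrid()
  shape <- 1 / (1 + exp((v - (-43.7)) / 10.1))
  peaks <- -1.2 * shape
  a <- normalizeSeries(peaks, v, mode = "reference_x")
  b <- normalizeSeries(peaks * 7.3, v, mode = "reference_x")
  expect_equal(peakMatrix(a), peakMatrix(b), tolerance = 1e-12)
  expect_equal(unname(peakMatrix(a)[1, ]), shape / shape[1],
               tolerance = 1e-12)
})
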