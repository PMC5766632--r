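test_that("zero-sigma noise replicates the input exactly", {
  ser <- genPhenoSeries(wtPheno(), "ssi", ssiGrid())
  out <- addNoise(ser, sigma = 0, nReplicates = 3, seed = 5)
  expect_identical(nReplicates(out), 3L)
  for (i in 1:3)
    expect_equal(peakMatrix(out)[i, ], seriesMeans(ser), tolerance = 0)
})

test_that("replicate scatter matches the requested sigma (law of large
           numbers at n = 1000)", {
  ser <- genPhenoSeries(wtPheno(), "ssi", ssiGrid())
  out <- addNoise(ser, sigma = 0.02, nReplicates = 1000, seed = 42)
  sds <- apply(peakMatrix(out), 2, sd)
  expect_lt(abs(mean(sds) - 0.02) / 0.02, 0.05)
  pooled <- sd(sweep(peakMatrix(out), 2, seriesMeans(ser)))
  expect_lt(abs(pooled - 0.02) / 0.02, 0.05)
})

test_that("replicate means converge to the noiseless series", {
  ser <- genPhenoSeries(wtPheno(), "ssi", ssiGrid())
  out <- addNoise(ser, sigma = 0.02, nReplicates = 1000, seed = 42)
  tol <- 3 * 0.02 / sqrt(1000)
  expect_true(all(abs(seriesMeans(out) - seriesMeans(ser)) < tol))
})

test_that("the noise stream is deterministic under a fixed seed and
           independent per construct", {
  ser <- genPhenoSeries(wtPheno(), "ssi", ssiGrid())
  a <- addNoise(ser, sigma = 0.02, nReplicates = 5, seed = 7)
  b <- addNoise(ser, sigma = 0.02, nReplicates = 5, seed = 7)
  expect_identical(peakMatrix(a), peakMatrix(b))
  c <- addNoise(ser, sigma = 0.02, nReplicates = 5, seed = 8)
  expect_false(identical(peakMatrix(a), peakMatrix(c)))
})

test_that("stable hashing gives reproducible 31-bit construct seeds", {
  expect_identical(stableHash("I1575C"), stableHash("I1575C"))
  expect_false(stableHash("I1575C") == stableHash("I1576C"))
  s <- constructSeed(1L, c("wt:ssi", "K1237E:ssi"))
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(s, constructSeed(1L, c("wt:ssi", "K1237E:ssi")))
})
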