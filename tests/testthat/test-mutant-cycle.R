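test_that("the inactivation free energy matches direct arithmetic for the
           printed wild-type parameters", {
  fe <- freeEnergy(v12 = -43.7, v12SE = 0.5, k = 10.1, kSE = 0.3,
                   temperature = 291.15)
  z <- rtfMillivolts(291.15) / 10.1
  expect_equal(deltaG(fe), z * 23.061 * (-43.7 / 1000), tolerance = 1e-12)
  expect_equal(deltaG(fe), -2.50, tolerance = 5e-3)
  expect_equal(standardError(fe), 0.080, tolerance = 5e-3)
})

test_that("free energy is linear in the valence and zero at a vanishing
           midpoint", {
  a <- freeEnergy(v12 = -40, k = 10, temperature = 291.15)
  b <- freeEnergy(v12 = -40, k = 5, temperature = 291.15)  # doubles z
  expect_equal(deltaG(b), 2 * deltaG(a), tolerance = 1e-12)

  z0 <- freeEnergy(v12 = 0, v12SE = 0.5, k = 10, kSE = 0.3,
                   temperature = 291.15)
  expect_identical(deltaG(z0), 0)
  expect_true("abs_se_fallback" %in% z0@flags)
  expect_gte(standardError(z0), 0)
})

test_that("free energies computed in millivolts rescale consistently with
           volts", {
  for (v in c(-80, -43.7, -12, 25)) {
    fe <- freeEnergy(v12 = v, k = 10.1, temperature = 291.15)
    zF <- (rtfMillivolts(291.15) / 10.1) * 23.061
    expect_equal(deltaG(fe), zF * (v / 1000), tolerance = 1e-12)
  }
})

.quartet <- function(tab) {
  fe <- function(id) {
    r <- tab[tab$constructId == id, ]
    freeEnergy(constructId = id, v12 = r$v12, v12SE = r$v12SE, k = r$slope,
               kSE = r$slopeSE, temperature = 291.15)
  }
  list(wt = fe("wt"), mut1 = fe("I1575C"), mut2 = fe("K1237E"),
       dbl = fe("K1237E/I1575C"))
}

test_that("the printed-parameter quartet gives a coupling energy far below
           the direct-coupling criterion", {
  q <- .quartet(constructScenario("oocyte-quartet"))
  res <- couplingEnergy(q$wt, q$mut1, q$mut2, q$dbl)
  ## independent arithmetic over the four free energies
  expected <- (deltaG(q$mut1) - deltaG(q$wt)) -
    (deltaG(q$dbl) - deltaG(q$mut2))
  expect_equal(deltaG(res), expected, tolerance = 1e-12)
  expect_equal(abs(deltaG(res)), 0.2113, tolerance = 1e-3)
  expect_false(isCoupled(res))
  ## conventional SE: quadrature of the two single-mutant SEs
  expect_equal(standardError(res),
               sqrt(standardError(q$mut1)^2 + standardError(q$mut2)^2),
               tolerance = 1e-12)
  full <- couplingEnergy(q$wt, q$mut1, q$mut2, q$dbl, seMode = "full")
  expect_gt(standardError(full), standardError(res))
})

test_that("coupling energy is invariant under mutant relabeling and zero
           for additive cycles", {
  q <- .quartet(constructScenario("oocyte-quartet"))
  ab <- couplingEnergy(q$wt, q$mut1, q$mut2, q$dbl)
  ba <- couplingEnergy(q$wt, q$mut2, q$mut1, q$dbl)
  expect_identical(deltaG(ab), deltaG(ba))

  wt <- freeEnergy(v12 = -43.7, k = 10.1, constructId = "wt")
  m1 <- freeEnergy(v12 = -50, k = 10.1, constructId = "m1")
  m2 <- freeEnergy(v12 = -48, k = 10.1, constructId = "m2")
  ## additive double: dG_dbl = dG_m1 + dG_m2 - dG_wt, with a shared slope
  vAdd <- -50 + -48 - -43.7
  dbl <- freeEnergy(v12 = vAdd, k = 10.1, constructId = "dbl")
  res <- couplingEnergy(wt, m1, m2, dbl)
  expect_lt(abs(deltaG(res)), 1e-12)
  expect_false(isCoupled(res))
})

test_that("coupling matches brute-force evaluation over random quartets", {
  set.seed(99)
  for (i in 1:100) {
    v <- runif(4, -90, -20); k <- runif(4, 6, 14)
    fes <- lapply(1:4, function(j)
      freeEnergy(v12 = v[j], k = k[j], constructId = paste0("c", j)))
    res <- couplingEnergy(fes[[1]], fes[[2]], fes[[3]], fes[[4]])
    rtf <- rtfMillivolts(291.15)
    g <- (rtf / k) * 23.061 * (v / 1000)
    expect_equal(deltaG(res), (g[2] - g[1]) - (g[4] - g[3]),
                 tolerance = 1e-12)
  }
})

test_that("temperature mismatches across the quartet are rejected", {
  wt <- freeEnergy(v12 = -43.7, k = 10.1, temperature = 291.15)
  m1 <- freeEnergy(v12 = -50, k = 10.1, temperature = 295.15)
  m2 <- freeEnergy(v12 = -48, k = 10.1, temperature = 291.15)
  dbl <- freeEnergy(v12 = -55, k = 10.1, temperature = 291.15)
  expect_error(couplingEnergy(wt, m1, m2, dbl), "temperature")
})

test_that("the cycle screen builds one result per complete quartet, skips
           missing doubles, and detects injected coupling", {
  ft <- tableFromScenario(constructScenario("oocyte-quartet"))
  res <- cycleScreen(ft, backgroundId = "K1237E", referenceId = "wt")
  expect_identical(nrow(res), 1L)
  expect_false(res$coupled[1])
  expect_identical(attr(res, "nCoupled"), 0L)

  ## a single mutant whose double never expressed is skipped with a reason
  ft2 <- rbind(ft, data.frame(constructId = "I1576C", v12 = -44, v12SE = 0.6,
                              slope = 10.4, slopeSE = 0.3, z = NA, zSE = NA,
                              residualRMS = 0, n = 6L, temperature = 291.15))
  res2 <- cycleScreen(ft2, backgroundId = "K1237E", referenceId = "wt")
  expect_identical(nrow(res2), 1L)
  expect_true("I1576C" %in% names(attr(res2, "skipped")))

  ## inject a strongly non-additive double mutant
  ft3 <- ft
  ft3$v12[ft3$constructId == "K1237E/I1575C"] <- -90
  res3 <- cycleScreen(ft3, backgroundId = "K1237E", referenceId = "wt")
  expect_true(res3$coupled[1])
  expect_gt(abs(res3$ddG[1]), 1)

  expect_error(cycleScreen(ft, backgroundId = "K1237E", referenceId = "zz"),
               "reference")
})
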