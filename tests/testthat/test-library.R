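test_that("a two-construct ssi library yields two series", {
  tab <- data.frame(constructId = c("wt", "mutA"), v12 = c(-43.7, -50),
                    slope = c(10.1, 10.5),
                    role = c("reference", "mutant"))
  lib <- makeConstructLibrary(tab, protocols = "ssi", sigma = 0,
                              nReplicates = 1)
  expect_length(lib, 2L)
  expect_s4_class(lib$wt$ssi, "PeakSeries")
  expect_s4_class(lib$mutA$ssi, "PeakSeries")
})

test_that("the noiseless default library reproduces the four printed
           midpoints through the fitting round trip", {
  lib <- defaultConstructLibrary(sigma = 0, nReplicates = 1)
  tab <- attr(lib, "params")
  for (id in names(lib)) {
    fit <- fitBoltzmann(lib[[id]]$ssi)
    expect_lt(abs(midpoint(fit) - tab$v12[tab$constructId == id]), 0.1)
  }
})

test_that("a construct sharing wild-type parameters produces a null shift", {
  tab <- data.frame(constructId = c("wt", "twin"), v12 = c(-43.7, -43.7),
                    slope = c(10.1, 10.1), role = c("reference", "mutant"),
                    n = c(7L, 7L), v12SE = c(0.5, 0.5),
                    slopeSE = c(0.3, 0.3))
  lib <- makeConstructLibrary(tab, sigma = 0, nReplicates = 1)
  fits <- lapply(lib, function(l) fitBoltzmann(l$ssi))
  st <- shiftTable(fitTable(fits, n = 7L), "wt")
  expect_lt(abs(st$shift[st$constructId == "twin"]), 1e-6)
})

test_that("library construction rejects duplicate ids and a missing
           reference", {
  tab <- data.frame(constructId = c("a", "a"), v12 = c(-40, -40),
                    slope = c(10, 10), role = c("reference", "mutant"))
  expect_error(makeConstructLibrary(tab), "duplicate")
  tab2 <- data.frame(constructId = c("a", "b"), v12 = c(-40, -40),
                     slope = c(10, 10), role = c("mutant", "mutant"))
  expect_error(makeConstructLibrary(tab2), "reference")
})

test_that("adding a construct never reshuffles existing constructs' data", {
  base <- constructScenario("oocyte-quartet")
  lib1 <- makeConstructLibrary(base, sigma = 0.02, nReplicates = 5, seed = 3)
  extra <- rbind(base, data.frame(constructId = "extraC", v12 = -48,
                                  v12SE = 0.5, slope = 10.2, slopeSE = 0.3,
                                  n = 6L, role = "mutant",
                                  temperature = 291.15))
  lib2 <- makeConstructLibrary(extra, sigma = 0.02, nReplicates = 5, seed = 3)
  expect_identical(peakMatrix(lib1$wt$ssi), peakMatrix(lib2$wt$ssi))
  expect_identical(peakMatrix(lib1$`K1237E/I1575C`$ssi),
                   peakMatrix(lib2$`K1237E/I1575C`$ssi))
})
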