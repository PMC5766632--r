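test_that("shift tables reproduce the printed hyperpolarizing shift and the
           degenerate self and equal-mean cases", {
  ft <- tableFromScenario(constructScenario("oocyte-quartet"))
  st <- shiftTable(ft, "wt")
  i1575 <- st[st$constructId == "I1575C", ]
  expect_equal(i1575$shift, -8.1, tolerance = 1e-12)
  expect_lt(i1575$p, 0.01)

  self <- st[st$constructId == "wt", ]
  expect_identical(self$shift, 0)
  expect_identical(self$t, 0)
  expect_identical(self$p, 1)

  twin <- rbind(ft, within(ft[1, ], constructId <- "twin"))
  st2 <- shiftTable(twin, "wt")
  expect_equal(st2$t[st2$constructId == "twin"], 0)
  expect_equal(st2$p[st2$constructId == "twin"], 1)
})

test_that("shifts are antisymmetric under swapping mutant and reference", {
  ft <- tableFromScenario(constructScenario("oocyte-quartet"))
  a <- shiftTable(ft, "wt")
  b <- shiftTable(ft, "I1575C")
  expect_equal(a$shift[a$constructId == "I1575C"],
               -b$shift[b$constructId == "wt"], tolerance = 1e-12)
})

test_that("a missing group size drops the p-value with a warning", {
  ft <- tableFromScenario(constructScenario("oocyte-quartet"))
  ft$n[2] <- NA_integer_
  expect_warning(st <- shiftTable(ft, "wt"), "omitted")
  expect_true(is.na(st$p[2]))
  expect_false(anyNA(st$shift))
})

.shiftsFrom <- function(ids, values, background = "wt") {
  data.frame(constructId = ids, shift = values, shiftSE = 0.5, t = NA,
             df = NA, p = NA, n = 6L, background = background)
}

test_that("Pearson correlation equals the direct covariance computation and
           is exact for collinear shifts", {
  set.seed(4)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10, sd = 0.4)
  a <- .shiftsFrom(paste0("m", 1:10), x)
  b <- .shiftsFrom(paste0("m", 1:10), y, background = "K1237E")
  res <- backgroundCorrelation(a, b)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res@r, direct, tolerance = 1e-12)
  expect_identical(res@nUsed, 10L)

  col <- backgroundCorrelation(a, .shiftsFrom(paste0("m", 1:10), 2 * x + 1,
                                              background = "K1237E"))
  expect_equal(col@r, 1, tolerance = 1e-12)
})

test_that("excluding an antagonistic outlier raises the correlation", {
  set.seed(8)
  x <- rnorm(12, sd = 6); y <- x + rnorm(12, sd = 1)
  x <- c(x, 20); y <- c(y, -20)
  ids <- c(paste0("m", 1:12), "pos1581")
  a <- .shiftsFrom(ids, x); b <- .shiftsFrom(ids, y, "K1237E")
  withOut <- backgroundCorrelation(a, b)
  without <- backgroundCorrelation(a, b, exclude = "pos1581")
  expect_gt(without@r, withOut@r)
  expect_identical(without@nUsed, 12L)
  expect_true("pos1581" %in% without@excluded)
  expect_error(backgroundCorrelation(a[1:3, ], b[1:3, ],
                                     exclude = c("m1", "m2")), "fewer than 3")
})

test_that("the synthetic screen recovers its target correlation through the
           full generate-fit-correlate pipeline", {
  tab <- screenScenario(nPositions = 14, targetR = 0.94, seed = 7)
  lib <- makeConstructLibrary(tab, sigma = 0.02, nReplicates = 7, seed = 7)
  fits <- lapply(lib, function(l) fitBoltzmann(l$ssi))
  ft <- fitTable(fits, n = tab$n[match(names(fits), tab$constructId)])
  stWt <- shiftTable(ft, "wt")
  bgRows <- ft[grepl("/", ft$constructId) | ft$constructId == "K1237E", ]
  bgRows$constructId <- stripBackground(bgRows$constructId, "K1237E")
  stBg <- shiftTable(bgRows, "K1237E", background = "K1237E")
  res <- backgroundCorrelation(stWt, stBg)
  expect_lt(abs(res@r - 0.94), 0.05)
  expect_lt(res@p, 1e-4)
})

test_that("leave-one-out flags exactly the antagonistic point and are
           invariant under axis swap", {
  x <- seq(-12, 12, length.out = 9); y <- x
  ids <- paste0("m", seq_along(x))
  clean <- flagOutliers(.shiftsFrom(ids, x), .shiftsFrom(ids, y, "K1237E"))
  expect_false(any(clean$flagged))

  x2 <- c(x, 20); y2 <- c(y, -20); ids2 <- c(ids, "pos1581")
  a <- .shiftsFrom(ids2, x2); b <- .shiftsFrom(ids2, y2, "K1237E")
  fl <- flagOutliers(a, b)
  expect_identical(fl$constructId[fl$flagged], "pos1581")
  swapped <- flagOutliers(b, a)
  expect_identical(fl$flagged, swapped$flagged)
})

test_that("activation-inactivation shift correlation handles identity and
           degenerate axes", {
  ids <- paste0("m", 1:6)
  v <- c(-3, 5, 1, -7, 2, 9)
  same <- pairedShiftCorrelation(.shiftsFrom(ids, v), .shiftsFrom(ids, v))
  expect_equal(same@r, 1, tolerance = 1e-12)
  expect_error(
    pairedShiftCorrelation(.shiftsFrom(ids, v), .shiftsFrom(ids, rep(1, 6))),
    "activation")
})
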