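## Small schemes and series used across tests.

## Two-state C <-> O scheme with voltage-independent rates.
twoStateScheme <- function(kOn = 2, kOff = 1, conductance = 1) {
  GatingScheme(
    stateLabels = c("C", "O"), conductingState = "O",
    rates = data.frame(from = c("C", "O"), to = c("O", "C"),
                       amplitude = c(kOn, kOff), vsens = c(20, 20),
                       sign = c(0, 0)),
    conductance = conductance, reversalPotential = 60)
}

## Two-state scheme with fast voltage-dependent activation and no
## inactivated state.
noInactScheme <- function() {
  GatingScheme(
    stateLabels = c("C", "O"), conductingState = "O",
    rates = data.frame(from = c("C", "O"), to = c("O", "C"),
                       amplitude = c(200, 200 * exp(-60 / 10)),
                       vsens = c(20, 20), sign = c(1, -1)),
    conductance = 1, reversalPotential = 60)
}

## Frozen wild-type phenomenological parameters (oocyte scenario).
wtPheno <- function() {
  PhenoParams("wt", inactV12 = -43.7, inactSlope = 10.1,
              recovery = list(
                p100ms = data.frame(amplitude = c(0.50, 0.25, 0.25),
                                    tau = c(0.8, 231.8, 1667.8)),
                p1s = data.frame(amplitude = c(0.70, 0.30),
                                 tau = c(486.5, 2588.1))),
              actV12 = -25, actSlope = 7, actReversal = 60)
}

## Default fine grids.
ssiGrid <- function() seq(-120, -10, by = 5)
recGrid100 <- function() 10^seq(log10(0.1), 4, length.out = 36)
recGrid1s <- function() 10^seq(0, log10(3e4), length.out = 30)

## Quick fit table straight from a printed-style parameter table.
tableFromScenario <- function(tab) {
  data.frame(constructId = tab$constructId, v12 = tab$v12,
             v12SE = tab$v12SE, slope = tab$slope, slopeSE = tab$slopeSE,
             z = rtfMillivolts(tab$temperature) / tab$slope,
             zSE = rtfMillivolts(tab$temperature) / tab$slope *
               tab$slopeSE / tab$slope,
             residualRMS = 0, n = tab$n, temperature = tab$temperature)
}
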