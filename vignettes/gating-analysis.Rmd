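---
title: "Models and methods: Nav-channel gating analysis with navgating"
author: "navgating authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Nav-channel gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navgating)
```

# Scope

`navgating` implements the analysis chain used in mutational screens of
voltage-gated sodium-channel fast inactivation: generation of normalized
peak-current series under the three standard voltage-clamp protocols,
least-squares fitting of the Boltzmann / multi-exponential /
conductance-voltage gating models, conversion of Boltzmann parameters into
inactivation free energies, double-mutant-cycle coupling energies with
analytic error propagation, and screen-level summaries (midpoint-shift
tables with Student's t-tests, background-sensitivity correlations with
advisory outlier flagging, and the activation-versus-inactivation
independence check). Because raw recordings behind published screens are
generally unavailable, the synthetic-data tier is first-class, tested code,
not a fixture: all statistical properties demonstrated by the test suite
are properties of the estimators under this generator's assumptions, which
this vignette makes explicit.

# Protocols

A `VoltageProtocol` is a piecewise-constant pulse train with exactly one
swept segment. The shipped constructors encode the conventional designs:

- `ssiProtocol()`: 50 ms conditioning pulses to varying potentials
  (default -100..-10 mV) followed by a 10 ms test pulse to -20 mV, holding
  -120 mV. Fifty milliseconds is long enough to equilibrate fast
  inactivation while leaving slow inactivated states essentially empty.
- `recoveryProtocol()`: a 100 ms (or 1 s) prepulse to -20 mV, a swept
  recovery interval at the holding potential, then the test pulse. The
  100 ms prepulse loads mostly fast-inactivated channels (recovery with up
  to three time constants); a 1 s prepulse loads slow states (two).
- `activationProtocol()`: 20 ms steps from -100 to +70 mV, holding
  -140 mV; here the swept step is itself the test pulse.

The cell is assumed stationary at the holding potential before each sweep.

# The Markov tier

`GatingScheme` is a master-equation model `dp/dt = p Q(V)` whose rates have
the exponential form `r(V) = a * exp(s * V / v)` with `s` in {-1, 0, 1}.
Because protocols are piecewise constant, each segment is propagated
*exactly* by the matrix exponential of its rate generator
(`propagateScheme()`); no integrator tolerance enters the simulated data.
The independent cross-check, `integrateSchemeRK4()`, is a classical
fourth-order Runge-Kutta integrator at a 1e-3 ms step; the two agree to
about 4e-8 on the default scheme, and occupancy is conserved to 1e-9 at
every sample (both are asserted in the test suite).

## The default five-state scheme

`defaultGatingScheme(midpoint, slope)` builds the linear chain
C1 - C2 - O - If - Is: two closed states, the open state, a fast and a slow
inactivated state — the minimal topology that yields a Boltzmann-like
availability curve together with multi-exponential recovery. Two design
choices deserve explanation:

1. **Activation is deliberately fast and strongly hyperpolarized**
   (half-activation near -90 mV, sub-0.1 ms gating at the test potential).
   This is not a model of physiological Nav activation; it ensures that at
   every conditioning voltage the closed-open equilibrium is complete and
   fast, so the quantity read out by the test pulse is the fast-inactivation
   availability alone. The peak detected just after the 0.3 ms blank window
   is then proportional to availability regardless of the sweep's history,
   which is exactly the proportionality the analysis assumes of real
   recordings. (With slower activation, channels conduct during conditioning
   and re-open from inactivated states during the test pulse, and the
   simulated series is no longer a clean Boltzmann — the fitted slope
   inflates by ~20%.)
2. **The O-If rates carry the designed voltage dependence.** Writing the
   onset rate `a_OI exp(V / s_OI)` and the recovery rate
   `b_IO exp(-V / s_IO)`, the equilibrium availability is a Boltzmann with
   slope factor `1/(1/s_OI + 1/s_IO)` and midpoint
   `ln(b/a) / (1/s_OI + 1/s_IO)`. The constructor solves these two
   equations for the requested `(midpoint, slope)` with `s_IO = 30` mV
   fixed; the remaining amplitudes set the recovery time constant at the
   holding potential (~2 ms) and the slow If-Is exchange (~100 ms at
   -120 mV).

`designedMidpoint()` returns the closed-form half-availability voltage of
the fast subsystem (slow states removed) by root bracketing on the
stationary distribution — an analytic design quantity, independent of the
simulation path. For the default scheme it is -43.68 mV; the full
simulate-and-fit round trip lands within 0.7 mV of it, the residual
reflecting finite 50 ms equilibration and the small closed-state occupancy
at the hyperpolarized foot of the curve.

The peak-detection blank window (0.3 ms, configurable) mimics capacitive
transient blanking. Simulated series are normalized to their
largest-magnitude peak, sign preserved, so inward currents give positive
availability.

# The phenomenological tier

`genPhenoSeries()` inverts the fitted forms directly from `PhenoParams`:

- SSI: `y = 1 / (1 + exp((V - V1/2) / k))` (decreasing, availability ~1 at
  hyperpolarized conditioning voltages);
- recovery: `y = 1 - sum_i A_i exp(-t / tau_i)`, the availability-positive
  equivalent of the inward-current convention
  `y = -sum_i A_i (1 - exp(-t/tau_i)) + C`, with identical parameters;
- activation: `I = (V - Vrev)(1 - 1/(1 + exp((V - Va1/2)/K)))` at unit
  maximum conductance.

Noiseless generate-fit round trips through this tier recover the
generating parameters to better than 1e-6 relative error for all three
forms; this is the package's primary correctness oracle for the fitting
code.

## Noise model and seeding

`addNoise()` adds independent Gaussian noise per replicate and point on
the normalized currents. Published screens report only means and standard
errors, so additive homoscedastic noise is the least-structured model
consistent with them; the default `sigma = 0.02` (normalized units) with
7 replicates reproduces mid-curve SEM magnitudes around 0.008, in line
with reported group statistics. What the generator deliberately does *not*
emulate: voltage-error and series-resistance artefacts, leak subtraction
residuals, run-down or time-dependent shifts within a recording session,
and replicate-to-replicate midpoint heterogeneity (noise is around a fixed
true curve). Passing tests therefore demonstrate estimator correctness and
calibration under these idealized conditions, not robustness to every
artefact of real recordings.

Randomness is controlled by one master seed; each construct and protocol
draws from a stream seeded by a stable polynomial hash of
`"<constructId>:<protocol>"` plus the master seed (`constructSeed()`), so
extending a library never reshuffles existing constructs' data.

## Shipped scenarios

`constructScenario()` provides three parameter sets mimicking published
values: the oocyte quartet (wild type -43.7/10.1 mV, I1575C -51.8/11.5,
K1237E -51.1/10.8, K1237E/I1575C -59.6/11.3, at 291.15 K — the 18 °C
oocyte bath), the mammalian isoform pair (wild type -66.2, I1581V -53.8,
holding -140 mV), and the oocyte pH series for the engineered histidine.
The oocyte and mammalian wild-type midpoints differ by >20 mV because the
recording conditions differ; the scenarios are kept separate and never
reconciled. Slope factors are not published for the mammalian and pH
scenarios; a representative 7.0 mV patch-clamp slope (respectively the
10.1 mV oocyte default) is used — midpoint shifts, the only quantity those
scenarios feed, do not depend on it. `recoveryScenario()` carries the
published two- and three-exponential component tables for wild type and
K1237E. `screenScenario()` builds a synthetic cysteine-scanning screen
whose paired-background shifts have an *exactly* imposed empirical
correlation (orthogonalize-and-mix construction), defaulting to R = 0.94
over 14 positions, with an optional antagonistic outlier position.

# Curve fitting

All fits are unweighted bounded Levenberg-Marquardt (`minpack.lm::nlsLM`)
on per-point replicate means (published analyses state no weighting
scheme), with up to 20 jittered restarts under a fixed restart seed and a
relative parameter tolerance of 1e-10. Slope factors are bounded to
(0.1, 100] mV and time constants to [1e-3, 1e6] ms; estimates pinned at a
bound are flagged rather than silently returned.

- `fitBoltzmann()` parameterizes by `(V1/2, k)` — the scale on which
  results are reported — and derives the valence `z = RT/(F k)` with a
  delta-method SE, so `z k = RT/F` holds identically. The temperature is a
  required input (the series carries its own): the same mV slope factor
  implies a different valence at a different temperature. Degenerate
  series (fewer than 5 voltages, or spanning less than 0.2 of the
  transition) are rejected as non-identifiable.
- `fitRecovery()` initializes time constants log-spaced across the sampled
  interval range. Component identity is fixed by ascending-tau sort with
  larger amplitude first on ties; adjacent time constants within a factor
  of 3 are flagged `tau_degenerate`, collapsed amplitudes
  `amplitude_collapsed`. Three-component fits require intervals spanning
  at least three decades.
- `fitActivation()` flags a reversal potential estimated outside the
  sampled voltages (`vrev_extrapolated`).
- `chooseRecoveryOrder()` defaults to the convention (three components
  after a 100 ms prepulse, two after 1 s); `auto = TRUE` selects by an
  extra-sum-of-squares F-test at alpha = 0.05.

Estimator calibration, asserted by the test suite at the study
conditions: over 200 seeded replicates of the wild-type SSI scenario
(sigma 0.02, n = 7) the mean fitted midpoint is within 0.3 mV of truth;
over 200 seeded replicates of each recovery scenario (sigma 0.01, n = 6)
the mean amplitudes and time constants lie within +-0.05 and +-20% of
truth and at least 95% of individual replicates fall inside those bands
(the 1 s two-exponential scenario places ~2% of draws just outside —
a sampling property of the slowest component, not an estimator bias).

# Energetics

`freeEnergy()` computes `dG = z F V1/2` in kcal/mol
(F = 23.061 kcal mol^-1 V^-1, V1/2 in volts) with the relative-error
propagation `SE = |dG| sqrt((SE_z/z)^2 + (SE_V12/V12)^2)`; the magnitude
is taken so SEs are non-negative, and the degenerate `V1/2 = 0` case falls
back to absolute propagation with a flag. `couplingEnergy()` evaluates the
cycle and classifies `|ddG| > 1` kcal/mol (threshold configurable). The
conventional SE — quadrature of the two single-mutant SEs — is the
default; because the convention's subscripts are ambiguous about whether
the wild type and double mutant contribute, `seMode = "full"` exposes the
four-term quadrature as a documented variant, asserting neither reading as
canonical. `cycleScreen()` walks a fit table, pairing each single mutant
with its background-combined double (skipping, with a logged reason,
mutants whose double never expressed).

Exact properties asserted in the tests: additive cycles give ddG = 0 to
1e-12; relabeling the two mutants leaves ddG unchanged; mV/V rescaling is
consistent; 100 random quartets match direct evaluation of the defining
expression to 1e-12.

# Screen statistics

`shiftTable()` uses the pooled-variance Student's t-test (not Welch),
matching the conventional analysis, with group SDs reconstructed as
`SE * sqrt(n)` when only summary statistics are available.
`backgroundCorrelation()` and `pairedShiftCorrelation()` report Pearson R
with the two-tailed test; degenerate (constant) axes are an error naming
the axis. Outlier handling is advisory by design: `flagOutliers()`
jackknifes the correlation and flags points whose removal raises R by more
than 0.15 (configurable), but exclusions are only ever applied through an
explicit list, because published exclusions are typically by inspection
and reproducibility demands they be stated, not rediscovered. P-values are
unadjusted (the conventional analysis applies no multiple-testing
correction); the type-I rate of the correlation test under the null is
asserted to sit in [0.03, 0.07] over 1000 seeded trials.

# Pipeline and problem sizes

`runPipeline()` chains simulate -> fit -> shifts -> cycles -> correlation
deterministically under the master seed, validating its configuration
eagerly (all problems reported in one error) and continuing past
per-construct fit failures. `writeReport()` serializes every table as TSV
and/or JSON at 6 significant digits with stable column order.

Default problem sizes were chosen as the smallest that make the targeted
properties sharp: 23-point SSI grids, 36-point (100 ms class) and 30-point
(1 s class) log-spaced recovery grids, 7 (SSI) / 6 (recovery) replicates,
200-replicate calibration studies and 1000-trial null simulations; the
mechanistic cross-checks use one sweep of the recovery protocol at a
0.05 ms sample interval against the 1e-3 ms RK4 reference.

# Known limitations

- The Markov tier is a calibrated generator, not an estimator: the package
  fits the closed-form gating models only, never rate constants of the
  scheme.
- The noise model omits the structured artefacts listed above; calibration
  results transfer to real data only insofar as those artefacts are small
  after standard preprocessing.
- The five-state chain yields at most four relaxation modes; recovery
  "three time constants" holds in the phenomenological tier exactly and in
  the Markov tier as a two-to-three-mode approximation (the shipped
  scheme's slow modes are close; the three-exponential fit residual is
  below 1e-3 and the test asserts exactly that).
- Analytic (delta-method) error propagation only; no resampling-based
  uncertainty for coupling energies.
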