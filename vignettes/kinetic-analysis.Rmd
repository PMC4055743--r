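---
title: "Pre-steady-state kinetic analysis of stopped-flow fluorescence traces"
author: "sfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-steady-state kinetic analysis of stopped-flow fluorescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfkin)
```

## The problem this package addresses

Endonuclease VIII (Nei) is an *E. coli* DNA-repair glycosylase/AP-lyase
that recognises oxidised pyrimidines such as 5,6-dihydrouracil (DHU),
excises the damaged base and nicks the strand. Recognition is not a single
binding event: the enzyme and the DNA pass through a cascade of mutual
conformational adjustments — initial encounter, DNA bending and eversion of
the damaged base, insertion of an amino-acid triad into the resulting void,
fine-tuning of the active site — before the chemistry happens and the
product is released. Stopped-flow fluorescence is the standard way to watch
this cascade: two syringes mix enzyme and labelled duplex in about a
millisecond, and one or more emission channels are recorded from the
instrument dead time (1.4 ms here) out to ~1000 s.

`sfkin` implements the full analysis chain for such experiments:

1. **Mechanism schemes** as explicit mass-action reaction lists
   (`kineticScheme()`).
2. **Deterministic integration** of the resulting stiff ODE systems and
   analysis of intermediate time courses (`integrateScheme()`,
   `timeOfMax()`).
3. **A linear observation model** mapping species concentrations to channel
   intensities, including the two-channel ratiometric statistic of the
   ESIPT probe 3-hydroxychromone (3HC) (`projectObservable()`,
   `intensityRatio()`).
4. **A synthetic stopped-flow instrument** so the whole chain is testable
   without real traces (`generateTraceSet()`).
5. **Global nonlinear least squares** across a concentration series, with
   multi-start safeguards, asymptotic uncertainties, and AIC/F-test model
   selection (`fitGlobal()`, `compareModels()`).

## The kinetic model

The five-state mechanism (`"nei5"`) used for the intrinsic tryptophan
channel and for the 3HC-labelled substrate is

$$
E + S
\underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} (E{\cdot}S)_1
\underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} (E{\cdot}S)_2
\underset{k_{-3}}{\overset{k_3}{\rightleftharpoons}} (E{\cdot}S)_3
\xrightarrow{k_{cat}} E{\cdot}P
\underset{}{\overset{K_P}{\rightleftharpoons}} E + P
$$

Three reversible binding/isomerisation equilibria are followed by one
irreversible catalytic step and a product-release equilibrium. $k_{cat}$
deliberately lumps the chemical sub-steps (N-glycosidic cleavage, β- and
δ-elimination) into a single rate: the fluorescence channels cannot
separate them, so giving them individual rates would only manufacture
unidentifiable parameters. Single-band DNA probes that cannot resolve the
third conformational transition are described by the reduced two-equilibria
variant (`"nei4"`, no $(E{\cdot}S)_3$).

Species are named `E, S, ES1, ES2, ES3, EP, P`. Both built-in schemes carry
two exact conservation laws — total enzyme and total DNA — which the
package verifies by integer arithmetic on the stoichiometry matrix and
monitors (to 1e-6 relative) along every integration.

**Product release.** Only the dissociation equilibrium constant $K_P$ of
$E{\cdot}P$ is treated as identifiable. The reversible pair is realised
with a dissociation rate `koff` (default 10 s⁻¹, configurable) and
association rate `koff / KP`. The default is fast relative to $k_{cat}$
(0.01–0.06 s⁻¹ in the shipped presets), so binding-phase observables are
insensitive to the particular `koff` chosen; `koff` is always held fixed in
fits.

**Scheme files.** Schemes serialise to a human-diffable one-reaction-per-line
dialect (`"E + S <-> ES1 : k1/k_1"`, `"ES3 -> EP : kcat"`) plus directives
that pin species order, the `kon = koff/KP` realisation, defaults and
conservation groups, so `readScheme(writeScheme(s))` is identical to `s`.

## Rate-constant presets

`neiRateConstants(label)` ships the published pre-steady-state constants
for Nei processing DHU-containing duplexes, one column per reporter:
`"Trp"` (intrinsic enzyme fluorescence) and `"3HC"` bind to `"nei5"`;
`"tCO"` and `"Cpy"` to `"nei4"`. `"aPu"` is rejected with an explanatory
error — 2-aminopurine showed no exploitable signal change, so no constants
were ever fitted for it. Units are M⁻¹s⁻¹ for the bimolecular association
`k1`, s⁻¹ for all unimolecular steps, and M for `KP`; `validateParams()`
checks positivity, completeness (strict by default, to catch configuration
typos) and — when units are declared — their consistency with reaction
order.

## The observation model

Stopped-flow channels report a background plus a linear combination of
species concentrations,

$$I_c(t) = b_c + \sum_s \beta_{c,s}\,[s](t),$$

with coefficients attaching to every species that contains the emitting
moiety: enzyme-containing species for tryptophan, DNA-containing species
for the base surrogates. This is the standard observation model for
stopped-flow transients; the coefficients are free parameters estimated
together with the rate constants.

The 3HC probe emits two resolvable bands (the ESIPT normal form N\* and
tautomer T\*). The instrument records the **total** N\*+T\* emission behind
a 395 nm long-pass filter and the **T\* band alone** behind a 495 nm
long-pass filter, so the band ratio at each time point is

$$\frac{I_{N^*}}{I_{T^*}} \;=\; \frac{I_{(N^*+T^*)} - I_{T^*}}{I_{T^*}}.$$

Given those channel definitions this identity is the only possible reading,
and it is what `intensityRatio()` computes, on background-subtracted
intensities whenever a channel declares a background. A non-positive T\*
intensity is a hard error naming the offending time point. The ratio is
attractive precisely because common multiplicative factors (lamp drift,
quenching, instrument gain) cancel; the package's `constantRatioModel()`
builds a dual-channel observation model with a constant encoded ratio,
which must survive a generate → ratio round trip exactly — one of the
package's acceptance checks.

## The synthetic instrument

`generateTraceSet()` emulates the experiment for each mixing condition and
channel: integrate, project, truncate to $t \ge$ dead time (1.4 ms),
overlay independent Gaussian noise per replicate, average the replicates.
Defaults mirror the study conditions: a 1–3 µM enzyme series against 1 µM
DNA, four replicates, logarithmic acquisition at 1000 samples per decade
capped at 5000 points per trace, and an active-enzyme fraction of 0.8
applied to nominal enzyme concentrations before integration (reported
concentrations stay nominal; both are recorded in the trace metadata).
Temperature and buffer are metadata only — kinetics enter solely through
the rate constants.

Two generator parameters have no published values and are declared choices:

* **Noise amplitude**: additive i.i.d. Gaussian with SD equal to 2% of each
  trace's noiseless dynamic range. This reproduces the visual jaggedness of
  real stopped-flow traces without asserting a photon-count model the data
  do not constrain.
* **Ground-truth emission coefficients** in the presets: order-1 a.u.
  signals at micromolar concentrations with distinct per-complex responses,
  so that every binding step is visible in the synthetic signal.

What the generator does *not* emulate: shot-noise scaling with intensity,
lamp drift, photobleaching, inner-filter effects, mixing artefacts inside
the dead time, and correlated noise. Passing recovery tests on synthetic
data therefore demonstrate that the estimator is correct and well
conditioned under the declared noise model — not that every real trace of
this kind will constrain all eight parameters equally well.

## Global fitting

`fitGlobal()` minimises the summed squared residuals over all traces
simultaneously: rate constants are shared across mixing conditions,
emission coefficients and backgrounds are shared per channel, and samples
earlier than the dead time are excluded. Residuals are weighted by
1/σ per trace when replicate scatter is recorded (the generator stores it),
or uniformly otherwise. Kinetic parameters are optimised in log₁₀ space —
the constants span more than eight decades — inside unit-appropriate bounds
(10²–10¹⁰ M⁻¹s⁻¹ bimolecular, 10⁻⁴–10⁶ s⁻¹ unimolecular, 10⁻¹²–10⁻² M for
$K_P$).

Three implementation choices matter for reliability, all adopted after
observing the failure modes they prevent:

* **Variable projection with a joint polish.** For fixed kinetics the
  observation parameters enter linearly, so they are solved exactly by
  weighted least squares inside the kinetic residual; Levenberg–Marquardt
  then runs on the reduced, far better-conditioned kinetic problem. From
  that optimum a final LM pass over *all* parameters jointly produces the
  reported estimates, residuals and covariance, so uncertainties reflect
  the full joint problem. The linear solve uses a column-scaled,
  rank-revealing QR: when a channel observes every member of a conserved
  moiety and the conserved total is identical across conditions, the
  intercept and the group coefficients are exactly collinear, and the
  aliased direction is fixed at zero (prediction-equivalent, minimum-norm).
* **Finite-difference steps above the solver noise floor.** Numeric
  Jacobians through an adaptive ODE solver are meaningless if the
  difference step is comparable to the integration tolerance; the LM step
  (`epsfcn`) is set so parameter perturbations are ~10⁻⁴ relative, orders
  of magnitude above the 10⁻⁸ relative solver error.
* **Multi-start and basin hops.** Sequential-relaxation mechanisms have
  near-degenerate "rate-assignment twin" optima. Each launch therefore
  follows LM with a few greedy basin hops (jitter the kinetic
  log-parameters by ±0.5 decades, keep improvements), and `n_starts`
  (default 16) launches run from a seeded Latin-hypercube within ±2 decades
  of the supplied start, the first launch starting at the guess itself.
  Per-launch RSS values are reported (`starts_rss`) so stranded launches
  are visible. The practical robustness statement validated in the tests is
  about whole fits: independent `fitGlobal()` invocations from different
  perturbed guesses agree on the optimum RSS to within 1% in at least 8 of
  10 runs. Individual launches from the full ±2-decade box frequently end
  in twin optima a few tenths of a percent to tens of percent above the
  best — that is a property of these objective surfaces, not something more
  iterations repair, which is why the multi-start table is part of the
  result object.

Uncertainties are asymptotic standard errors from the Jacobian at the joint
optimum, delta-transformed to natural scale ($\mathrm{se}(k) = \ln 10 \cdot
k \cdot \mathrm{se}(\log_{10} k)$); a singular Jacobian flags them
unavailable rather than failing the fit. The reduced chi-square is reported
whenever per-trace noise SDs are known; under a correctly specified model
on generator output it sits in [0.8, 1.2].

## Model comparison

`compareModels()` fits each candidate scheme and ranks them by
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2p$; nested pairs additionally get
the extra-sum-of-squares F statistic. With thousands of points the AIC race
is decided by RSS differences of a few tenths of a percent, so fairness is
entirely an optimisation question. Models are therefore fitted smallest
first, and every larger scheme is additionally warm-started from the best
nested reduced optimum with its extra steps switched off (extra forward
rates at the lower bound, reverse partners at 1 s⁻¹); the better of the
configured and warm starts is kept. The warm embedding cannot be exact —
the catalytic step changes its substrate species between the two built-in
schemes — but it reliably prevents the reduced model from winning or losing
by optimiser luck: on reduced-scheme synthetic data the reduced scheme is
preferred, and on five-state data with a distinct third-step amplitude the
five-state scheme wins decisively. No multiple-testing correction is
applied; raw AIC and F values are reported.

## Numerical choices

* Integration: `deSolve::lsoda` on a compiled mass-action right-hand side,
  rtol 10⁻⁸, atol 10⁻¹² M. Reporting grids are logarithmic (default 500
  points from 1.4 ms to 1000 s) with $t=0$ always integrated; undershoot
  below −10⁻¹² M is an error in reported runs (a looser floor is used
  inside fitting, where wild parameter excursions are expected and
  penalised rather than fatal), and smaller undershoot is clipped to zero.
* `timeOfMax()` refines the discrete argmax by a three-point quadratic in
  time; ties resolve to the earliest point; maxima on the final grid point
  are flagged as boundary maxima (monotone accumulation, e.g. free
  product) and not interpolated.
* Integration failures during fitting return a large finite residual
  penalty so LM backs off instead of aborting a launch.

## Problem sizes used by the shipped tests

Unit and property tests run on reduced designs (two conditions, 150
acquisition samples per decade) chosen so the full suite exercises every
code path at desk scale; the parameter-recovery check uses the full default
design (three enzyme concentrations, 1000 samples per decade capped at
5000, 2% noise, four replicates, ten seeds) with perturbed starts within
±0.3 decades of truth and two launches per fit. These sizes are the
package's own testing choices and are restated here so a reader can
reproduce them outside the test runner.

## Known limitations

* $K_P$ and the late-phase coefficients are only weakly identified by
  single-channel data when the product-release plateau is subtle; the
  bounds-hit flags and standard errors make this visible per fit.
* The estimator assumes additive Gaussian noise with per-trace scale; real
  photon noise is intensity-dependent.
* The warm-start embedding for nested comparisons is approximate (see
  above); comparison verdicts are robust to this, but the larger model's
  reported RSS on reduced-truth data can sit visibly above the reduced
  model's when its own launches strand.
* Recovery tolerances (25% per constant) are not tied to the published ±
  values, whose estimation method (standard errors versus confidence
  half-widths) is not stated with the constants themselves.
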