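# sfkin — pre-steady-state kinetics of stopped-flow fluorescence traces

`sfkin` is an R package for the transient-phase kinetic analysis of
DNA-repair enzymes watched by stopped-flow fluorescence, built around the
mechanism of Endonuclease VIII (Nei) excising 5,6-dihydrouracil (DHU) from
labelled DNA duplexes. It is aimed at enzymologists who need to turn raw
multi-channel stopped-flow traces into elementary rate constants and to
decide how many kinetic intermediates their data actually support.

## The model

The central object is the five-state mass-action mechanism

```
E + S <-> ES1 <-> ES2 <-> ES3 -> EP <-> E + P
      k1/k_1  k2/k_2  k3/k_3  kcat    KP
```

three sequential binding/isomerisation equilibria (encounter complex, DNA
bending and base eversion, active-site adjustment), one irreversible lumped
catalytic step `kcat`, and a product-release equilibrium parameterised by
its dissociation constant `KP` (realised as a fast reversible pair
`koff`/`koff/KP`). A reduced two-equilibria variant (`"nei4"`) describes
single-band DNA probes that cannot resolve the third transition. Observed
intensity per channel is a background plus a linear combination of species
concentrations; for the dual-band ESIPT probe 3-hydroxychromone the
N\*/T\* band ratio is computed as
`(I_total − I_Tstar) / I_Tstar` from the 395 nm and 495 nm long-pass
channels.

The package provides: declarative kinetic schemes with exact conservation
checking and a plain-text file dialect; stiff ODE integration on a compiled
mass-action core; species-curve analysis (interpolated times of maximum,
half-rise times); a synthetic stopped-flow instrument (1.4 ms dead time,
log-time acquisition, replicate averaging, fractional-range noise, 80%
active-enzyme fraction); global multi-start nonlinear least squares with
variable projection, asymptotic standard errors and AIC/F-test model
comparison; and the published Nei rate-constant presets for the Trp, 3HC,
tCO and Cpy reporter channels.

## Worked example

Integrate the five-state scheme with the published Trp-channel constants at
2 µM enzyme and 2 µM substrate, and ask when the second intermediate peaks:

```r
library(sfkin)

sc <- kineticScheme("nei5")
sc
#> Kinetic scheme 'nei5': 7 species, 9 elementary reactions
#>   species: E, S, ES1, ES2, ES3, EP, P
#>   E + S <-> ES1 : k1/k_1
#>   ES1 <-> ES2 : k2/k_2
#>   ES2 <-> ES3 : k3/k_3
#>   EP <-> E + P : koff/kon
#>   ES3 -> EP : kcat
#>   derived: kon = koff/KP
#>   conserved total: E + ES1 + ES2 + ES3 + EP
#>   conserved total: S + ES1 + ES2 + ES3 + EP + P

tc <- integrateScheme(sc, neiRateConstants("Trp"), initialConditions(2e-6, 2e-6))
m <- timeOfMax(tc, "ES2")
sprintf("ES2 maximum: %.3g M at %.3f s", m$value, m$time)
#> "ES2 maximum: 1.19e-06 M at 0.628 s"
sprintf("ES1 half-rise: %.1f ms", 1e3 * timeToFraction(tc, "ES1", 0.5))
#> "ES1 half-rise: 11.3 ms"
```

The second enzyme–substrate complex peaks at ≈0.6 s and the first complex
forms within the first tens of milliseconds — the hallmark ordering of the
Nei conformational cascade. Cross-fluorophore ratios of the published
constants quantify how much faster the DNA reports the initial binding
than the protein does, and how the catalytic rate drops when the probe
replaces the estranged base:

```r
derivedQuantities(list(Trp = neiRateConstants("Trp"),
                       `3HC` = neiRateConstants("3HC")))
#>                 ratio constant numerator denominator    value
#> 1     k1(3HC)/k1(Trp)       k1       3HC         Trp 5.047619
#> 2     k2(Trp)/k2(3HC)       k2       Trp         3HC 2.435897
#> 3 kcat(Trp)/kcat(3HC)     kcat       Trp         3HC 4.000000
```

A complete simulate → fit cycle on synthetic data:

```r
pre <- neiPresets("Trp")                      # scheme, constants, design, optics
ts  <- generateTraceSet(pre$scheme, pre$params, pre$fmodel, pre$design, seed = 1)
fit <- fitGlobal(ts, "nei5", fitOptions(n_starts = 2))
fit$estimates / setNames(as.numeric(pre$params), names(pre$params))[names(fit$estimates)]
```

returns recovered/true ratios near 1 for all eight constants. A thin
command-line wrapper (`inst/scripts/sfkin-cli.R`) exposes the same
operations as `simulate | fit | compare | ratio | reproduce` subcommands
over YAML configs.

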