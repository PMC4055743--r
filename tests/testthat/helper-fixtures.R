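# Shared fixtures: small designs keep ODE/fit tests fast while preserving
# the instrument structure (log acquisition from the dead time, replicate
# averaging, fractional-range noise).

small_design <- function(label, E0 = c(1e-6, 3e-6), S0 = 1e-6,
                         samples_per_decade = 150, ...) {
  pre <- neiPresets(label)
  experimentDesign(conditions = data.frame(E0 = E0, S0 = S0),
                   channels = pre$design$channels,
                   samples_per_decade = samples_per_decade, ...)
}

small_trace_set <- function(label, seed = 1, ...) {
  pre <- neiPresets(label)
  generateTraceSet(pre$scheme, pre$params, pre$fmodel,
                   small_design(label, ...), seed = seed)
}

truth_vector <- function(label) {
  p <- neiRateConstants(label)
  stats::setNames(as.numeric(p), names(p))
}

# single reversible binding step, the minimal scheme used by closed-form
# oracles
one_step_scheme <- function() {
  kineticScheme(c("!name onestep", "E + S <-> ES : k1/k_1"))
}
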