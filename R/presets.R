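# Published pre-steady-state rate constants for Nei acting on DHU-containing
# duplexes, one column per reporter fluorophore. Trp (intrinsic enzyme
# fluorescence) and 3HC resolve three binding equilibria (five-state scheme);
# the single-band DNA labels tCO and Cpy resolve only two (reduced scheme).
# Units: k1 in M^-1 s^-1; k_1, k2, k_2, k3, k_3, kcat in s^-1; KP in M.
.NEI_CONSTANTS <- list(
  Trp = c(k1 = 10.5e6, k_1 = 6.1, k2 = 9.5, k_2 = 1.6,
          k3 = 0.4, k_3 = 0.9, kcat = 0.056, KP = 6.5e-6),
  `3HC` = c(k1 = 53e6, k_1 = 69, k2 = 3.9, k_2 = 4.8,
            k3 = 0.30, k_3 = 0.4, kcat = 0.014, KP = 0.16e-6),
  tCO = c(k1 = 200e6, k_1 = 380, k2 = 0.46, k_2 = 0.005,
          kcat = 0.035, KP = 6.0e-6),
  Cpy = c(k1 = 115e6, k_1 = 246, k2 = 0.52, k_2 = 2.5,
          kcat = 0.040, KP = 3.6e-6)
)

.NEI_SCHEME <- c(Trp = "nei5", `3HC` = "nei5", tCO = "nei4", Cpy = "nei4")

# Instrument metadata per fluorophore: excitation wavelength and long-pass
# emission filter(s). 3HC is dual-band: a 395 nm filter collects the total
# N*+T* emission and a 495 nm filter the T* band alone.
.NEI_OPTICS <- list(
  Trp = list(excitation_nm = 290, channels = c(em_320 = 320)),
  `3HC` = list(excitation_nm = 375, channels = c(total_395 = 395,
                                                 tstar_495 = 495)),
  tCO = list(excitation_nm = 360, channels = c(em_395 = 395)),
  Cpy = list(excitation_nm = 344, channels = c(em_370 = 370)),
  aPu = list(excitation_nm = 310, channels = c(em_370 = 370))
)

#' Published Nei rate constants for a reporter fluorophore
#'
#' @param label one of `"Trp"`, `"3HC"`, `"tCO"`, `"Cpy"`.
#' @return a [rateParams()] object bound to the fluorophore's scheme
#'   (`"nei5"` for Trp and 3HC, `"nei4"` for tCO and Cpy).
#' @export
neiRateConstants <- function(label) {
  if (identical(label, "aPu")) {
    stop("no fitted rate constants exist for aPu: its fluorescence shows ",
         "no significant change on Nei binding, so the kinetics were never fit")
  }
  if (!label %in% names(.NEI_CONSTANTS)) {
    stop("unknown fluorophore label '", label,
         "' (available: ", paste(names(.NEI_CONSTANTS), collapse = ", "), ")")
  }
  rateParams(.NEI_CONSTANTS[[label]])
}

#' Default experiment, scheme and observation model per fluorophore
#'
#' Bundles the published rate-constant column for the requested reporter
#' with its mechanism variant, the instrument optics (excitation
#' wavelength, long-pass filters, 1.4 ms dead time) and a default
#' concentration-series design (1-3 uM enzyme vs 1 uM DNA at 10 C,
#' four averaged replicates), plus a plausible fluorescence observation
#' model used as ground truth when simulating.
#'
#' @param label one of `"Trp"`, `"3HC"`, `"tCO"`, `"Cpy"`; `"aPu"` is an
#'   error (no fitted constants exist).
#' @return list with elements `scheme` (scheme id), `params`
#'   ([rateParams()]), `design` ([experimentDesign()]) and `fmodel`
#'   ([fluorescenceModel()]).
#' @examples
#' pre <- neiPresets("Trp")
#' pre$scheme
#' @export
neiPresets <- function(label) {
  params <- neiRateConstants(label)
  scheme_id <- .NEI_SCHEME[[label]]
  optics <- .NEI_OPTICS[[label]]
  conditions <- data.frame(E0 = c(1e-6, 2e-6, 3e-6), S0 = 1e-6)
  design <- experimentDesign(conditions = conditions,
                             channels = names(optics$channels),
                             filters_nm = optics$channels,
                             excitation_nm = optics$excitation_nm)
  list(scheme = scheme_id, params = params, design = design,
       fmodel = .defaultFModel(label, scheme_id, optics))
}

# Ground-truth observation models for simulation. Coefficients (a.u. per M)
# attach to enzyme-containing species for Trp and to DNA-containing species
# for the base analogues; amplitudes give O(1) a.u. signals at micromolar
# concentrations, with distinct per-complex responses so every binding step
# is visible in the synthetic signal.
.defaultFModel <- function(label, scheme_id, optics) {
  esp <- if (scheme_id == "nei5") c("E", "ES1", "ES2", "ES3", "EP")
         else c("E", "ES1", "ES2", "EP")
  dsp <- if (scheme_id == "nei5") c("S", "ES1", "ES2", "ES3", "EP", "P")
         else c("S", "ES1", "ES2", "EP", "P")
  ch <- list()
  if (identical(label, "Trp")) {
    co <- c(E = 1.00e6, ES1 = 0.82e6, ES2 = 0.65e6, ES3 = 0.78e6, EP = 0.90e6)
    ch[[names(optics$channels)[1L]]] <-
      list(background = 0.1, coef = co[esp])
  } else if (identical(label, "3HC")) {
    # T*-band response: intensity rises on complex formation, relaxes on
    # product release; total channel mirrors it with a different band ratio
    # per species (probe hydration changes along the pathway).
    tstar <- c(S = 1.00e6, ES1 = 1.35e6, ES2 = 1.60e6, ES3 = 1.50e6,
               EP = 1.20e6, P = 1.00e6)
    ratio <- c(S = 0.30, ES1 = 0.24, ES2 = 0.18, ES3 = 0.17,
               EP = 0.22, P = 0.30)
    ch$total_395 <- list(background = 0.05,
                         coef = (1 + ratio[dsp]) * tstar[dsp])
    ch$tstar_495 <- list(background = 0.05, coef = tstar[dsp])
  } else {
    co <- c(S = 1.00e6, ES1 = 1.10e6, ES2 = 0.80e6, EP = 0.95e6, P = 1.00e6)
    ch[[names(optics$channels)[1L]]] <-
      list(background = 0.1, coef = co[dsp])
  }
  for (nm in names(ch)) {
    ch[[nm]]$filter_nm <- unname(optics$channels[nm])
    ch[[nm]]$excitation_nm <- optics$excitation_nm
  }
  fluorescenceModel(ch)
}

#' Dual-channel observation model with a constant band ratio
#'
#' Builds a two-channel 3HC-style model in which every species has the same
#' N*/T* band ratio `r`: the total (395 nm) coefficients are `(1 + r)`
#' times the T* (495 nm) coefficients, so [intensityRatio()] of noiseless
#' traces returns `r` at every time point.
#'
#' @param tstar_coef named numeric, T*-channel coefficients (a.u. per M).
#' @param ratio the constant N*/T* ratio (default 0.3, the duplex
#'   baseline).
#' @param background common channel background (default 0).
#' @return a [fluorescenceModel()] with channels `total_395`, `tstar_495`.
#' @export
constantRatioModel <- function(tstar_coef, ratio = 0.3, background = 0) {
  fluorescenceModel(list(
    total_395 = list(background = background, coef = (1 + ratio) * tstar_coef,
                     filter_nm = 395),
    tstar_495 = list(background = background, coef = tstar_coef,
                     filter_nm = 495)))
}
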