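#' Stopped-flow experiment design
#'
#' Describes a concentration series as mixed in the stopped-flow cell: the
#' nominal enzyme/substrate concentrations per mixing condition, the
#' detection channels, the instrument dead time (samples before it are
#' unobservable), the logarithmic acquisition grid, the replicate count to
#' average, and the noise amplitude.
#'
#' @param conditions data frame with columns `E0`, `S0` (nominal
#'   concentrations, M).
#' @param channels character vector of channel names (must match the
#'   fluorescence model used for generation).
#' @param dead_time instrument dead time, s (default 1.4e-3).
#' @param t_max last acquired time, s.
#' @param samples_per_decade acquisition density of the log grid
#'   (default 1000), capped at `max_samples`.
#' @param max_samples cap on points per trace (default 5000).
#' @param replicates traces averaged per condition (default 4).
#' @param noise_frac additive Gaussian noise SD as a fraction of each
#'   trace's noiseless dynamic range (default 0.02).
#' @param active_fraction fraction of nominal enzyme that is catalytically
#'   active (default 0.8); multiplies `E0` before integration while
#'   reported concentrations stay nominal.
#' @param filters_nm,excitation_nm optional optics metadata.
#' @return object of class `experiment_design`.
#' @export
experimentDesign <- function(conditions, channels,
                             dead_time = 1.4e-3, t_max = 1000,
                             samples_per_decade = 1000L, max_samples = 5000L,
                             replicates = 4L, noise_frac = 0.02,
                             active_fraction = 0.8,
                             filters_nm = NULL, excitation_nm = NULL) {
  stopifnot(is.data.frame(conditions), all(c("E0", "S0") %in% names(conditions)))
  if (any(!is.finite(conditions$E0)) || any(conditions$E0 <= 0)) {
    stop("invalid design: E0 must be positive (M)")
  }
  if (any(!is.finite(conditions$S0)) || any(conditions$S0 <= 0)) {
    stop("invalid design: S0 must be positive (M)")
  }
  if (replicates < 1L) stop("invalid design: replicates must be >= 1")
  if (noise_frac < 0 || noise_frac >= 1) {
    stop("invalid design: noise_frac must lie in [0, 1)")
  }
  if (dead_time <= 0 || t_max <= dead_time) {
    stop("invalid design: need 0 < dead_time < t_max")
  }
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("invalid design: active_fraction must lie in (0, 1]")
  }
  structure(list(conditions = conditions, channels = channels,
                 dead_time = dead_time, t_max = t_max,
                 samples_per_decade = as.integer(samples_per_decade),
                 max_samples = as.integer(max_samples),
                 replicates = as.integer(replicates),
                 noise_frac = noise_frac,
                 active_fraction = active_fraction,
                 filters_nm = filters_nm, excitation_nm = excitation_nm),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Stopped-flow design: ", nrow(x$conditions), " condition(s) x ",
      length(x$channels), " channel(s), dead time ",
      format(x$dead_time * 1e3), " ms, ", x$replicates,
      " replicate(s), noise ", format(100 * x$noise_frac), "% of range\n",
      sep = "")
  invisible(x)
}

# Acquisition grid implied by a design: log-spaced from the dead time.
.designGrid <- function(design) {
  decades <- log10(design$t_max / design$dead_time)
  n <- min(max(2L, ceiling(decades * design$samples_per_decade)),
           design$max_samples)
  logTimeGrid(design$dead_time, design$t_max, n)
}

#' Generate a synthetic stopped-flow trace set
#'
#' Emulates the instrument: for every mixing condition the scheme is
#' integrated (with the active-enzyme fraction applied to the nominal
#' enzyme concentration), projected through the fluorescence model onto
#' each channel, truncated to times at or after the dead time, and
#' measured `replicates` times with independent additive Gaussian noise
#' before averaging. The per-trace noise SD is `noise_frac` times the
#' noiseless dynamic range, so the averaged trace has residual SD
#' `noise_frac * range / sqrt(replicates)`.
#'
#' @param scheme a [kineticScheme()] or built-in scheme id.
#' @param params [rateParams()] for the scheme.
#' @param fmodel a [fluorescenceModel()] covering `design$channels`.
#' @param design an [experimentDesign()].
#' @param seed integer seed; the same design and seed give a bit-identical
#'   trace set.
#' @return object of class `trace_set`: list with `traces` (list of
#'   [sfTrace()], metadata carrying nominal and active concentrations,
#'   channel, and the per-point noise SD of the average) and `truth`
#'   (scheme name, params, fmodel, design, seed) for synthetic sets.
#' @export
generateTraceSet <- function(scheme, params, fmodel, design, seed = 1L) {
  if (is.character(scheme)) scheme <- kineticScheme(scheme)
  stopifnot(inherits(design, "experiment_design"),
            inherits(fmodel, "fluorescence_model"))
  miss <- setdiff(design$channels, names(fmodel$channels))
  if (length(miss)) {
    stop("design channels missing from fluorescence model: ",
         paste(miss, collapse = ", "))
  }
  params <- validateParams(scheme, params, strict = FALSE)
  grid <- .designGrid(design)
  set.seed(as.integer(seed))
  traces <- list()
  for (i in seq_len(nrow(design$conditions))) {
    E0n <- design$conditions$E0[i]
    S0 <- design$conditions$S0[i]
    tc <- integrateScheme(scheme, params,
                          initialConditions(E0n * design$active_fraction, S0),
                          times = grid)
    for (ch in design$channels) {
      clean <- projectObservable(tc, fmodel, ch)
      keep <- clean$time >= design$dead_time
      tt <- clean$time[keep]
      truth <- clean$intensity[keep]
      sdev <- design$noise_frac * diff(range(truth))
      if (sdev > 0 && design$replicates >= 1L) {
        reps <- matrix(stats::rnorm(length(truth) * design$replicates,
                                    sd = sdev),
                       nrow = length(truth))
        avg <- truth + rowMeans(reps)
        sigma_emp <- if (design$replicates > 1L) {
          sqrt(mean(apply(reps, 1L, stats::var)) / design$replicates)
        } else {
          sdev
        }
      } else {
        avg <- truth
        sigma_emp <- 0
      }
      meta <- list(channel = ch,
                   E0_nominal = E0n,
                   E0_active = E0n * design$active_fraction,
                   S0 = S0,
                   replicates = design$replicates,
                   sigma = sigma_emp,
                   sigma_truth = sdev / sqrt(max(1L, design$replicates)),
                   background = fmodel$channels[[ch]]$background,
                   filter_nm = fmodel$channels[[ch]]$filter_nm,
                   excitation_nm = fmodel$channels[[ch]]$excitation_nm)
      traces[[length(traces) + 1L]] <- sfTrace(tt, avg, meta)
    }
  }
  structure(list(traces = traces,
                 truth = list(scheme = scheme$name, params = params,
                              fmodel = fmodel, design = design,
                              seed = as.integer(seed))),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("Trace set:", length(x$traces), "trace(s)")
  if (!is.null(x$truth)) cat(" [synthetic, scheme '", x$truth$scheme,
                             "', seed ", x$truth$seed, "]", sep = "")
  cat("\n")
  for (tr in x$traces) {
    cat(sprintf("  %-10s E0 %.2g M, S0 %.2g M, %d pts\n",
                tr$meta$channel, tr$meta$E0_nominal, tr$meta$S0,
                length(tr$time)))
  }
  invisible(x)
}

#' Write a trace set to CSV files plus a JSON manifest
#'
#' One trace CSV per condition/channel in the dialect of [writeTrace()],
#' plus `manifest.json` recording conditions, seed and (for synthetic
#' sets) the generating truth, enabling exact regeneration.
#'
#' @param ts a `trace_set`.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
writeTraceSet <- function(ts, dir) {
  stopifnot(inherits(ts, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_along(ts$traces)) {
    tr <- ts$traces[[i]]
    fn <- sprintf("trace_%02d_%s.csv", i, tr$meta$channel)
    writeTrace(tr, file.path(dir, fn))
    files[fn] <- fn
  }
  manifest <- list(
    files = unname(files),
    conditions = lapply(ts$traces, function(tr) {
      list(channel = tr$meta$channel, E0_nominal = tr$meta$E0_nominal,
           S0 = tr$meta$S0, replicates = tr$meta$replicates)
    }),
    truth = if (!is.null(ts$truth)) {
      list(scheme = ts$truth$scheme,
           params = as.list(stats::setNames(as.numeric(ts$truth$params),
                                            names(ts$truth$params))),
           fmodel = lapply(ts$truth$fmodel$channels, function(ch) {
             list(background = ch$background,
                  coef = as.list(ch$coef),
                  filter_nm = ch$filter_nm,
                  excitation_nm = ch$excitation_nm)
           }),
           design = list(
             conditions = ts$truth$design$conditions,
             dead_time = ts$truth$design$dead_time,
             t_max = ts$truth$design$t_max,
             samples_per_decade = ts$truth$design$samples_per_decade,
             max_samples = ts$truth$design$max_samples,
             replicates = ts$truth$design$replicates,
             noise_frac = ts$truth$design$noise_frac,
             active_fraction = ts$truth$design$active_fraction),
           seed = ts$truth$seed)
    }
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, manifest = "manifest.json"))
}

#' Read a trace set written by [writeTraceSet()]
#'
#' @param dir directory containing the trace CSVs and `manifest.json`.
#' @return a `trace_set` (truth restricted to what the manifest records).
#' @export
readTraceSet <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in '", dir, "'")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  traces <- lapply(manifest$files, function(fn) readTrace(file.path(dir, fn)))
  for (tr in traces) {
    if (is.null(tr$meta$channel)) {
      stop("trace file missing channel metadata; refusing a silent default")
    }
  }
  truth <- NULL
  if (!is.null(manifest$truth)) {
    fmodel <- NULL
    if (!is.null(manifest$truth$fmodel)) {
      fmodel <- fluorescenceModel(lapply(manifest$truth$fmodel, function(ch) {
        list(background = ch$background, coef = unlist(ch$coef),
             filter_nm = ch$filter_nm, excitation_nm = ch$excitation_nm)
      }))
    }
    truth <- list(scheme = manifest$truth$scheme,
                  params = rateParams(unlist(manifest$truth$params)),
                  fmodel = fmodel,
                  seed = manifest$truth$seed)
  }
  structure(list(traces = traces, truth = truth), class = "trace_set")
}
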