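# Command-layer orchestration: simulate / fit / compare / ratio / reproduce.
# The functions are the interface; inst/scripts/sfkin-cli.R is a thin
# Rscript wrapper over them.

.log <- function(level, ..., verbose = TRUE) {
  if (!verbose && level == "debug") return(invisible(NULL))
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

# "2 uM" / "2e-6" / 2e-6 -> mol/L. Plain numbers are already in M; a uM/nM/mM
# suffix converts explicitly.
.parseConc <- function(x, field = "concentration") {
  if (is.numeric(x)) {
    v <- x
  } else {
    m <- regmatches(x, regexec(
      "^[[:space:]]*([-0-9.eE+]+)[[:space:]]*(uM|nM|mM|M)?[[:space:]]*$", x))[[1]]
    if (length(m) != 3L) stop("cannot parse ", field, " '", x, "'")
    v <- as.numeric(m[2L]) *
      switch(if (nzchar(m[3L])) m[3L] else "M",
             M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  }
  if (!is.finite(v) || v <= 0) {
    stop("invalid ", field, ": must be a positive concentration, got '", x, "'")
  }
  v
}

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file '", config, "' does not exist")
    cfg <- yaml::read_yaml(config)
    cfg$.hash <- unname(tools::md5sum(config))
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop("'config' must be a YAML file path or a list")
  }
}

.configDesign <- function(cfg, preset) {
  design <- preset$design
  if (!is.null(cfg$conditions)) {
    design$conditions <- data.frame(
      E0 = vapply(cfg$conditions, function(cc) .parseConc(cc$E0, "E0"),
                  numeric(1L)),
      S0 = vapply(cfg$conditions, function(cc) .parseConc(cc$S0, "S0"),
                  numeric(1L)))
  }
  for (f in c("replicates", "noise_frac", "dead_time", "t_max",
              "samples_per_decade", "max_samples", "active_fraction")) {
    if (!is.null(cfg[[f]])) design[[f]] <- cfg[[f]]
  }
  # re-validate after overrides
  do.call(experimentDesign,
          design[c("conditions", "channels", "dead_time", "t_max",
                   "samples_per_decade", "max_samples", "replicates",
                   "noise_frac", "active_fraction", "filters_nm",
                   "excitation_nm")])
}

#' Simulate a stopped-flow trace set from a config
#'
#' Config fields: `label` (fluorophore preset) or `scheme` + `params`;
#' optional `conditions` (list of `E0`/`S0`, micromolar accepted with a
#' `uM` suffix), design overrides (`replicates`, `noise_frac`, ...),
#' `seed`, `out` (output directory).
#'
#' @param config YAML file path or list.
#' @param seed overrides the config seed when non-`NULL`.
#' @param out overrides the config output directory.
#' @param verbose log progress.
#' @return the written `trace_set`, invisibly; files land in `out`
#'   (trace CSVs plus `manifest.json` carrying seed and config hash).
#' @export
cmdSimulate <- function(config, seed = NULL, out = NULL, verbose = TRUE) {
  cfg <- .loadConfig(config)
  seed <- if (!is.null(seed)) as.integer(seed)
          else if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  out <- if (!is.null(out)) out else cfg$out
  if (is.null(out)) stop("no output directory: set 'out'")
  if (!is.null(cfg$label)) {
    preset <- neiPresets(cfg$label)
  } else {
    stop("config must name a fluorophore 'label' with published constants")
  }
  design <- .configDesign(cfg, preset)
  .log("info", "simulating '", cfg$label, "' (scheme ", preset$scheme,
       "), seed ", seed, verbose = verbose)
  ts <- generateTraceSet(preset$scheme, preset$params, preset$fmodel,
                         design, seed = seed)
  files <- writeTraceSet(ts, out)
  # stamp seed + config hash into the manifest
  mf <- file.path(out, "manifest.json")
  manifest <- jsonlite::read_json(mf)
  manifest$seed <- seed
  manifest$config_hash <- if (!is.null(cfg$.hash)) cfg$.hash else NA
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .log("info", "wrote ", length(files), " file(s) to ", out,
       verbose = verbose)
  invisible(ts)
}

#' Reproduce modelled intermediate time courses for a fluorophore
#'
#' Integrates the mechanism bound to the fluorophore with its published
#' rate constants at the requested concentrations and reports, per
#' transient intermediate, the (interpolated) time and value of maximal
#' concentration, plus whether the species accumulates monotonically
#' (boundary maximum — the free product). The species-concentration matrix
#' can be written as CSV.
#'
#' @param label fluorophore with published constants (`"Trp"`, `"3HC"`,
#'   `"tCO"`, `"Cpy"`).
#' @param E0,S0 mixed concentrations (M, or strings like `"2 uM"`).
#' @param out optional directory for `timecourse_<label>.csv` and
#'   `timesofmax_<label>.json`.
#' @param t_max end of the reporting grid, s.
#' @return list with `timecourse` (a `time_course`) and `times_of_max`
#'   (data frame: species, time_s, value_M, boundary).
#' @export
cmdReproduceTimecourses <- function(label, E0 = "2 uM", S0 = "2 uM",
                                    out = NULL, t_max = 1000) {
  preset <- neiPresets(label)
  sc <- kineticScheme(preset$scheme)
  init <- initialConditions(.parseConc(E0, "E0"), .parseConc(S0, "S0"))
  tc <- integrateScheme(sc, preset$params, init,
                        times = logTimeGrid(to = t_max))
  inter <- setdiff(sc$species, c("E", "S"))
  tom <- do.call(rbind, lapply(inter, function(sp) {
    m <- timeOfMax(tc, sp)
    data.frame(species = sp, time_s = m$time, value_M = m$value,
               boundary = m$boundary)
  }))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    writeTimeCourse(tc, file.path(out, paste0("timecourse_", label, ".csv")))
    jsonlite::write_json(tom, file.path(out,
                                        paste0("timesofmax_", label, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(timecourse = tc, times_of_max = tom)
}

#' Fit trace files from a manifest directory
#'
#' Reads the trace set written by [cmdSimulate()] / [writeTraceSet()],
#' runs [fitGlobal()] for each requested scheme (and [compareModels()]
#' when more than one is listed), and writes a JSON fit report plus
#' residual CSVs. For synthetic sets the report includes the
#' recovered/true ratio per rate constant.
#'
#' @param config YAML path or list with fields `traces` (manifest
#'   directory), `schemes` (ids), optional `start`, `n_starts`, `seed`,
#'   `out`.
#' @param seed,out overrides.
#' @param verbose log progress.
#' @return list with `fits` (per scheme) and optional `comparison`,
#'   invisibly; report written to `out/fit_report.json`.
#' @export
cmdFit <- function(config, seed = NULL, out = NULL, verbose = TRUE) {
  cfg <- .loadConfig(config)
  seed <- if (!is.null(seed)) as.integer(seed)
          else if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  out <- if (!is.null(out)) out else cfg$out
  if (is.null(cfg$traces)) stop("config must name a 'traces' manifest directory")
  ts <- readTraceSet(cfg$traces)
  schemes <- cfg$schemes
  if (is.null(schemes)) stop("config must list at least one scheme id")
  opts <- fitOptions(
    start = if (!is.null(cfg$start)) unlist(cfg$start) else NULL,
    n_starts = if (!is.null(cfg$n_starts)) cfg$n_starts else 16L,
    channel_species = cfg$channel_species,
    seed = seed)
  .log("info", "fitting ", length(ts$traces), " trace(s) with scheme(s) ",
       paste(schemes, collapse = ", "), verbose = verbose)
  result <- if (length(schemes) > 1L) {
    cmp <- compareModels(ts, as.list(schemes), opts)
    list(fits = cmp$fits, comparison = cmp)
  } else {
    list(fits = stats::setNames(list(fitGlobal(ts, schemes[[1L]], opts)),
                                schemes[[1L]]),
         comparison = NULL)
  }
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    report <- list(seed = seed,
                   config_hash = if (!is.null(cfg$.hash)) cfg$.hash else NA)
    for (id in names(result$fits)) {
      fr <- result$fits[[id]]
      if (!inherits(fr, "fit_result")) {
        report$fits[[id]] <- list(error = conditionMessage(fr))
        next
      }
      entry <- list(estimates = as.list(fr$estimates),
                    se = as.list(fr$se),
                    fixed = as.list(fr$fixed),
                    rss = fr$rss, chisq_red = fr$chisq_red,
                    n = fr$n, p = fr$p, aic = aicOf(fr),
                    converged = fr$converged,
                    bounds_hit = as.list(fr$bounds_hit),
                    per_trace = fr$per_trace)
      if (!is.null(ts$truth) &&
          identical(ts$truth$scheme, fr$scheme)) {
        truth <- stats::setNames(as.numeric(ts$truth$params),
                                 names(ts$truth$params))
        common <- intersect(names(fr$estimates), names(truth))
        entry$recovered_over_true <-
          as.list(fr$estimates[common] / truth[common])
      }
      report$fits[[id]] <- entry
    }
    if (!is.null(result$comparison)) {
      report$comparison <- list(table = result$comparison$table,
                                ftests = result$comparison$ftests)
    }
    jsonlite::write_json(report, file.path(out, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log("info", "report written to ", file.path(out, "fit_report.json"),
         verbose = verbose)
  }
  invisible(result)
}

#' Cross-fluorophore ratio report from published or fitted constants
#'
#' @param labels fluorophore labels to include (default all with
#'   published constants).
#' @param fits optional named list of `fit_result` objects overriding the
#'   published constants for those labels.
#' @param out optional directory for `ratios.json`.
#' @return a `ratio_report` data frame.
#' @export
cmdRatio <- function(labels = c("Trp", "3HC", "tCO", "Cpy"), fits = NULL,
                     out = NULL) {
  results <- stats::setNames(lapply(labels, neiRateConstants), labels)
  for (nm in names(fits)) results[[nm]] <- fits[[nm]]
  rep <- derivedQuantities(results)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(rep, file.path(out, "ratios.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}
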