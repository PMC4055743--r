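#' Logarithmic reporting grid
#'
#' Stopped-flow kinetics span many decades; all figures and fits use a
#' log-spaced time grid starting at the instrument dead time.
#'
#' @param from first reported time, s (default the 1.4 ms dead time).
#' @param to last reported time, s.
#' @param n number of grid points.
#' @return strictly increasing numeric vector of times (s), not including 0.
#' @export
logTimeGrid <- function(from = 1.4e-3, to = 1000, n = 500L) {
  stopifnot(from > 0, to > from, n >= 2L)
  10^seq(log10(from), log10(to), length.out = n)
}

# Load a scheme + rate vector into the compiled mass-action RHS.
.maLoad <- function(scheme, rates) {
  N <- stoichiometryMatrix(scheme)
  r1 <- integer(length(scheme$reactions))
  r2 <- integer(length(scheme$reactions))
  for (j in seq_along(scheme$reactions)) {
    re <- match(scheme$reactions[[j]]$reactants, scheme$species)
    r1[j] <- re[1L]
    r2[j] <- if (length(re) == 2L) re[2L] else 0L
  }
  storage.mode(N) <- "double"
  .Call(ma_set_scheme, length(scheme$species), length(scheme$reactions),
        r1, r2, N, as.double(rates))
  invisible(NULL)
}

#' Integrate a kinetic scheme
#'
#' Solves the mass-action ODE system with a stiff-capable integrator
#' (`deSolve::lsoda` on a compiled right-hand side). Tight tolerances are
#' the default because rate constants span roughly 10^-2 to 10^8.
#'
#' @param scheme a [kineticScheme()] object.
#' @param params rate constants ([rateParams()]); validated against the
#'   scheme.
#' @param init an [initialConditions()] object.
#' @param times reporting grid (s); default [logTimeGrid()]. `t = 0` is
#'   always integrated and included in the result.
#' @param rtol,atol relative / absolute solver tolerance (atol in M).
#' @param check_conservation verify every conservation-group total is
#'   constant to 1e-6 relative (default `TRUE`).
#' @param negative_floor solver undershoot below this magnitude (M) is an
#'   error; smaller undershoot is clipped to 0 (default 1e-12 M).
#' @return object of class `time_course`: list with `time` (length m),
#'   `conc` (species x m concentration matrix, M; tiny negative solver
#'   undershoot below 1e-12 M is clipped to 0), and `provenance`.
#' @examples
#' sc <- kineticScheme("nei5")
#' tc <- integrateScheme(sc, neiRateConstants("Trp"),
#'                       initialConditions(2e-6, 2e-6))
#' timeOfMax(tc, "ES2")
#' @export
integrateScheme <- function(scheme, params, init, times = logTimeGrid(),
                            rtol = 1e-8, atol = 1e-12,
                            check_conservation = TRUE,
                            negative_floor = 1e-12) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  params <- validateParams(scheme, params, strict = FALSE)
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("'times' must be non-negative and strictly increasing")
  }
  if (max(times) > 1e4) stop("reporting grid must lie within [0, 1e4] s")
  rates <- .resolveRates(scheme, params)
  y0 <- .initialState(scheme, init)
  tt <- if (times[1L] > 0) c(0, times) else times
  .maLoad(scheme, rates)
  out <- deSolve::lsoda(y0, tt, func = "ma_derivs", parms = NULL,
                        dllname = "sfkin", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE solver failed to converge: ",
         paste(attr(out, "istate")[1:2], collapse = "/"))
  }
  conc <- t(unclass(out)[, -1L, drop = FALSE])
  if (any(!is.finite(conc))) stop("non-finite concentrations in ODE solution")
  if (any(conc < -negative_floor)) {
    stop("solver produced concentrations below -", format(negative_floor),
         " M; tighten tolerances")
  }
  conc[conc < 0] <- 0
  tc <- structure(list(
    time = tt,
    conc = conc,
    provenance = list(scheme = scheme$name, params = params, init = init,
                      rtol = rtol, atol = atol)
  ), class = "time_course")
  if (check_conservation) .checkTotals(scheme, tc, init)
  tc
}

.checkTotals <- function(scheme, tc, init, tol = 1e-6) {
  for (g in scheme$conservation) {
    tot <- colSums(tc$conc[g, , drop = FALSE])
    ref <- tot[1L]
    if (ref > 0 && max(abs(tot - ref)) / ref > tol) {
      stop("conservation violated for group {", paste(g, collapse = ", "),
           "}: relative drift ", format(max(abs(tot - ref)) / ref))
    }
  }
  invisible(TRUE)
}

#' @export
print.time_course <- function(x, ...) {
  cat("Time course of scheme '", x$provenance$scheme, "': ",
      nrow(x$conc), " species x ", length(x$time), " time points, t in [",
      format(min(x$time)), ", ", format(max(x$time)), "] s\n", sep = "")
  invisible(x)
}

#' Time and value of a species' concentration maximum
#'
#' Finds the discrete maximum of a species curve and refines it with
#' three-point quadratic interpolation in time. For monotonically
#' accumulating species (e.g. free product) the maximum sits on the final
#' grid point and is flagged as a boundary maximum; no interpolation is
#' attempted there. Ties resolve to the earliest maximum.
#'
#' @param tc a `time_course` from [integrateScheme()].
#' @param species species label.
#' @return list with `time` (s), `value` (M) and `boundary` (logical).
#' @export
timeOfMax <- function(tc, species) {
  stopifnot(inherits(tc, "time_course"))
  if (!species %in% rownames(tc$conc)) {
    stop("species '", species, "' not present in time course")
  }
  y <- tc$conc[species, ]
  t <- tc$time
  if (!length(t)) stop("empty time grid")
  i <- which.max(y) # earliest on ties
  if (i == length(y) || i == 1L) {
    return(list(time = t[i], value = y[i],
                boundary = i == length(y)))
  }
  # quadratic through (t[i-1],y[i-1]), (t[i],y[i]), (t[i+1],y[i+1])
  t0 <- t[i - 1L]; t1 <- t[i]; t2 <- t[i + 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  d1 <- (y1 - y0) / (t1 - t0)
  d2 <- (y2 - y1) / (t2 - t1)
  a <- (d2 - d1) / (t2 - t0)
  if (a >= 0) { # degenerate/flat: keep the grid point
    return(list(time = t1, value = y1, boundary = FALSE))
  }
  tm <- (t0 + t1) / 2 - d1 / (2 * a)
  tm <- min(max(tm, t0), t2)
  ym <- y0 + d1 * (tm - t0) + a * (tm - t0) * (tm - t1)
  list(time = tm, value = ym, boundary = FALSE)
}

#' First time a species reaches a fraction of its maximum
#'
#' Linear interpolation between the bracketing grid points of the first
#' upward crossing of `frac * max`.
#'
#' @param tc a `time_course`.
#' @param species species label.
#' @param frac fraction of the global maximum (default 0.5, the half-rise).
#' @return time in seconds.
#' @export
timeToFraction <- function(tc, species, frac = 0.5) {
  stopifnot(inherits(tc, "time_course"), frac > 0, frac <= 1)
  if (!species %in% rownames(tc$conc)) {
    stop("species '", species, "' not present in time course")
  }
  y <- tc$conc[species, ]
  t <- tc$time
  target <- frac * max(y)
  i <- which(y >= target)[1L]
  if (is.na(i)) stop("species never reaches the requested fraction")
  if (i == 1L) return(t[1L])
  t[i - 1L] + (target - y[i - 1L]) * (t[i] - t[i - 1L]) / (y[i] - y[i - 1L])
}

#' Write / read a time course as CSV
#'
#' Columns: `time_s` plus one column per species (concentrations in M).
#'
#' @param tc a `time_course`.
#' @param file path.
#' @return `writeTimeCourse` returns `file` invisibly; `readTimeCourse`
#'   returns a `time_course` (without provenance).
#' @export
writeTimeCourse <- function(tc, file) {
  stopifnot(inherits(tc, "time_course"))
  df <- data.frame(time_s = tc$time, t(tc$conc), check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTimeCourse
#' @export
readTimeCourse <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  structure(list(time = df$time_s,
                 conc = t(as.matrix(df[, setdiff(names(df), "time_s"),
                                       drop = FALSE])),
                 provenance = list(scheme = NA_character_)),
            class = "time_course")
}
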