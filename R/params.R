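#' Rate constants for a kinetic scheme
#'
#' A named set of rate constants in internal units (M, s): bimolecular
#' association constants in M^-1 s^-1, unimolecular rates in s^-1, and the
#' product-complex dissociation constant `KP` in M. Values must be strictly
#' positive and finite.
#'
#' @param ... named rate constants, or a single named numeric vector / list.
#' @param units optional named character vector declaring the unit class of
#'   each value (`"M-1s-1"`, `"s-1"`, `"M"`); checked against the reaction
#'   order by [validateParams()].
#' @return object of class `rate_params` (named numeric vector, with a
#'   `units` attribute when given).
#' @examples
#' p <- rateParams(k1 = 10.5e6, k_1 = 6.1, k2 = 9.5, k_2 = 1.6,
#'                 k3 = 0.4, k_3 = 0.9, kcat = 0.056, KP = 6.5e-6)
#' @export
rateParams <- function(..., units = NULL) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && !is.null(names(vals[[1L]]))) {
    vals <- as.list(vals[[1L]])
  }
  if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
    stop("all rate constants must be named")
  }
  x <- vapply(vals, function(v) as.numeric(v)[1L], numeric(1L))
  structure(x, units = units, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Rate constants (internal units M, s):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Validate rate constants against a scheme
#'
#' Checks completeness (every rate label the scheme requires is present),
#' strict positivity and finiteness, and — when the parameters declare unit
#' classes — that each unit matches the reaction order (M^-1 s^-1 for
#' bimolecular steps, s^-1 for unimolecular, M for an equilibrium
#' dissociation constant). Defaults declared by the scheme (the
#' product-release `koff`) are filled in.
#'
#' @param scheme a [kineticScheme()] object.
#' @param params a [rateParams()] object or named numeric vector.
#' @param strict if `TRUE` (default) labels not used by the scheme are an
#'   error, catching configuration typos; if `FALSE` extras are ignored.
#' @return the checked `rate_params`, with scheme defaults filled in.
#' @export
validateParams <- function(scheme, params, strict = TRUE) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!inherits(params, "rate_params")) params <- rateParams(params)
  labs <- .requiredRateLabels(scheme)
  have <- names(params)
  miss <- setdiff(labs$required, have)
  if (length(miss)) {
    stop("missing rate constant(s) for scheme '", scheme$name, "': ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(have, c(labs$required, labs$optional))
  if (strict && length(extra)) {
    stop("rate constant(s) not used by scheme '", scheme$name, "': ",
         paste(extra, collapse = ", "),
         " (strict matching; pass strict = FALSE to ignore)")
  }
  keep <- intersect(have, c(labs$required, labs$optional))
  vals <- as.numeric(params)[match(keep, have)]
  names(vals) <- keep
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    stop("rate constants must be strictly positive and finite: ",
         paste(keep[bad], collapse = ", "))
  }
  units <- attr(params, "units")
  if (!is.null(units)) {
    expected <- .rateUnitClasses(scheme)
    for (nm in intersect(names(units), names(expected))) {
      if (!identical(units[[nm]], expected[[nm]])) {
        stop("unit mismatch for '", nm, "': declared ", units[[nm]],
             ", expected ", expected[[nm]])
      }
    }
  }
  for (d in names(scheme$rate_defaults)) {
    if (!d %in% names(vals)) vals[d] <- scheme$rate_defaults[[d]]
  }
  structure(vals, units = units, class = "rate_params")
}

# Numeric rate vector, one entry per reaction in scheme order, with derived
# rates (kon = koff/KP) resolved.
.resolveRates <- function(scheme, params) {
  params <- validateParams(scheme, params, strict = FALSE)
  vals <- as.numeric(params)
  names(vals) <- names(params)
  for (d in names(scheme$derived_rates)) {
    rule <- scheme$derived_rates[[d]]
    vals[d] <- vals[[rule$num]] / vals[[rule$den]]
  }
  out <- vals[vapply(scheme$reactions, `[[`, "", "rate")]
  if (anyNA(out)) stop("unresolved reaction rate(s)")
  unname(out)
}

#' Initial conditions for a mixing experiment
#'
#' Total active-enzyme and substrate concentrations at the moment of mixing;
#' all intermediates and product start at zero.
#'
#' @param E0 total active enzyme concentration, M.
#' @param S0 total substrate concentration, M.
#' @return object of class `initial_conditions`.
#' @export
initialConditions <- function(E0, S0) {
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 <= 0) {
    stop("E0 must be a single positive finite concentration (M)")
  }
  if (!is.numeric(S0) || length(S0) != 1L || !is.finite(S0) || S0 <= 0) {
    stop("S0 must be a single positive finite concentration (M)")
  }
  structure(list(E0 = E0, S0 = S0), class = "initial_conditions")
}

# Map initial conditions onto a scheme's species vector: free enzyme label
# "E" gets E0, free substrate "S" gets S0, everything else zero.
.initialState <- function(scheme, init) {
  stopifnot(inherits(init, "initial_conditions"))
  y0 <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  if (!all(c("E", "S") %in% scheme$species)) {
    stop("scheme must contain species 'E' and 'S' for standard mixing initial conditions")
  }
  y0["E"] <- init$E0
  y0["S"] <- init$S0
  y0
}
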