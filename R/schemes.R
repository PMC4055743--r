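#' Kinetic schemes for stopped-flow mechanism analysis
#'
#' A kinetic scheme is an ordered list of species plus an ordered list of
#' elementary mass-action reactions (at most bimolecular on either side).
#' Two mechanisms of Endonuclease VIII (Nei) acting on a
#' 5,6-dihydrouracil-containing duplex are built in:
#'
#' \describe{
#'   \item{`"nei5"`}{the five-intermediate mechanism
#'     `E + S <-> ES1 <-> ES2 <-> ES3 -> EP <-> E + P`: three sequential
#'     binding equilibria (initial encounter, DNA bending/base eversion,
#'     active-site adjustment), one lumped irreversible catalytic step
#'     (`kcat` covers N-glycosidic cleavage plus beta- and
#'     delta-elimination), and a product-release equilibrium.}
#'   \item{`"nei4"`}{the reduced mechanism with two binding equilibria
#'     (`ES3` absent), adequate for single-band DNA probes that cannot
#'     distinguish the third conformational transition.}
#' }
#'
#' Product release is parameterised by the dissociation equilibrium constant
#' `KP` (M): the dissociation rate is `koff` (default 10 s^-1, fast relative
#' to `kcat` so binding-phase observables are insensitive to it) and the
#' association rate is derived as `koff/KP`. Only `KP` is treated as
#' identifiable.
#'
#' @param spec either the name of a built-in scheme (`"nei5"`, `"nei4"`) or
#'   a character vector of reaction lines in the plain-text dialect
#'   `"A + B <-> C : kf/kr"` / `"C -> D : k"` (see [readScheme()] for the
#'   full dialect including directives).
#' @param name optional scheme name when building from reaction lines.
#' @return an object of class `kinetic_scheme`: a list with elements
#'   `name`, `species`, `reactions` (each a list with `reactants`,
#'   `products`, `rate`), `reversible_pairs` (2-row integer matrix),
#'   `conservation` (named list of species subsets with constant total),
#'   `derived_rates` and `rate_defaults` (the `kon = koff/KP` realisation).
#' @examples
#' sc <- kineticScheme("nei5")
#' sc
#' stoichiometryMatrix(sc)
#' @export
kineticScheme <- function(spec, name = NULL) {
  if (is.character(spec) && length(spec) == 1L && !grepl("[:>]", spec)) {
    return(.builtinScheme(spec))
  }
  if (is.character(spec)) {
    return(.parseSchemeLines(spec, name = name))
  }
  stop("'spec' must be a built-in scheme name or a character vector of reaction lines")
}

.builtinScheme <- function(id) {
  if (identical(id, "nei5")) {
    lines <- c(
      "!name nei5",
      "!species E S ES1 ES2 ES3 EP P",
      "E + S <-> ES1 : k1/k_1",
      "ES1 <-> ES2 : k2/k_2",
      "ES2 <-> ES3 : k3/k_3",
      "ES3 -> EP : kcat",
      "EP <-> E + P : koff/kon",
      "!derived kon = koff/KP",
      "!default koff = 10"
    )
  } else if (identical(id, "nei4")) {
    lines <- c(
      "!name nei4",
      "!species E S ES1 ES2 EP P",
      "E + S <-> ES1 : k1/k_1",
      "ES1 <-> ES2 : k2/k_2",
      "ES2 -> EP : kcat",
      "EP <-> E + P : koff/kon",
      "!derived kon = koff/KP",
      "!default koff = 10"
    )
  } else {
    stop("unknown scheme identifier '", id, "' (built-ins: \"nei5\", \"nei4\")")
  }
  .parseSchemeLines(lines)
}

# Parse the plain-text scheme dialect. Reaction lines:
#   "A + B <-> C : kf/kr"   reversible pair (two elementary reactions)
#   "C -> D : k"            irreversible elementary reaction
# Directives:
#   "!name id"              scheme name
#   "!species A B C"        pins species ordering
#   "!derived x = a/b"      reaction-rate label x computed as params a / b
#   "!default a = v"        default value for parameter label a
#   "!conserve A B C"       pins a conservation group (else auto-detected)
.parseSchemeLines <- function(lines, name = NULL) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  species <- character()
  reactions <- list()
  pairs <- list()
  derived <- list()
  defaults <- list()
  conserve <- list()

  add_species <- function(x) {
    new <- setdiff(x, species)
    if (length(new)) species <<- c(species, new)
  }
  parse_side <- function(txt, line) {
    labs <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    if (any(!nzchar(labs)) || length(labs) < 1L) {
      stop("malformed reaction side in '", line, "'")
    }
    if (length(labs) > 2L) {
      stop("termolecular reaction in '", line, "': at most two species per side")
    }
    labs
  }

  for (ln in lines) {
    if (startsWith(ln, "!")) {
      toks <- strsplit(sub("^!", "", ln), "[[:space:]]+")[[1]]
      key <- toks[1L]
      if (key == "name") {
        name <- toks[2L]
      } else if (key == "species") {
        add_species(toks[-1L])
      } else if (key == "conserve") {
        conserve[[length(conserve) + 1L]] <- toks[-1L]
      } else if (key == "derived") {
        m <- regmatches(ln, regexec(
          "^!derived[[:space:]]+([^[:space:]=]+)[[:space:]]*=[[:space:]]*([^/[:space:]]+)[[:space:]]*/[[:space:]]*([^[:space:]]+)$", ln))[[1]]
        if (length(m) != 4L) stop("malformed derived-rate directive '", ln, "'")
        derived[[m[2L]]] <- list(num = m[3L], den = m[4L])
      } else if (key == "default") {
        m <- regmatches(ln, regexec(
          "^!default[[:space:]]+([^[:space:]=]+)[[:space:]]*=[[:space:]]*([^[:space:]]+)$", ln))[[1]]
        if (length(m) != 3L) stop("malformed default directive '", ln, "'")
        defaults[[m[2L]]] <- as.numeric(m[3L])
      } else {
        stop("unknown directive '", ln, "'")
      }
      next
    }
    m <- regmatches(ln, regexec(
      "^(.+?)(<->|->)(.+?):(.+)$", ln))[[1]]
    if (length(m) != 5L) stop("malformed reaction line '", ln, "'")
    lhs <- parse_side(m[2L], ln)
    rhs <- parse_side(m[4L], ln)
    rate <- trimws(m[5L])
    add_species(c(lhs, rhs))
    if (m[3L] == "<->") {
      kk <- trimws(strsplit(rate, "/", fixed = TRUE)[[1]])
      if (length(kk) != 2L || any(!nzchar(kk))) {
        stop("reversible reaction '", ln, "' needs a 'kf/kr' rate pair")
      }
      i <- length(reactions) + 1L
      reactions[[i]] <- list(reactants = lhs, products = rhs, rate = kk[1L])
      reactions[[i + 1L]] <- list(reactants = rhs, products = lhs, rate = kk[2L])
      pairs[[length(pairs) + 1L]] <- c(i, i + 1L)
    } else {
      if (grepl("/", rate, fixed = TRUE)) {
        stop("irreversible reaction '", ln, "' takes a single rate label")
      }
      reactions[[length(reactions) + 1L]] <-
        list(reactants = lhs, products = rhs, rate = rate)
    }
  }
  if (!length(reactions)) stop("scheme contains no reactions")

  sc <- structure(list(
    name = if (is.null(name)) "scheme" else name,
    species = species,
    reactions = reactions,
    reversible_pairs = if (length(pairs)) do.call(cbind, pairs) else
      matrix(integer(), nrow = 2L),
    conservation = list(),
    derived_rates = derived,
    rate_defaults = defaults
  ), class = "kinetic_scheme")
  sc$conservation <- if (length(conserve)) {
    .checkConservation(sc, conserve)
  } else {
    .detectConservation(sc)
  }
  .validateScheme(sc)
  sc
}

.validateScheme <- function(sc) {
  for (rx in sc$reactions) {
    miss <- setdiff(c(rx$reactants, rx$products), sc$species)
    if (length(miss)) {
      stop("reaction references undeclared species: ", paste(miss, collapse = ", "))
    }
    if (length(rx$reactants) > 2L || length(rx$products) > 2L ||
        length(rx$reactants) < 1L || length(rx$products) < 1L) {
      stop("reactions must have 1 or 2 reactants and 1 or 2 products")
    }
  }
  for (g in sc$conservation) {
    ind <- as.numeric(sc$species %in% g)
    if (any(abs(crossprod(ind, stoichiometryMatrix(sc))) != 0)) {
      stop("conservation group {", paste(g, collapse = ", "),
           "} is not in the left null space of the stoichiometry matrix")
    }
  }
  invisible(sc)
}

.checkConservation <- function(sc, groups) {
  N <- stoichiometryMatrix(sc)
  out <- list()
  for (g in groups) {
    miss <- setdiff(g, sc$species)
    if (length(miss)) stop("conservation group names unknown species: ",
                           paste(miss, collapse = ", "))
    ind <- as.numeric(sc$species %in% g)
    if (any(abs(crossprod(ind, N)) != 0)) {
      stop("declared conservation group {", paste(g, collapse = ", "),
           "} is not conserved")
    }
    out[[length(out) + 1L]] <- g
  }
  names(out) <- paste0("group", seq_along(out))
  out
}

# Exhaustive search for minimal 0/1 conservation groups (exact integer test).
# Kept to schemes of moderate size; larger schemes should declare groups.
.detectConservation <- function(sc) {
  n <- length(sc$species)
  if (n > 14L) return(list())
  N <- stoichiometryMatrix(sc)
  found <- list()
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      if (length(found) &&
          any(vapply(found, function(f) all(f %in% idx), logical(1L)))) next
      ind <- numeric(n); ind[idx] <- 1
      if (all(crossprod(ind, N) == 0)) found[[length(found) + 1L]] <- idx
    }
  }
  out <- lapply(found, function(idx) sc$species[idx])
  names(out) <- paste0("group", seq_along(out))
  out
}

#' Stoichiometry matrix of a kinetic scheme
#'
#' @param scheme a [kineticScheme()] object.
#' @return integer matrix (species x reactions); entry is the net
#'   stoichiometric change of the species in the reaction. Every
#'   conservation group of the scheme annihilates it from the left.
#' @export
stoichiometryMatrix <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  N <- matrix(0, nrow = length(scheme$species), ncol = length(scheme$reactions),
              dimnames = list(scheme$species,
                              vapply(scheme$reactions, `[[`, "", "rate")))
  for (j in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[j]]
    for (s in rx$reactants) N[s, j] <- N[s, j] - 1
    for (s in rx$products) N[s, j] <- N[s, j] + 1
  }
  N
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", length(x$species), " species, ",
      length(x$reactions), " elementary reactions\n", sep = "")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  done <- logical(length(x$reactions))
  if (ncol(x$reversible_pairs)) {
    for (p in seq_len(ncol(x$reversible_pairs))) {
      i <- x$reversible_pairs[1L, p]; j <- x$reversible_pairs[2L, p]
      rx <- x$reactions[[i]]
      cat("  ", paste(rx$reactants, collapse = " + "), " <-> ",
          paste(rx$products, collapse = " + "), " : ", rx$rate, "/",
          x$reactions[[j]]$rate, "\n", sep = "")
      done[c(i, j)] <- TRUE
    }
  }
  for (i in which(!done)) {
    rx <- x$reactions[[i]]
    cat("  ", paste(rx$reactants, collapse = " + "), " -> ",
        paste(rx$products, collapse = " + "), " : ", rx$rate, "\n", sep = "")
  }
  for (d in names(x$derived_rates)) {
    cat("  derived: ", d, " = ", x$derived_rates[[d]]$num, "/",
        x$derived_rates[[d]]$den, "\n", sep = "")
  }
  for (g in x$conservation) {
    cat("  conserved total:", paste(g, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Serialise a kinetic scheme to its plain-text dialect
#'
#' Writes one reaction per line (`"A + B <-> C : kf/kr"`,
#' `"C -> D : k"`) plus directives pinning the species order, derived-rate
#' realisation, parameter defaults and conservation groups, so that
#' [readScheme()] reproduces an identical scheme.
#'
#' @param scheme a [kineticScheme()] object.
#' @param file path, or `NULL` to return the lines invisibly.
#' @return character vector of lines, invisibly.
#' @export
writeScheme <- function(scheme, file = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  lines <- c(paste("!name", scheme$name),
             paste("!species", paste(scheme$species, collapse = " ")))
  done <- logical(length(scheme$reactions))
  side <- function(s) paste(s, collapse = " + ")
  ordered <- character(length(scheme$reactions))
  if (ncol(scheme$reversible_pairs)) {
    for (p in seq_len(ncol(scheme$reversible_pairs))) {
      i <- scheme$reversible_pairs[1L, p]; j <- scheme$reversible_pairs[2L, p]
      rx <- scheme$reactions[[i]]
      ordered[i] <- paste0(side(rx$reactants), " <-> ", side(rx$products),
                           " : ", rx$rate, "/", scheme$reactions[[j]]$rate)
      done[c(i, j)] <- TRUE
    }
  }
  for (i in which(!done)) {
    rx <- scheme$reactions[[i]]
    ordered[i] <- paste0(side(rx$reactants), " -> ", side(rx$products),
                         " : ", rx$rate)
  }
  lines <- c(lines, ordered[nzchar(ordered)])
  for (d in names(scheme$derived_rates)) {
    lines <- c(lines, paste0("!derived ", d, " = ",
                             scheme$derived_rates[[d]]$num, "/",
                             scheme$derived_rates[[d]]$den))
  }
  for (d in names(scheme$rate_defaults)) {
    lines <- c(lines, paste0("!default ", d, " = ",
                             format(scheme$rate_defaults[[d]], digits = 15)))
  }
  for (g in scheme$conservation) {
    lines <- c(lines, paste("!conserve", paste(g, collapse = " ")))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a kinetic scheme from a plain-text scheme file
#'
#' @param file path to a scheme file in the dialect of [writeScheme()].
#' @return a `kinetic_scheme` object.
#' @export
readScheme <- function(file) {
  kineticScheme(readLines(file))
}

# Rate labels the user must supply for a scheme: literal reaction labels,
# minus derived outputs, plus derived inputs. Labels with declared defaults
# are optional.
.requiredRateLabels <- function(scheme) {
  lit <- unique(vapply(scheme$reactions, `[[`, "", "rate"))
  lit <- setdiff(lit, names(scheme$derived_rates))
  inputs <- unique(unlist(lapply(scheme$derived_rates, unlist), use.names = FALSE))
  all <- unique(c(lit, inputs))
  list(required = setdiff(all, names(scheme$rate_defaults)),
       optional = intersect(all, names(scheme$rate_defaults)))
}

# Expected unit class per user-facing rate label, from reaction order.
.rateUnitClasses <- function(scheme) {
  units <- character()
  for (rx in scheme$reactions) {
    u <- if (length(rx$reactants) == 2L) "M-1s-1" else "s-1"
    units[rx$rate] <- u
  }
  for (d in names(scheme$derived_rates)) {
    num <- scheme$derived_rates[[d]]$num
    den <- scheme$derived_rates[[d]]$den
    # derived = num/den; the derived label's unit is known from its reaction
    if (!num %in% names(units)) units[num] <- "s-1"
    if (!den %in% names(units)) {
      units[den] <- if (identical(units[[d]], "M-1s-1")) "M" else "1"
    }
    units <- units[setdiff(names(units), d)]
  }
  units
}
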