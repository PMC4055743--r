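#' Linear fluorescence observation model
#'
#' Stopped-flow intensity is modelled as a per-channel background plus a
#' linear combination of species concentrations:
#' `I(t) = b + sum_s c_s [s](t)`. For an intrinsic-Trp channel the
#' coefficients attach to all enzyme-containing species; for a DNA-label
#' channel to all DNA-containing species. The dual-band 3HC probe uses two
#' channels: the 395 nm long-pass channel collects the total N*+T*
#' emission, the 495 nm long-pass channel the T* band alone.
#'
#' @param channels a named list; each element is a list with `background`
#'   (a.u.) and `coef` (named numeric, a.u. per M of each emitting
#'   species). Optional fields `filter_nm` and `excitation_nm` are carried
#'   as metadata.
#' @return object of class `fluorescence_model`.
#' @examples
#' fm <- fluorescenceModel(channels = list(
#'   total_395 = list(background = 0, coef = c(S = 1.3e6, P = 1.3e6)),
#'   tstar_495 = list(background = 0, coef = c(S = 1.0e6, P = 1.0e6))))
#' @export
fluorescenceModel <- function(channels) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$background)) channels[[nm]]$background <- 0
    co <- ch$coef
    if (is.null(co) || is.null(names(co)) || !all(is.finite(co))) {
      stop("channel '", nm, "' needs finite named emission coefficients")
    }
    if (all(co == 0)) {
      stop("channel '", nm, "' must have at least one nonzero coefficient")
    }
    if (!is.finite(channels[[nm]]$background)) {
      stop("channel '", nm, "' background must be finite")
    }
  }
  structure(list(channels = channels), class = "fluorescence_model")
}

#' @export
print.fluorescence_model <- function(x, ...) {
  cat("Fluorescence model with", length(x$channels), "channel(s):\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat("  ", nm, ": background ", format(ch$background), ", species ",
        paste(names(ch$coef), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a single-channel stopped-flow trace
#'
#' @param time time grid, s.
#' @param intensity intensity, arbitrary units.
#' @param meta named list of metadata (channel, filter_nm, excitation_nm,
#'   concentrations, background, per-point noise SD `sigma`, ...).
#' @return object of class `sf_trace`.
#' @export
sfTrace <- function(time, intensity, meta = list()) {
  stopifnot(is.numeric(time), is.numeric(intensity),
            length(time) == length(intensity))
  if (any(diff(time) <= 0)) stop("trace time grid must be strictly increasing")
  structure(list(time = time, intensity = intensity, meta = meta),
            class = "sf_trace")
}

#' @export
print.sf_trace <- function(x, ...) {
  cat("Stopped-flow trace: ", length(x$time), " points, t in [",
      format(min(x$time)), ", ", format(max(x$time)), "] s",
      if (!is.null(x$meta$channel)) paste0(", channel ", x$meta$channel),
      "\n", sep = "")
  invisible(x)
}

#' Project a time course onto a fluorescence channel
#'
#' @param tc a `time_course` from [integrateScheme()].
#' @param model a [fluorescenceModel()].
#' @param channel channel name in `model`.
#' @return an [sfTrace()] with `intensity = background +
#'   sum(coef * concentration)`; metadata records the channel and its
#'   background.
#' @export
projectObservable <- function(tc, model, channel) {
  stopifnot(inherits(tc, "time_course"), inherits(model, "fluorescence_model"))
  if (!channel %in% names(model$channels)) {
    stop("unknown channel '", channel, "'")
  }
  ch <- model$channels[[channel]]
  miss <- setdiff(names(ch$coef), rownames(tc$conc))
  if (length(miss)) {
    stop("model references species absent from the time course: ",
         paste(miss, collapse = ", "))
  }
  intensity <- as.numeric(ch$background +
    crossprod(tc$conc[names(ch$coef), , drop = FALSE], ch$coef))
  sfTrace(tc$time, intensity,
          meta = list(channel = channel, background = ch$background,
                      filter_nm = ch$filter_nm,
                      excitation_nm = ch$excitation_nm))
}

#' Ratiometric N*/T* intensity statistic for dual-band ESIPT probes
#'
#' The 395 nm long-pass channel records the total N*+T* emission and the
#' 495 nm long-pass channel the T* band alone, so the band ratio at each
#' time point is `I_N*/I_T* = (I_(N*+T*) - I_T*) / I_T*`. When a channel
#' declares a background it is subtracted before the ratio is formed, so
#' the statistic is computed on signal intensities.
#'
#' @param total trace from the 395 nm (total N*+T*) channel.
#' @param tstar trace from the 495 nm (T*-only) channel.
#' @param interpolate if the two grids differ, interpolate the finer trace
#'   onto the coarser grid (default `FALSE`: mismatched grids are an
#'   error).
#' @return an [sfTrace()] holding the pointwise ratio (dimensionless).
#' @examples
#' t <- c(0.01, 0.1, 1)
#' r <- intensityRatio(sfTrace(t, c(1.3, 1.3, 1.3)), sfTrace(t, c(1, 1, 1)))
#' r$intensity # 0.3 0.3 0.3
#' @export
intensityRatio <- function(total, tstar, interpolate = FALSE) {
  stopifnot(inherits(total, "sf_trace"), inherits(tstar, "sf_trace"))
  sub_bg <- function(tr) {
    b <- tr$meta$background
    if (is.null(b)) 0 else b
  }
  if (!isTRUE(all.equal(total$time, tstar$time))) {
    if (!interpolate) {
      stop("traces are on different time grids; set interpolate = TRUE")
    }
    if (length(total$time) <= length(tstar$time)) {
      grid <- total$time
      tstar <- sfTrace(grid,
                       stats::approx(tstar$time, tstar$intensity, grid,
                                     rule = 2)$y, tstar$meta)
    } else {
      grid <- tstar$time
      total <- sfTrace(grid,
                       stats::approx(total$time, total$intensity, grid,
                                     rule = 2)$y, total$meta)
    }
  }
  it <- total$intensity - sub_bg(total)
  ts <- tstar$intensity - sub_bg(tstar)
  bad <- which(ts <= 0)
  if (length(bad)) {
    stop("non-positive T* intensity at t = ",
         format(total$time[bad[1L]]), " s; ratio undefined")
  }
  sfTrace(total$time, (it - ts) / ts,
          meta = list(channel = "ratio_NT",
                      from = c(total$meta$channel, tstar$meta$channel)))
}

#' Write / read a trace as CSV
#'
#' The dialect carries instrument metadata as `# key: value` header
#' comments followed by columns `time_s, intensity_au`.
#'
#' @param trace an [sfTrace()].
#' @param file path.
#' @return `writeTrace` returns `file` invisibly; `readTrace` returns an
#'   `sf_trace` with the header metadata restored.
#' @export
writeTrace <- function(trace, file) {
  stopifnot(inherits(trace, "sf_trace"))
  con <- file(file, "w")
  on.exit(close(con))
  meta <- trace$meta
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.null(v) || length(v) == 0L) next
    writeLines(paste0("# ", nm, ": ",
                      paste(format(v, digits = 15), collapse = " ")), con)
  }
  writeLines("time_s,intensity_au", con)
  writeLines(paste(format(trace$time, digits = 15),
                   format(trace$intensity, digits = 15), sep = ","), con)
  invisible(file)
}

#' @rdname writeTrace
#' @export
readTrace <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#[[:space:]]*([^:]+):[[:space:]]*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2L]); val <- trimws(m[3L])
      num <- suppressWarnings(as.numeric(strsplit(val, "[[:space:]]+")[[1]]))
      meta[[key]] <- if (anyNA(num)) val else num
    }
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || !identical(trimws(body[1L]), "time_s,intensity_au")) {
    stop("malformed trace file '", file, "': expected 'time_s,intensity_au' header at line ",
         sum(grepl("^#", lines)) + 1L)
  }
  df <- utils::read.csv(text = body)
  sfTrace(df$time_s, df$intensity_au, meta = meta)
}
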