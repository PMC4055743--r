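#' Options for global trace fitting
#'
#' @param start named numeric vector of starting rate constants (natural
#'   units). Defaults to the ground truth recorded in a synthetic trace
#'   set, which is convenient for recovery studies; real data must supply
#'   a start.
#' @param fix character vector of rate labels to hold fixed at their start
#'   value (the product-release `koff` is always fixed: only `KP` is
#'   treated as identifiable).
#' @param n_starts number of multi-start launches (default 16); the first
#'   start is `start` itself, the rest are a seeded Latin-hypercube draw
#'   in log10 space within `spread` decades of it (clipped to bounds).
#' @param spread half-width of the multi-start box, decades (default 2).
#' @param bounds named list `label -> c(lower, upper)` overriding the
#'   unit-class defaults (bimolecular 1e2..1e10 M^-1 s^-1, unimolecular
#'   1e-4..1e6 s^-1, dissociation constants 1e-12..1e-2 M).
#' @param weighting `"sigma"` (default): per-trace 1/sigma^2 weights when
#'   replicate scatter is recorded, else uniform; `"uniform"`: unweighted.
#' @param channel_species named list `channel -> species` receiving free
#'   emission coefficients. Default: the conservation group (enzyme or
#'   DNA moiety) matching the generating model's channel, which adapts
#'   automatically when a different scheme variant is fitted.
#' @param n_hops greedy basin-hop attempts per start after the first LM
#'   convergence (jitter of +/- 0.3 decades, keep if improved, stop after
#'   two consecutive failures; default 4).
#' @param seed RNG seed for the multi-start draw and basin hops.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param dead_time samples earlier than this are excluded from the
#'   objective (s; default 1.4e-3).
#' @return list of class `fit_options`.
#' @export
fitOptions <- function(start = NULL, fix = character(), n_starts = 16L,
                       spread = 2, bounds = NULL,
                       weighting = c("sigma", "uniform"),
                       channel_species = NULL, n_hops = 4L, seed = 1L,
                       maxiter = 200L, dead_time = 1.4e-3) {
  structure(list(start = start, fix = fix, n_starts = as.integer(n_starts),
                 spread = spread, bounds = bounds,
                 weighting = match.arg(weighting),
                 channel_species = channel_species, n_hops = as.integer(n_hops),
                 seed = as.integer(seed),
                 maxiter = as.integer(maxiter), dead_time = dead_time),
            class = "fit_options")
}

.defaultBounds <- function(scheme) {
  units <- .rateUnitClasses(scheme)
  out <- list()
  for (nm in names(units)) {
    out[[nm]] <- switch(units[[nm]],
                        "M-1s-1" = c(1e2, 1e10),
                        "s-1" = c(1e-4, 1e6),
                        "M" = c(1e-12, 1e-2),
                        c(1e-4, 1e10))
  }
  out
}

# Channel -> species map: emitting moiety inferred from a reference
# coefficient set (enzyme moiety if it covers free E, else DNA moiety),
# expressed as the fitted scheme's matching conservation group (plus free
# product for the DNA moiety, which the group already contains).
.channelSpecies <- function(scheme, fmodel) {
  grp_of <- function(sp) {
    for (g in scheme$conservation) if (sp %in% g) return(g)
    stop("scheme has no conservation group containing '", sp, "'")
  }
  out <- list()
  for (ch in names(fmodel$channels)) {
    ref <- names(fmodel$channels[[ch]]$coef)
    out[[ch]] <- if ("E" %in% ref) grp_of("E") else grp_of("S")
  }
  out
}

# Assemble the weighted-residual closure shared by all starts. Kinetic
# parameters live in log10 space; observation parameters (per-channel
# emission coefficients and background) are linear. ODE solutions are
# cached on the kinetic sub-vector so coefficient perturbations during
# numeric differentiation do not trigger new integrations.
.makeObjective <- function(ts, scheme, free_kin, fixed_kin, chspecies,
                           weighting, dead_time) {
  keep_tr <- vapply(ts$traces, function(tr) any(tr$time >= dead_time),
                    logical(1L))
  traces <- ts$traces[keep_tr]
  cond_key <- vapply(traces, function(tr) {
    paste(format(tr$meta$E0_active, digits = 15),
          format(tr$meta$S0, digits = 15))
  }, character(1L))
  conds <- unique(cond_key)
  cond_info <- lapply(conds, function(k) {
    idx <- which(cond_key == k)
    grid <- sort(unique(unlist(lapply(traces[idx], function(tr) {
      tr$time[tr$time >= dead_time]
    }))))
    list(idx = idx,
         E0 = traces[[idx[1L]]]$meta$E0_active,
         S0 = traces[[idx[1L]]]$meta$S0,
         grid = grid)
  })
  sig <- vapply(traces, function(tr) {
    s <- tr$meta$sigma
    if (is.null(s) || !is.finite(s) || s <= 0) NA_real_ else s
  }, numeric(1L))
  w <- if (weighting == "sigma" && !anyNA(sig)) 1 / sig
       else rep(1, length(traces))

  obs_template <- list()
  for (ch in names(chspecies)) {
    obs_template[[paste0("b.", ch)]] <- 0
    for (sp in chspecies[[ch]]) obs_template[[paste0("c.", ch, ".", sp)]] <- 0
  }
  obs_names <- names(obs_template)

  cache <- new.env(parent = emptyenv())
  solve_conds <- function(kin) {
    key <- paste(format(kin, digits = 17), collapse = ",")
    hit <- cache$key
    if (identical(hit, key)) return(cache$sol)
    full <- c(kin, fixed_kin)
    sol <- lapply(cond_info, function(ci) {
      tc <- integrateScheme(scheme, rateParams(full),
                            initialConditions(ci$E0, ci$S0),
                            times = ci$grid, check_conservation = FALSE,
                            negative_floor = 1e-9)
      tc$conc[, tc$time %in% ci$grid, drop = FALSE]
    })
    cache$key <- key
    cache$sol <- sol
    sol
  }

  predict_all <- function(kin, obs) {
    sol <- solve_conds(kin)
    preds <- vector("list", length(traces))
    for (ci_i in seq_along(cond_info)) {
      ci <- cond_info[[ci_i]]
      conc <- sol[[ci_i]]
      for (ti in ci$idx) {
        tr <- traces[[ti]]
        ch <- tr$meta$channel
        sel <- tr$time >= dead_time
        cols <- match(tr$time[sel], ci$grid)
        sp <- chspecies[[ch]]
        cf <- obs[paste0("c.", ch, ".", sp)]
        preds[[ti]] <- obs[[paste0("b.", ch)]] +
          as.numeric(crossprod(conc[sp, cols, drop = FALSE], cf))
      }
    }
    preds
  }

  n_points_all <- sum(vapply(traces, function(tr) sum(tr$time >= dead_time),
                             integer(1L)))
  # integration failures on wild parameter excursions return a large
  # finite penalty so Levenberg-Marquardt backs off instead of aborting
  penalty <- rep(1e4, n_points_all)

  resid_fun <- function(par) {
    tryCatch({
      kin <- 10^par[free_kin]
      names(kin) <- free_kin
      obs <- par[obs_names]
      preds <- predict_all(kin, obs)
      unlist(lapply(seq_along(traces), function(ti) {
        tr <- traces[[ti]]
        sel <- tr$time >= dead_time
        w[ti] * (tr$intensity[sel] - preds[[ti]])
      }), use.names = FALSE)
    }, error = function(e) penalty)
  }

  # weighted linear least squares for the observation parameters at fixed
  # kinetics: exact profile solution of the linear sub-problem
  profile_obs <- function(kin) {
    sol <- solve_conds(kin)
    obs <- unlist(obs_template)
    for (ch in names(chspecies)) {
      sp <- chspecies[[ch]]
      X <- NULL; yy <- NULL
      for (ci_i in seq_along(cond_info)) {
        ci <- cond_info[[ci_i]]
        for (ti in ci$idx) {
          tr <- traces[[ti]]
          if (!identical(tr$meta$channel, ch)) next
          sel <- tr$time >= dead_time
          cols <- match(tr$time[sel], ci$grid)
          X <- rbind(X, w[ti] * cbind(1, t(sol[[ci_i]][sp, cols,
                                                       drop = FALSE])))
          yy <- c(yy, w[ti] * tr$intensity[sel])
        }
      }
      if (is.null(X)) next
      # min-norm solution: when every species of a conserved moiety is in
      # the channel and the conserved total is the same in all conditions,
      # the intercept and the group coefficients are exactly collinear;
      # the pseudo-inverse picks the (prediction-equivalent) minimum-norm
      # representative instead of failing
      cs <- sqrt(colSums(X^2))
      cs[cs == 0] <- 1
      Xs <- sweep(X, 2L, cs, "/")
      beta <- stats::lm.fit(Xs, yy)$coefficients
      beta[is.na(beta)] <- 0 # aliased direction (conserved-total collinearity)
      beta <- beta / cs
      obs[paste0("b.", ch)] <- beta[1L]
      obs[paste0("c.", ch, ".", sp)] <- beta[-1L]
    }
    obs
  }

  # kinetic-only residual with the linear parameters projected out
  # (variable projection); same objective, far better conditioned
  resid_kin <- function(kin_log) {
    tryCatch({
      kin <- 10^kin_log
      names(kin) <- free_kin
      obs <- profile_obs(kin)
      preds <- predict_all(kin, obs)
      unlist(lapply(seq_along(traces), function(ti) {
        tr <- traces[[ti]]
        sel <- tr$time >= dead_time
        w[ti] * (tr$intensity[sel] - preds[[ti]])
      }), use.names = FALSE)
    }, error = function(e) penalty)
  }

  n_points <- sum(vapply(traces, function(tr) sum(tr$time >= dead_time),
                         integer(1L)))
  list(resid = resid_fun, resid_kin = resid_kin, profile_obs = profile_obs,
       obs_names = obs_names, traces = traces, weights = w,
       n_points = n_points, sigma = sig, dead_time = dead_time)
}

#' Global fit of rate constants to a stopped-flow trace set
#'
#' Minimises the summed (optionally 1/sigma-weighted) squared residuals
#' over all traces simultaneously: rate constants are shared across mixing
#' conditions and emission coefficients are shared per channel, exactly as
#' in a global analysis of a concentration series. Optimisation runs in
#' log10 space for the kinetic parameters with multi-start
#' Levenberg-Marquardt; emission coefficients and backgrounds are free
#' linear parameters, initialised by linear least squares at each start.
#'
#' @param ts a `trace_set` ([generateTraceSet()] or [readTraceSet()]).
#' @param scheme a [kineticScheme()] or built-in scheme id.
#' @param options a [fitOptions()] list.
#' @return object of class `fit_result`: point estimates and asymptotic
#'   standard errors for every free rate constant (natural units, delta
#'   method from the log10 fit), emission coefficients and backgrounds per
#'   channel, weighted RSS, reduced chi-square (when per-trace noise SDs
#'   are known), AIC ingredients (`n`, `p`), convergence status, per-start
#'   RSS table, the seed, and bounds-hit flags.
#' @export
fitGlobal <- function(ts, scheme, options = fitOptions()) {
  if (is.character(scheme)) scheme <- kineticScheme(scheme)
  stopifnot(inherits(ts, "trace_set"), inherits(options, "fit_options"))
  if (!length(ts$traces)) stop("trace set is empty")

  nconc <- length(unique(vapply(ts$traces, function(tr)
    paste(tr$meta$E0_nominal, tr$meta$S0), character(1L))))
  if (nconc < 2L) {
    warning("single mixing condition: rate constants may be poorly identifiable")
  }

  start <- options$start
  if (is.null(start)) {
    if (is.null(ts$truth)) {
      stop("no start supplied and the trace set records no generating truth")
    }
    start <- stats::setNames(as.numeric(ts$truth$params),
                             names(ts$truth$params))
  }
  start <- validateParams(scheme, rateParams(start), strict = FALSE)
  start <- stats::setNames(as.numeric(start), names(start))

  labs <- .requiredRateLabels(scheme)
  fix <- unique(c(options$fix, labs$optional)) # koff etc. always fixed
  free_kin <- setdiff(c(labs$required), fix)
  fixed_kin <- start[intersect(names(start), fix)]

  chspecies <- options$channel_species
  if (is.null(chspecies)) {
    if (is.null(ts$truth) || is.null(ts$truth$fmodel)) {
      stop("supply options$channel_species for trace sets without a recorded truth model")
    }
    chspecies <- .channelSpecies(scheme, ts$truth$fmodel)
  }
  used_ch <- unique(vapply(ts$traces, function(tr) tr$meta$channel,
                           character(1L)))
  chspecies <- chspecies[intersect(names(chspecies), used_ch)]
  if (!length(chspecies)) stop("no channel/species mapping for the traces")

  obj <- .makeObjective(ts, scheme, free_kin, fixed_kin, chspecies,
                        options$weighting, options$dead_time)

  bounds <- .defaultBounds(scheme)
  if (!is.null(options$bounds)) bounds[names(options$bounds)] <- options$bounds
  lo_kin <- log10(vapply(free_kin, function(nm) bounds[[nm]][1L], numeric(1L)))
  hi_kin <- log10(vapply(free_kin, function(nm) bounds[[nm]][2L], numeric(1L)))

  start_log <- pmin(pmax(log10(start[free_kin]), lo_kin), hi_kin)
  set.seed(options$seed)
  starts <- matrix(rep(start_log, each = options$n_starts),
                   nrow = options$n_starts,
                   dimnames = list(NULL, free_kin))
  if (options$n_starts > 1L) {
    u <- lhs::randomLHS(options$n_starts - 1L, length(free_kin))
    box_lo <- pmax(start_log - options$spread, lo_kin)
    box_hi <- pmin(start_log + options$spread, hi_kin)
    starts[-1L, ] <- sweep(sweep(u, 2L, box_hi - box_lo, "*"), 2L, box_lo, "+")
  }

  # epsfcn sets the forward-difference step to ~1e-4 of each parameter:
  # large enough that Jacobian columns of weakly sensitive rate constants
  # are not dominated by the adaptive ODE solver's O(rtol) noise
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$maxiter,
                                     ftol = 1e-12, ptol = 1e-12,
                                     epsfcn = 1e-8)
  lower <- c(lo_kin, rep(-Inf, length(obj$obs_names)))
  upper <- c(hi_kin, rep(Inf, length(obj$obs_names)))

  # One launch: Levenberg-Marquardt on the variable-projection residual
  # (linear emission parameters solved exactly at every kinetic step),
  # followed by greedy basin hops (jitter the kinetic log-parameters,
  # re-run LM, keep improvements) to escape the correlated-rate local
  # minima endemic to multi-step schemes, then a joint polish over all
  # parameters so the reported estimates, RSS and standard errors come
  # from the full joint problem.
  launch <- function(kin_log) {
    run_vp <- function(kl) {
      minpack.lm::nls.lm(kl, lower = lo_kin, upper = hi_kin,
                         fn = obj$resid_kin, control = ctrl)
    }
    vp <- run_vp(kin_log)
    hops <- options$n_hops
    fails <- 0L
    while (hops > 0L && fails < 3L) {
      cand <- pmin(pmax(vp$par + stats::runif(length(vp$par), -0.5, 0.5),
                        lo_kin), hi_kin)
      trial <- tryCatch(run_vp(cand), error = function(e) NULL)
      if (!is.null(trial) && trial$deviance < vp$deviance * (1 - 1e-6)) {
        vp <- trial
        fails <- 0L
      } else {
        fails <- fails + 1L
      }
      hops <- hops - 1L
    }
    kin1 <- 10^vp$par
    names(kin1) <- free_kin
    par1 <- c(vp$par, obj$profile_obs(kin1))
    names(par1)[seq_along(free_kin)] <- free_kin
    fit <- minpack.lm::nls.lm(par1, lower = lower, upper = upper,
                              fn = obj$resid, control = ctrl)
    if (fit$deviance > vp$deviance * (1 + 1e-10)) {
      # joint polish should never worsen; keep the projected optimum
      fit <- minpack.lm::nls.lm(par1, lower = lower, upper = upper,
                                fn = obj$resid,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 1))
    }
    fit
  }
  runs <- vector("list", options$n_starts)
  for (s in seq_len(options$n_starts)) {
    runs[[s]] <- tryCatch(launch(starts[s, ]), error = function(e) e)
  }
  ok <- vapply(runs, function(f) inherits(f, "nls.lm"), logical(1L))
  if (!any(ok)) {
    stop("all ", options$n_starts, " starts failed: ",
         conditionMessage(runs[[1L]]))
  }
  rss_all <- vapply(runs, function(f) {
    if (inherits(f, "nls.lm")) f$deviance else Inf
  }, numeric(1L))
  best <- which.min(rss_all)
  fit <- runs[[best]]

  est_log <- fit$par[free_kin]
  estimates <- 10^est_log
  se_nat <- rep(NA_real_, length(free_kin))
  obs_se <- rep(NA_real_, length(obj$obs_names))
  se_ok <- TRUE
  covm <- tryCatch({
    sm <- summary(fit)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) NULL)
  if (is.null(covm)) {
    se_ok <- FALSE
  } else {
    se_log <- covm[seq_along(free_kin)]
    se_nat <- log(10) * estimates * se_log
    obs_se <- covm[-seq_along(free_kin)]
  }
  names(estimates) <- free_kin
  names(se_nat) <- free_kin

  rss <- fit$deviance
  n <- obj$n_points
  p <- length(fit$par)
  chisq_red <- if (options$weighting == "sigma" && !anyNA(obj$sigma)) {
    rss / (n - p)
  } else if (!anyNA(obj$sigma)) {
    res <- obj$resid(fit$par)
    idx <- rep(seq_along(obj$traces), vapply(obj$traces, function(tr)
      sum(tr$time >= obj$dead_time), integer(1L)))
    sum((res / obj$sigma[idx])^2) / (n - p)
  } else {
    NA_real_
  }

  hit <- (abs(est_log - lo_kin) < 1e-8) | (abs(est_log - hi_kin) < 1e-8)
  names(hit) <- free_kin

  per_trace <- {
    res <- obj$resid(fit$par)
    lens <- vapply(obj$traces, function(tr) sum(tr$time >= obj$dead_time),
                   integer(1L))
    split_idx <- rep(seq_along(lens), lens)
    data.frame(
      trace = seq_along(lens),
      channel = vapply(obj$traces, function(tr) tr$meta$channel, character(1L)),
      n = lens,
      rss = as.numeric(tapply((res)^2, split_idx, sum))
    )
  }

  structure(list(
    scheme = scheme$name,
    estimates = estimates,
    se = se_nat,
    fixed = fixed_kin,
    obs = stats::setNames(fit$par[obj$obs_names], obj$obs_names),
    obs_se = stats::setNames(obs_se, obj$obs_names),
    rss = rss,
    chisq_red = chisq_red,
    n = n,
    p = p,
    converged = fit$info %in% 1:4,
    message = fit$message,
    niter = fit$niter,
    se_available = se_ok,
    bounds_hit = hit,
    start = start,
    starts_rss = data.frame(start = seq_along(rss_all), rss = rss_all,
                            converged = ok),
    best_start = best,
    seed = options$seed,
    weighting = options$weighting,
    per_trace = per_trace
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Global fit, scheme '", x$scheme, "': ", x$n, " points, ", x$p,
      " free parameters, ", if (x$converged) "converged" else "NOT converged",
      "\n", sep = "")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    se = signif(x$se, 3),
                    at_bound = x$bounds_hit)
  print(tab)
  cat("weighted RSS:", format(x$rss),
      " reduced chi-square:", format(x$chisq_red), "\n")
  invisible(x)
}

#' Akaike information criterion of a fit
#'
#' `AIC = n log(RSS/n) + 2p`, comparable across schemes fitted to the same
#' trace set with the same weighting.
#'
#' @param result a `fit_result`.
#' @return numeric AIC value.
#' @export
aicOf <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  result$n * log(result$rss / result$n) + 2 * result$p
}

#' Compare mechanism variants on one trace set
#'
#' Fits every scheme to the same traces, ranks them by
#' `AIC = n log(RSS/n) + 2p`, and, for nested pairs (one scheme's rate
#' labels a subset of the other's), reports the extra-sum-of-squares F
#' statistic and p-value.
#'
#' @param ts a `trace_set`.
#' @param schemes list of schemes or built-in ids (>= 2).
#' @param options a single [fitOptions()] shared by all fits, or a named
#'   list of per-scheme options.
#' @return object of class `model_comparison`: `table` (scheme, rss, n, p,
#'   aic, daic; the best model has `daic = 0`), `ftests` (nested pairs),
#'   `fits` (per-scheme `fit_result` or the error that felled it).
#' @export
compareModels <- function(ts, schemes, options = fitOptions()) {
  stopifnot(length(schemes) >= 2L)
  schemes <- lapply(schemes, function(s) {
    if (is.character(s)) kineticScheme(s) else s
  })
  ids <- vapply(schemes, function(s) s$name, character(1L))
  labsets <- lapply(schemes, function(s) .requiredRateLabels(s)$required)
  fits <- vector("list", length(schemes))
  # fit small models first so larger nested ones can be warm-started from
  # the reduced optimum (extra steps initialised effectively off), making
  # the nested comparison a fair race: the full model starts at the
  # reduced model's RSS and can only genuinely improve on it
  ord <- order(vapply(labsets, length, integer(1L)))
  for (i in ord) {
    opt <- if (inherits(options, "fit_options")) options
           else if (ids[i] %in% names(options)) options[[ids[i]]]
           else stop("no fit options for scheme '", ids[i], "'")
    need <- labsets[[i]]
    st <- opt$start
    if (is.null(st) && !is.null(ts$truth)) {
      st <- stats::setNames(as.numeric(ts$truth$params),
                            names(ts$truth$params))
    }
    # extra steps of a larger scheme start switched off: forward rate at
    # the lower bound, reverse partners (k_*) at a moderate 1 per second,
    # so the larger model's start reproduces the smaller model's fit
    off_values <- function(labels) {
      stats::setNames(ifelse(grepl("^k_", labels), 1.0, 1e-4), labels)
    }
    missing_labs <- setdiff(need, names(st))
    if (length(missing_labs)) st <- c(st, off_values(missing_labs))
    cand_starts <- list(st)
    for (j in seq_along(schemes)) {
      if (j == i || !inherits(fits[[j]], "fit_result")) next
      if (all(labsets[[j]] %in% need) && length(need) > length(labsets[[j]])) {
        warm <- c(fits[[j]]$estimates, fits[[j]]$fixed)
        extra <- setdiff(need, names(warm))
        warm <- c(warm, off_values(extra))
        cand_starts <- c(cand_starts, list(warm))
      }
    }
    best <- NULL
    for (cs in cand_starts) {
      opt2 <- opt
      opt2$start <- cs
      f <- tryCatch(fitGlobal(ts, schemes[[i]], opt2), error = function(e) e)
      if (inherits(f, "fit_result") &&
          (is.null(best) || !inherits(best, "fit_result") ||
           f$rss < best$rss)) {
        best <- f
      } else if (is.null(best)) {
        best <- f
      }
    }
    fits[[i]] <- best
  }
  names(fits) <- make.unique(ids)
  okf <- vapply(fits, inherits, logical(1L), "fit_result")
  if (!any(okf)) stop("every scheme failed to fit")
  tab <- data.frame(
    scheme = ids[okf],
    rss = vapply(fits[okf], `[[`, numeric(1L), "rss"),
    n = vapply(fits[okf], `[[`, numeric(1L), "n"),
    p = vapply(fits[okf], `[[`, numeric(1L), "p"),
    row.names = NULL
  )
  tab$aic <- tab$n * log(tab$rss / tab$n) + 2 * tab$p
  tab$daic <- tab$aic - min(tab$aic)

  ftests <- list()
  oki <- which(okf)
  if (length(oki) >= 2L) {
    for (a in seq_along(oki)) for (b in seq_along(oki)) {
      if (a == b) next
      sa <- schemes[[oki[a]]]; sb <- schemes[[oki[b]]]
      la <- .requiredRateLabels(sa)$required
      lb <- .requiredRateLabels(sb)$required
      if (all(la %in% lb) && length(lb) > length(la)) {
        fa <- fits[[oki[a]]]; fb <- fits[[oki[b]]] # a nested in b
        dfn <- fb$p - fa$p
        dfd <- fb$n - fb$p
        Fv <- ((fa$rss - fb$rss) / dfn) / (fb$rss / dfd)
        ftests[[paste(sa$name, "vs", sb$name)]] <- list(
          reduced = sa$name, full = sb$name, F = Fv, df1 = dfn, df2 = dfd,
          p_value = stats::pf(max(Fv, 0), dfn, dfd, lower.tail = FALSE))
      }
    }
  }
  structure(list(table = tab, ftests = ftests, fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (AIC = n log(RSS/n) + 2p):\n")
  print(x$table, row.names = FALSE)
  for (nm in names(x$ftests)) {
    ft <- x$ftests[[nm]]
    cat(sprintf("  F-test %s: F(%d,%d) = %.3g, p = %.3g\n",
                nm, ft$df1, ft$df2, ft$F, ft$p_value))
  }
  invisible(x)
}

#' Cross-fluorophore rate-constant ratios
#'
#' Computes the derived comparisons between reporters: how much faster the
#' DNA probe sees the initial binding than the protein does
#' (`k1(label)/k1(reference)`), and how the second-step and catalytic rate
#' constants seen through the reference compare to each label
#' (`k2(reference)/k2(label)`, `kcat(reference)/kcat(label)`).
#'
#' @param results named list mapping fluorophore label to a
#'   [rateParams()] object or a `fit_result`.
#' @param reference the reference label (default `"Trp"`, the intrinsic
#'   enzyme channel).
#' @return data frame of class `ratio_report` with columns `ratio`,
#'   `constant`, `numerator`, `denominator`, `value`.
#' @examples
#' derivedQuantities(list(Trp = neiRateConstants("Trp"),
#'                        `3HC` = neiRateConstants("3HC")))
#' @export
derivedQuantities <- function(results, reference = "Trp") {
  if (!reference %in% names(results)) {
    stop("reference label '", reference, "' absent from results")
  }
  getk <- function(label, const) {
    r <- results[[label]]
    v <- if (inherits(r, "fit_result")) {
      c(r$estimates, r$fixed)[const]
    } else {
      stats::setNames(as.numeric(r), names(r))[const]
    }
    if (is.na(v)) stop("missing constant '", const, "' for label '", label, "'")
    unname(v)
  }
  rows <- list()
  for (label in setdiff(names(results), reference)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = sprintf("k1(%s)/k1(%s)", label, reference),
      constant = "k1", numerator = label, denominator = reference,
      value = getk(label, "k1") / getk(reference, "k1"))
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = sprintf("k2(%s)/k2(%s)", reference, label),
      constant = "k2", numerator = reference, denominator = label,
      value = getk(reference, "k2") / getk(label, "k2"))
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = sprintf("kcat(%s)/kcat(%s)", reference, label),
      constant = "kcat", numerator = reference, denominator = label,
      value = getk(reference, "kcat") / getk(label, "kcat"))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ratio_report", class(out))
  out
}
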