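test_that("single-step binding matches the exact and pseudo-first-order closed forms", {
  sc <- one_step_scheme()
  k1 <- 1e7; km1 <- 5
  run <- function(E0, S0) {
    integrateScheme(sc, rateParams(k1 = k1, k_1 = km1),
                    initialConditions(E0, S0),
                    times = logTimeGrid(1e-5, 1, 200),
                    rtol = 1e-10, atol = 1e-16)
  }
  # exact solution of the bimolecular binding ODE: with x = [ES],
  # dx/dt = k1 (x - x+)(x - x-), x(t) = x+ x- (1 - e^-theta t) /
  # (x+ - x- e^-theta t), theta = k1 (x+ - x-)
  exact <- function(t, E0, S0) {
    Kd <- km1 / k1
    b <- E0 + S0 + Kd
    xp <- (b + sqrt(b^2 - 4 * E0 * S0)) / 2
    xm <- (b - sqrt(b^2 - 4 * E0 * S0)) / 2
    th <- k1 * (xp - xm)
    xp * xm * (1 - exp(-th * t)) / (xp - xm * exp(-th * t))
  }
  E0 <- 10e-6; S0 <- 0.1e-6
  tc <- run(E0, S0)
  ex <- exact(tc$time, E0, S0)
  expect_lt(max(abs(tc$conc["ES", ] - ex) / pmax(ex, 1e-3 * max(ex))), 1e-5)

  # pseudo-first-order limit: at a 1000-fold enzyme excess the exponential
  # relaxation form holds pointwise to 1e-3
  S0 <- 0.01e-6
  tc2 <- run(E0, S0)
  kobs <- k1 * E0 + km1
  pfo <- S0 * (k1 * E0 / kobs) * (1 - exp(-kobs * tc2$time))
  expect_lt(max(abs(tc2$conc["ES", ] - pfo) /
                  pmax(pfo, 1e-3 * max(pfo))), 1e-3)
})

test_that("with catalysis disabled the long-time state satisfies every step equilibrium", {
  # three sequential binding equilibria and no chemistry: detailed balance
  # fixes [ES1]/([E][S]) = k1/k_1 and the two isomerisation ratios
  sc <- kineticScheme(c("!name equil3",
                        "E + S <-> ES1 : k1/k_1",
                        "ES1 <-> ES2 : k2/k_2",
                        "ES2 <-> ES3 : k3/k_3"))
  p <- rateParams(k1 = 5e6, k_1 = 10, k2 = 4, k_2 = 2, k3 = 0.5, k_3 = 1)
  tc <- integrateScheme(sc, p, initialConditions(2e-6, 1e-6),
                        times = logTimeGrid(1e-3, 1e4, 300),
                        rtol = 1e-10, atol = 1e-16)
  last <- tc$conc[, ncol(tc$conc)]
  expect_equal(last[["ES1"]] / (last[["E"]] * last[["S"]]), 5e6 / 10,
               tolerance = 1e-6)
  expect_equal(last[["ES2"]] / last[["ES1"]], 4 / 2, tolerance = 1e-6)
  expect_equal(last[["ES3"]] / last[["ES2"]], 0.5 / 1, tolerance = 1e-6)
})

test_that("enzyme and DNA totals are conserved at every grid point", {
  sc <- kineticScheme("nei5")
  tc <- integrateScheme(sc, neiRateConstants("Trp"),
                        initialConditions(2e-6, 2e-6))
  etot <- colSums(tc$conc[c("E", "ES1", "ES2", "ES3", "EP"), ])
  dtot <- colSums(tc$conc[c("S", "ES1", "ES2", "ES3", "EP", "P"), ])
  expect_lt(max(abs(etot - 2e-6)) / 2e-6, 1e-6)
  expect_lt(max(abs(dtot - 2e-6)) / 2e-6, 1e-6)
})

test_that("interpolated argmax agrees with a dense-grid oracle and flags boundary maxima", {
  sc <- kineticScheme("nei5")
  p <- neiRateConstants("Trp")
  init <- initialConditions(2e-6, 2e-6)
  coarse <- integrateScheme(sc, p, init, times = logTimeGrid(n = 200L))
  dense <- integrateScheme(sc, p, init, times = logTimeGrid(n = 2000L))
  for (sp in c("ES1", "ES2", "ES3")) {
    tm <- timeOfMax(coarse, sp)
    expect_false(tm$boundary)
    dense_t <- dense$time[which.max(dense$conc[sp, ])]
    i <- findInterval(tm$time, coarse$time)
    spacing <- coarse$time[min(i + 1, length(coarse$time))] - coarse$time[i]
    expect_lt(abs(tm$time - dense_t), spacing)
  }
  # free product accumulates monotonically in a cleavable run
  expect_true(timeOfMax(coarse, "P")$boundary)
  expect_error(timeOfMax(coarse, "ES9"), "not present")
})

test_that("reported times of maximum are stable under solver-tolerance refinement", {
  sc <- kineticScheme("nei5")
  p <- neiRateConstants("Trp")
  init <- initialConditions(2e-6, 2e-6)
  a <- integrateScheme(sc, p, init)
  b <- integrateScheme(sc, p, init, rtol = 5e-9, atol = 5e-13)
  for (sp in c("ES1", "ES2", "ES3")) {
    ta <- timeOfMax(a, sp)$time
    tb <- timeOfMax(b, sp)$time
    expect_lt(abs(ta - tb) / ta, 0.01)
  }
})
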