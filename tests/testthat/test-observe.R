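test_that("projection is the declared background-plus-linear-combination and is linear", {
  sc <- kineticScheme("nei5")
  tc <- integrateScheme(sc, neiRateConstants("Trp"),
                        initialConditions(2e-6, 2e-6),
                        times = logTimeGrid(n = 50L))
  # identity projection: unit coefficient on one species, no background
  fm1 <- fluorescenceModel(list(ch = list(background = 0, coef = c(ES2 = 1))))
  tr1 <- projectObservable(tc, fm1, "ch")
  expect_equal(tr1$intensity, unname(tc$conc["ES2", ]))

  # two-species weighted sum checked by hand at three grid points
  fm2 <- fluorescenceModel(list(ch = list(background = 0.2,
                                          coef = c(ES1 = 1, ES2 = 0.5))))
  tr2 <- projectObservable(tc, fm2, "ch")
  for (i in c(5L, 20L, 40L)) {
    expect_equal(tr2$intensity[i],
                 unname(0.2 + 1 * tc$conc["ES1", i] +
                          0.5 * tc$conc["ES2", i]))
  }

  # linearity: project(a*m1 + b*m2) = a*project(m1) + b*project(m2)
  a <- 2.5; b <- -0.75
  fm3 <- fluorescenceModel(list(ch = list(
    background = a * 0 + b * 0.2,
    coef = c(ES1 = b * 1, ES2 = a * 1 + b * 0.5))))
  tr3 <- projectObservable(tc, fm3, "ch")
  expect_equal(tr3$intensity, a * tr1$intensity + b * tr2$intensity)

  expect_error(projectObservable(tc, fm1, "nope"), "unknown channel")
  expect_error(fluorescenceModel(list(ch = list(coef = c(ES1 = 0)))),
               "nonzero")
})

test_that("the dual-band ratio is (total - tstar)/tstar on background-subtracted signal", {
  t <- c(0.01, 0.1, 1, 10)
  # duplex baseline regime: total = 1.3, T* = 1.0 -> ratio 0.3
  r <- intensityRatio(sfTrace(t, rep(1.3, 4)), sfTrace(t, rep(1, 4)))
  expect_equal(r$intensity, rep(0.3, 4))
  # total = 2 T* -> ratio 1 everywhere
  r2 <- intensityRatio(sfTrace(t, 2 * (1:4)), sfTrace(t, as.numeric(1:4)))
  expect_equal(r2$intensity, rep(1, 4))
  # declared backgrounds are removed before the ratio is formed
  r3 <- intensityRatio(
    sfTrace(t, rep(1.3, 4) + 0.2, meta = list(background = 0.2)),
    sfTrace(t, rep(1.0, 4) + 0.1, meta = list(background = 0.1)))
  expect_equal(r3$intensity, rep(0.3, 4))

  # division guard names the offending time point
  expect_error(
    intensityRatio(sfTrace(t, rep(1.3, 4)), sfTrace(t, c(1, 0, 1, 1))),
    "0.1")
  # grids must match unless interpolation is requested
  t2 <- c(0.01, 0.5, 10)
  expect_error(intensityRatio(sfTrace(t, rep(1.3, 4)),
                              sfTrace(t2, rep(1, 3))), "interpolate")
  r4 <- intensityRatio(sfTrace(t, rep(1.3, 4)), sfTrace(t2, rep(1, 3)),
                       interpolate = TRUE)
  expect_length(r4$intensity, 3L) # coarser grid wins
  expect_equal(r4$intensity, rep(0.3, 3))
})

test_that("trace CSV dialect round-trips data and instrument metadata", {
  tr <- sfTrace(c(0.0014, 0.01, 0.1), c(1.25, 1.5, 1.75),
                meta = list(channel = "total_395", filter_nm = 395,
                            excitation_nm = 375, E0_nominal = 2e-6))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, f)
  back <- readTrace(f)
  expect_equal(back$time, tr$time)
  expect_equal(back$intensity, tr$intensity)
  expect_identical(back$meta$channel, "total_395")
  expect_equal(back$meta$filter_nm, 395)
  expect_equal(back$meta$E0_nominal, 2e-6)

  writeLines(c("# channel: x", "bad,header", "1,2"), f)
  expect_error(readTrace(f), "malformed")
})
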