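test_that("noiseless single-replicate generation equals the projection exactly", {
  pre <- neiPresets("Trp")
  design <- small_design("Trp", E0 = 2e-6, S0 = 1e-6,
                         replicates = 1, noise_frac = 0)
  ts <- generateTraceSet(pre$scheme, pre$params, pre$fmodel, design, seed = 1)
  expect_length(ts$traces, 1L)
  tc <- integrateScheme(kineticScheme("nei5"), pre$params,
                        initialConditions(2e-6 * 0.8, 1e-6),
                        times = sfkin:::.designGrid(design))
  clean <- projectObservable(tc, pre$fmodel, "em_320")
  keep <- clean$time >= design$dead_time
  expect_identical(ts$traces[[1]]$intensity, clean$intensity[keep])
})

test_that("no sample precedes the instrument dead time", {
  ts <- small_trace_set("3HC")
  for (tr in ts$traces) expect_gte(min(tr$time), 1.4e-3)
})

test_that("generation is bit-identical under a fixed seed and differs otherwise", {
  a <- small_trace_set("Trp", seed = 7)
  b <- small_trace_set("Trp", seed = 7)
  expect_identical(a, b)
  c <- small_trace_set("Trp", seed = 8)
  expect_false(identical(a$traces[[1]]$intensity, c$traces[[1]]$intensity))
})

test_that("averaging four replicates halves the noise SD", {
  pre <- neiPresets("Trp")
  design <- small_design("Trp", E0 = 2e-6, samples_per_decade = 300,
                         replicates = 4, noise_frac = 0.02)
  ts <- generateTraceSet(pre$scheme, pre$params, pre$fmodel, design, seed = 3)
  tc <- integrateScheme(kineticScheme("nei5"), pre$params,
                        initialConditions(2e-6 * 0.8, 1e-6),
                        times = sfkin:::.designGrid(design))
  clean <- projectObservable(tc, pre$fmodel, "em_320")
  keep <- clean$time >= design$dead_time
  resid <- ts$traces[[1]]$intensity - clean$intensity[keep]
  expect_gte(length(resid), 1000L)
  expected_sd <- 0.02 * diff(range(clean$intensity[keep])) / 2 # 1/sqrt(4)
  expect_lt(abs(sd(resid) - expected_sd) / expected_sd, 0.20)
})

test_that("published presets bind the right scheme, constants and optics", {
  trp <- neiPresets("Trp")
  expect_identical(trp$scheme, "nei5")
  expect_equal(trp$params[["k1"]], 10.5e6)
  expect_equal(trp$params[["kcat"]], 0.056)
  expect_equal(trp$params[["KP"]], 6.5e-6)
  expect_identical(trp$design$excitation_nm, 290)

  hc <- neiPresets("3HC")
  expect_identical(hc$scheme, "nei5")
  expect_equal(hc$params[["KP"]], 0.16e-6)
  expect_setequal(hc$design$channels, c("total_395", "tstar_495"))

  tco <- neiPresets("tCO")
  expect_identical(tco$scheme, "nei4")
  expect_false("k3" %in% names(tco$params))

  expect_error(neiPresets("aPu"), "no fitted rate constants")
  expect_error(neiRateConstants("FAM"), "unknown fluorophore")
})

test_that("a constant-band-ratio model survives the generate/ratio round trip", {
  # both channels share the kinetics; encoding N*/T* = 0.3 in the
  # coefficients must come back exactly from noiseless dual-channel traces
  pre <- neiPresets("3HC")
  fm <- constantRatioModel(
    c(S = 1e6, ES1 = 1.4e6, ES2 = 1.6e6, ES3 = 1.5e6, EP = 1.2e6, P = 1e6),
    ratio = 0.3)
  design <- small_design("3HC", E0 = 2e-6, S0 = 1e-6,
                         replicates = 1, noise_frac = 0)
  ts <- generateTraceSet("nei5", pre$params, fm, design, seed = 1)
  chans <- vapply(ts$traces, function(tr) tr$meta$channel, character(1))
  r <- intensityRatio(ts$traces[[which(chans == "total_395")]],
                      ts$traces[[which(chans == "tstar_495")]])
  expect_equal(r$intensity, rep(0.3, length(r$intensity)))
})

test_that("trace sets round-trip through CSV files plus manifest", {
  ts <- small_trace_set("3HC", seed = 4, samples_per_decade = 30)
  dir <- withr::local_tempdir()
  writeTraceSet(ts, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- readTraceSet(dir)
  expect_length(back$traces, length(ts$traces))
  for (i in seq_along(ts$traces)) {
    expect_equal(back$traces[[i]]$time, ts$traces[[i]]$time)
    expect_equal(back$traces[[i]]$intensity, ts$traces[[i]]$intensity)
    expect_identical(back$traces[[i]]$meta$channel, ts$traces[[i]]$meta$channel)
  }
  expect_identical(back$truth$scheme, "nei5")
  expect_equal(stats::setNames(as.numeric(back$truth$params),
                               names(back$truth$params)),
               stats::setNames(as.numeric(ts$truth$params),
                               names(ts$truth$params)))
  # the manifest records the generating observation model
  expect_s3_class(back$truth$fmodel, "fluorescence_model")

  # a trace file without channel metadata is a hard error, not a default
  f <- file.path(dir, grep("trace_01", list.files(dir), value = TRUE))
  lines <- readLines(f)
  writeLines(lines[!grepl("^# channel", lines)], f)
  expect_error(readTraceSet(dir), "channel")
})

test_that("invalid experiment designs are rejected with the offending field", {
  ch <- "em_320"
  expect_error(experimentDesign(data.frame(E0 = -1e-6, S0 = 1e-6), ch), "E0")
  expect_error(experimentDesign(data.frame(E0 = 1e-6, S0 = 0), ch), "S0")
  expect_error(experimentDesign(data.frame(E0 = 1e-6, S0 = 1e-6), ch,
                                replicates = 0), "replicates")
  expect_error(experimentDesign(data.frame(E0 = 1e-6, S0 = 1e-6), ch,
                                noise_frac = 1), "noise_frac")
})
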