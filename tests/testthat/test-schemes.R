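test_that("built-in schemes realise the five- and four-state mechanisms", {
  sc5 <- kineticScheme("nei5")
  expect_identical(sc5$species, c("E", "S", "ES1", "ES2", "ES3", "EP", "P"))
  expect_length(sc5$reactions, 9L)
  expect_identical(ncol(sc5$reversible_pairs), 4L)
  # one irreversible step: the lumped catalytic conversion ES3 -> EP
  irrev <- setdiff(seq_along(sc5$reactions), as.integer(sc5$reversible_pairs))
  expect_length(irrev, 1L)
  expect_identical(sc5$reactions[[irrev]]$rate, "kcat")
  expect_identical(sc5$reactions[[irrev]]$reactants, "ES3")

  sc4 <- kineticScheme("nei4")
  expect_identical(sc4$species, c("E", "S", "ES1", "ES2", "EP", "P"))
  expect_length(sc4$reactions, 7L)
  expect_identical(ncol(sc4$reversible_pairs), 3L)

  # product release realised through KP with a fast default dissociation
  for (sc in list(sc5, sc4)) {
    expect_identical(sc$derived_rates$kon, list(num = "koff", den = "KP"))
    expect_identical(sc$rate_defaults$koff, 10)
  }

  expect_error(kineticScheme("nei7"), "unknown scheme")
})

test_that("explicit reaction lists build minimal schemes and malformed input is rejected", {
  sc <- one_step_scheme()
  expect_identical(sc$species, c("E", "S", "ES"))
  expect_length(sc$reactions, 2L)
  # both conserved moieties detected automatically
  expect_setequal(lapply(sc$conservation, sort),
                  list(c("E", "ES"), c("ES", "S")))

  expect_error(kineticScheme("A + B + C -> D : k"), "termolecular")
  expect_error(kineticScheme("A <-> B : k1"), "kf/kr")
  expect_error(kineticScheme("A -> B"), "malformed")
})

test_that("stoichiometry matrix columns, rank and exact conservation", {
  sc <- one_step_scheme()
  N <- stoichiometryMatrix(sc)
  expect_identical(unname(N[, 1]), c(-1, -1, 1))
  expect_identical(unname(N[, 2]), c(1, 1, -1))

  for (case in list(list(id = "nei5", rank = 5L), list(id = "nei4", rank = 4L))) {
    sc <- kineticScheme(case$id)
    N <- stoichiometryMatrix(sc)
    expect_identical(qr(N)$rank, case$rank)
    # two conservation laws span the left null space
    expect_length(sc$conservation, nrow(N) - case$rank)
    for (g in sc$conservation) {
      ind <- as.numeric(sc$species %in% g)
      expect_true(all(crossprod(ind, N) == 0)) # exact integer arithmetic
    }
    # the two laws are the enzyme total and the DNA total
    expect_true(any(vapply(sc$conservation, function(g) "E" %in% g, logical(1))))
    expect_true(any(vapply(sc$conservation, function(g)
      all(c("S", "P") %in% g), logical(1))))
  }
})

test_that("scheme serialisation round-trips identically", {
  for (spec in list("nei5", "nei4",
                    c("!name custom", "A + B <-> C : kf/kr", "C -> D : kc"))) {
    sc <- kineticScheme(spec)
    f <- withr::local_tempfile(fileext = ".scheme")
    writeScheme(sc, f)
    expect_identical(readScheme(f), sc)
  }
})

test_that("parameter validation enforces completeness, positivity, units and strictness", {
  sc5 <- kineticScheme("nei5")
  sc4 <- kineticScheme("nei4")
  trp <- neiRateConstants("Trp")

  ok <- validateParams(sc5, trp)
  expect_s3_class(ok, "rate_params")
  expect_identical(ok[["koff"]], 10) # scheme default filled in

  bad <- trp; bad[["k2"]] <- 0
  expect_error(validateParams(sc5, bad), "positive")

  # the five-state column carries k3/k_3 that the reduced scheme never uses
  expect_error(validateParams(sc4, trp), "strict")
  perm <- validateParams(sc4, trp, strict = FALSE)
  expect_false("k3" %in% names(perm))

  expect_error(validateParams(sc5, trp[names(trp) != "k3"]), "missing")

  wrong_units <- rateParams(stats::setNames(as.numeric(trp), names(trp)),
                            units = c(k1 = "s-1"))
  expect_error(validateParams(sc5, wrong_units), "unit mismatch")
})
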