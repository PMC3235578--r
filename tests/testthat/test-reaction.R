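make_db <- function(seed = 1, n = 6) {
  set.seed(seed)
  db <- lapply(seq_len(n), function(i) random_species(paste0("s", i)))
  names(db) <- paste0("s", seq_len(n))
  c(db, list(`H+` = proton_species(), H2O = water_species(),
             `e-` = electron_species()))
}

test_that("balance bookkeeping handles clean and broken stoichiometries", {
  db <- list(
    `H+` = proton_species(),
    H2 = species_thermo("H2", "H2", 0, -1.17, -1.18, -1.16, 0.01, 0.003, 130.7),
    H2O = water_species()
  )
  good <- reaction("hydrogen", c(`H+` = 2), c(H2 = 1), electrons = 2)
  expect_true(validate_balance(good, db)$balanced)

  bad <- reaction("broken", c(`H+` = 1), c(H2O = 1))
  rep <- validate_balance(bad, db)
  expect_false(rep$balanced)
  expect_equal(rep$element_imbalance[["O"]], 1)
  expect_equal(rep$element_imbalance[["H"]], 1)
  expect_equal(rep$charge_imbalance, -1)

  expect_error(validate_balance(reaction("ghost", c(nope = 1), c(H2 = 1)), db),
               "nope")
})

test_that("reaction construction auto-cancels shared species and checks inputs", {
  r <- reaction("cancel", c(A = 2, B = 1), c(A = 1, C = 1))
  expect_equal(r$reactants, c(A = 1, B = 1))
  expect_equal(r$products, c(C = 1))
  expect_error(reaction("neg", c(A = -1), c(B = 1)), "positive")
  expect_error(reaction("anon", c(1), c(B = 1)), "named")
})

test_that("reaction thermochemistry matches the brute-force oracle", {
  db <- make_db(seed = 31)
  set.seed(31)
  for (i in 1:50) {
    ids <- sample(paste0("s", 1:6), 2)
    rxn <- reaction(paste0("r", i),
                    setNames(sample(1:2, 2, replace = TRUE), ids),
                    c(setNames(1, sample(setdiff(paste0("s", 1:6), ids), 1)),
                      H2O = sample(1:3, 1), `H+` = 1))
    th <- reaction_thermo(rxn, db, check_balance = FALSE)
    o <- oracle_reaction_thermo(rxn, db)
    for (f in c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")) {
      expect_equal(th[[f]], o[[f]], tolerance = 1e-9)
    }
    expect_equal(th$dG_g, th$dH_g + th$minus_TdS_g, tolerance = 1e-9)
    expect_equal(th$dG_aq, th$dG_g + th$ddG_solv, tolerance = 1e-9)
  }
})

test_that("identity reactions vanish and reversal negates every field", {
  db <- make_db(seed = 7)
  ident <- reaction("ident", c(s1 = 1, s2 = 2), c(s1 = 1, s2 = 2))
  th <- reaction_thermo(ident, db, check_balance = FALSE)
  expect_equal(unlist(th[c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")]),
               c(dH_g = 0, minus_TdS_g = 0, dG_g = 0, ddG_solv = 0, dG_aq = 0))

  fwd <- reaction("fwd", c(s1 = 1, s2 = 1), c(s3 = 2, H2O = 1))
  rev <- reverse_reaction(fwd)
  tf <- reaction_thermo(fwd, db, check_balance = FALSE)
  tr <- reaction_thermo(rev, db, check_balance = FALSE)
  for (f in c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")) {
    expect_equal(tr[[f]], -tf[[f]], tolerance = 1e-9)
  }
})

test_that("Hess additivity and spectator invariance hold", {
  db <- make_db(seed = 13)
  r1 <- reaction("r1", c(s1 = 1, s2 = 1), c(s3 = 1, H2O = 1))
  r2 <- reaction("r2", c(s3 = 1), c(s4 = 1, `H+` = 1))
  r3 <- reaction("r3", c(s1 = 1, s2 = 1), c(s4 = 1, H2O = 1, `H+` = 1)) # r1 + r2
  t1 <- reaction_thermo(r1, db, check_balance = FALSE)
  t2 <- reaction_thermo(r2, db, check_balance = FALSE)
  t3 <- reaction_thermo(r3, db, check_balance = FALSE)
  for (f in c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")) {
    expect_equal(t3[[f]], t1[[f]] + t2[[f]], tolerance = 1e-9)
  }

  spect <- reaction("spect", c(s1 = 1, s2 = 1, s5 = 3), c(s3 = 1, H2O = 1, s5 = 3))
  ts <- reaction_thermo(spect, db, check_balance = FALSE)
  for (f in c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")) {
    expect_equal(ts[[f]], t1[[f]], tolerance = 1e-9)
  }
})

test_that("pH adjustment reproduces printed worked examples and is linear", {
  # one proton released at pH 7 is worth -39.96 kJ/mol
  expect_equal(ph_adjust(22.0, 1, 7), -18.0, tolerance = 0.05)
  # pH 6 case compared at the source's integer rounding
  expect_equal(ph_adjust(29.7, 1, 6), -4.6, tolerance = 0.1)
  expect_lt(abs(ph_adjust(29.7, 1, 6) - (-4)), 1)

  expect_identical(ph_adjust(12.3, 0, 7), 12.3)
  expect_identical(ph_adjust(5.5, 2, 0), 5.5)
  # linear in pH and proton count
  x <- 17.2
  expect_equal(ph_adjust(x, 2, 5) - x, 2 * (ph_adjust(x, 1, 5) - x),
               tolerance = 1e-12)
  expect_equal(ph_adjust(x, 1, 10) - x, 2 * (ph_adjust(x, 1, 5) - x),
               tolerance = 1e-12)
  expect_error(ph_adjust(0, 1, 15), "pH")
})

test_that("stability differences compare products over a shared reactant side", {
  expect_equal(stability_difference(14.3, -18.0), 32.3)
  expect_equal(stability_difference(29.1, -18.0), 47.1)
  expect_identical(stability_difference(3.2, 3.2), 0)

  ra <- reaction("a", c(X = 1, Y = 1), c(P = 1))
  rb <- reaction("b", c(X = 1, Y = 1), c(Q = 1))
  rc <- reaction("c", c(X = 1, Z = 1), c(Q = 1))
  expect_equal(stability_difference(list(dG_aq = 5, reaction = ra),
                                    list(dG_aq = 2, reaction = rb)), 3)
  expect_error(stability_difference(list(dG_aq = 5, reaction = ra),
                                    list(dG_aq = 2, reaction = rc)),
               "reactant side")
})
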