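test_that("the packaged reaction table loads with every printed row intact", {
  t1 <- load_table1()
  expect_equal(nrow(t1), 45)
  expect_false(anyDuplicated(t1$eq_label) > 0)
  expect_false(anyDuplicated(t1$text_eq) > 0) # label <-> display-number map is total

  r12 <- t1[t1$eq_label == "EEq12", ]
  expect_equal(unlist(r12[c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")],
                      use.names = FALSE),
               c(-300.3, -29.5, -329.8, 293.8, -36.0))
  expect_false(r12$is_reduction)
  expect_true(t1$is_reduction[t1$eq_label == "EEq27"])
  expect_equal(sum(t1$is_reduction), 10)
  # reduction rows never fold a pH term into dG_aq
  expect_true(all(t1$protons_released_at_pH7[t1$is_reduction] == 0))
  # proton-consuming reductions store n for the conditional potential
  expect_equal(t1$eq_label[t1$n_H_consumed == 1],
               c("EEq29a", "EEq29b", "EEq30", "EEq31"))
})

test_that("a corrupted fixture is refused", {
  t1 <- load_table1()
  tmp <- tempfile(fileext = ".tsv")
  t1$dG_aq[3] <- t1$dG_aq[3] + 5
  write.table(t1, tmp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_error(load_table1(tmp), "checksum")
  expect_error(load_table1(system.file("extdata", "table1_species.tsv",
                                       package = "cuabthermo")),
               "missing column")
})

test_that("fixture data round-trips through the TSV dialect", {
  t1 <- load_table1()
  tmp <- tempfile(fileext = ".tsv")
  write.table(t1, tmp, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  expect_identical(load_table1(tmp), t1)
})

test_that("the consistency audit flags exactly the three known anomalies", {
  t1 <- load_table1()
  audit <- check_internal_consistency(t1)
  expect_equal(nrow(audit), 3)
  expect_setequal(audit$label, c("EEq16a", "EEq16c", "EEq29a"))
  expect_equal(audit$check[audit$label == "EEq16a"], "H+S vs G")
  expect_equal(audit$magnitude[audit$label == "EEq16a"], 6.2, tolerance = 0.05)
  expect_equal(audit$check[audit$label == "EEq16c"], "direction")
  expect_equal(audit$check[audit$label == "EEq29a"], "duplicate")
  # every unflagged row satisfies both column identities
  expect_equal(sum(!(t1$eq_label %in% audit$label)), 42)
})

test_that("every packaged stoichiometry balances with the declared compositions", {
  db <- table1_species()
  rxns <- table1_reactions()
  expect_equal(length(rxns), 45)
  for (r in rxns) {
    rep <- validate_balance(r, db)
    expect_true(rep$balanced, label = paste0("balance(", r$label, ")"))
  }
  # reversal of the chemical (non-reduction) reactions balances too
  for (r in rxns) {
    if (r$electrons == 0) {
      expect_true(validate_balance(reverse_reaction(r), db)$balanced,
                  label = paste0("balance(rev ", r$label, ")"))
    }
  }
})

test_that("all headline free energies, constants and potentials regenerate", {
  hl <- reproduce_headlines()
  expect_equal(sum(hl$core), 12)
  expect_true(all(hl$pass))
  pick <- function(id) hl$computed[hl$id == id]
  expect_equal(pick("log10K_cu1_hishis"), 12.75, tolerance = 0.01)
  expect_lt(abs(pick("E0_component2_nma") - 0.63), 0.015)
  expect_lt(abs(pick("E0_asp1_couple") - -0.07), 0.015)
})

test_that("paper_check composes audit, balance and headline reports", {
  res <- paper_check(quiet = TRUE)
  expect_true(all(res$balance))
  expect_equal(nrow(res$audit), 3)
  expect_true(all(res$headlines$pass))
})
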