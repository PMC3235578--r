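test_that("species generation is deterministic per seed and sized as asked", {
  spec <- synthetic_spec(seed = 101, n_species = 25)
  db1 <- generate_species(spec)
  db2 <- generate_species(spec)
  expect_identical(db1, db2)
  expect_equal(length(db1), 25 + 3)
  roles <- vapply(db1, `[[`, character(1), "role")
  expect_setequal(roles[c("H+", "H2O", "e-")], c("proton", "water", "electron"))

  # written twice, the TSV is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_species_table(db1, f1, header_comment = "seed: 101")
  write_species_table(generate_species(spec), f2, header_comment = "seed: 101")
  expect_identical(readLines(f1), readLines(f2))

  expect_error(synthetic_spec(n_species = 0), "n_species")
})

test_that("solvation magnitudes grow with charge squared", {
  db <- generate_species(synthetic_spec(seed = 17, n_species = 40))
  normals <- Filter(function(s) s$role == "normal", db)
  q <- vapply(normals, `[[`, integer(1), "charge")
  g <- abs(vapply(normals, `[[`, numeric(1), "dg_solv"))
  if (any(abs(q) == 2) && any(q == 0)) {
    expect_gt(min(g[abs(q) == 2]), max(g[q == 0]))
  }
  if (any(abs(q) == 2) && any(abs(q) == 1)) {
    expect_gt(min(g[abs(q) == 2]), max(g[abs(q) == 1]))
  }
  expect_true(all(vapply(normals, `[[`, numeric(1), "dg_solv") < 0))
})

test_that("generated reactions balance by construction, forwards and reversed", {
  db <- generate_species(synthetic_spec(seed = 23, n_species = 20))
  gen <- generate_reactions(db, seed = 23, n_reactions = 30, p_reduction = 0.3)
  expect_equal(length(gen$reactions), 30)
  for (r in gen$reactions) {
    expect_true(validate_balance(r, gen$species)$balanced,
                label = paste0("balance(", r$label, ")"))
    if (r$electrons == 0) {
      expect_true(validate_balance(reverse_reaction(r), gen$species)$balanced)
    }
  }
  # reduction-shaped reactions exist and keep copper on both sides
  red <- Filter(function(r) r$electrons == 1, gen$reactions)
  expect_gt(length(red), 0)
  for (r in red) {
    has_cu <- function(ids) any(vapply(ids, function(id) {
      "Cu" %in% names(gen$species[[id]]$composition)
    }, logical(1)))
    expect_true(has_cu(names(r$reactants)))
    expect_true(has_cu(names(r$products)))
  }
})

test_that("engine and brute-force oracle agree over 500 seeded reactions", {
  worst <- 0
  for (seed in 1:5) {
    db <- generate_species(synthetic_spec(seed = seed, n_species = 15))
    gen <- generate_reactions(db, seed = seed, n_reactions = 100)
    for (r in gen$reactions) {
      th <- reaction_thermo(r, gen$species)
      o <- oracle_reaction_thermo(r, gen$species)
      for (f in c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq")) {
        worst <- max(worst, abs(th[[f]] - o[[f]]))
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("oracle free energies invert exactly through log K and potentials", {
  const <- cu_constants()
  db <- generate_species(synthetic_spec(seed = 3, n_species = 10))
  gen <- generate_reactions(db, seed = 3, n_reactions = 20)
  for (r in gen$reactions) {
    dg <- oracle_reaction_thermo(r, gen$species, const)$dG_aq
    expect_equal(-equilibrium_log10K(dg, const) * rt_ln10_kjmol(const), dg,
                 tolerance = 1e-6)
    expect_equal(-reduction_potential(dg, FALSE, const) * const$F + const$dG_SHE,
                 dg, tolerance = 1e-6)
  }
})

test_that("a synthetic bundle round-trips through the file dialects", {
  out <- tempfile("bundle")
  paths <- write_synthetic_bundle(out, seed = 11, n_species = 10, n_reactions = 8)
  db <- read_species_table(paths$species)
  rxns <- read_reactions(paths$reactions)
  truth <- read.delim(paths$truth, comment.char = "#")
  expect_equal(length(rxns), 8)
  for (i in seq_len(nrow(truth))) {
    th <- reaction_thermo(rxns[[truth$label[i]]], db)
    expect_equal(th$dG_aq, truth$dG_aq[i], tolerance = 1e-6)
    expect_equal(th$dH_g, truth$dH_g[i], tolerance = 1e-6)
  }
})
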