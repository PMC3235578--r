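test_that("composite energy scheme reduces to direct arithmetic", {
  sp <- random_species("x")
  sp$e_mp2_sb <- -1975.234
  sp$e_b3lyp_lb <- -1975.891
  sp$e_b3lyp_sb <- -1974.990
  expect_equal(composite_mp2_lb(sp), -1975.234 + -1975.891 - -1974.990,
               tolerance = 1e-12)

  # small-basis terms cancel when MP2/SB and B3LYP/SB coincide
  sp$e_mp2_sb <- sp$e_b3lyp_sb <- -1200.5
  sp$e_b3lyp_lb <- -1201.25
  expect_identical(composite_mp2_lb(sp), -1201.25)

  sp$e_mp2_sb <- sp$e_b3lyp_sb <- sp$e_b3lyp_lb <- 0
  expect_identical(composite_mp2_lb(sp), 0)

  sp$e_b3lyp_lb <- NA_real_
  expect_error(composite_mp2_lb(sp), "e_b3lyp_lb")
})

test_that("standard-state and mixing entropy terms enter as closed forms", {
  const <- cu_constants()
  expect_equal(standard_state_entropy(const), 8.314 * log(1 / 24.46),
               tolerance = 1e-12)
  expect_equal(standard_state_entropy(const), -26.58, tolerance = 0.005)

  set.seed(11)
  sp <- random_species("m")
  sp$n_conf <- 1L
  base <- gas_energetics(sp, const)
  # n_conf = 1: mixing contributes nothing beyond the standard-state term
  expect_equal(base$s_corrected, sp$s_gas + standard_state_entropy(const))
  # the standard-state term alone raises g_gas by R*T*ln(24.46) = +7.93 kJ/mol
  no_ss <- cu_constants(standard_volume = 1)
  expect_equal(base$g_gas - gas_energetics(sp, no_ss)$g_gas,
               8.314 * 298.15 * log(24.46) / 1000, tolerance = 1e-9)
  expect_equal(base$g_gas - gas_energetics(sp, no_ss)$g_gas, 7.93,
               tolerance = 0.005)
})

test_that("species energetics match the single-expression oracle on seeded draws", {
  set.seed(42)
  const <- cu_constants()
  for (i in 1:1000) {
    sp <- random_species(paste0("r", i))
    en <- species_energetics(sp, const)
    expect_equal(en$g_gas, oracle_g_gas(sp), tolerance = 1e-9)
    expect_equal(en$g_aq, oracle_g_aq(sp), tolerance = 1e-9)
    expect_equal(en$g_gas, en$h_gas - const$temperature * en$s_corrected / 1000,
                 tolerance = 1e-9)
  }
})

test_that("gas free energy is linear in each component", {
  set.seed(5)
  sp <- random_species("lin")
  const <- cu_constants()
  h1 <- gas_energetics(sp, const)$h_gas
  sp2 <- sp
  sp2$zpe <- 2 * sp$zpe
  h2 <- gas_energetics(sp2, const)$h_gas
  expect_equal(h2 - h1, const$hartree_to_kjmol * const$zpe_scale * sp$zpe,
               tolerance = 1e-9)
})

test_that("solvation overrides apply by role and are idempotent", {
  const <- cu_constants()
  p <- proton_species()
  p$dg_solv <- 999 # stored value must be ignored
  expect_equal(aqueous_free_energy(p, const) - gas_energetics(p, const)$g_gas,
               -1107)
  w <- water_species(dg_solv = 999)
  expect_equal(aqueous_free_energy(w, const) - gas_energetics(w, const)$g_gas,
               -16.2)
  expect_identical(aqueous_free_energy(electron_species(), const), 0)

  set.seed(9)
  n <- random_species("n0")
  n$dg_solv <- 0
  expect_equal(aqueous_free_energy(n, const), gas_energetics(n, const)$g_gas)
  # repeated evaluation on the same record is bit-identical
  expect_identical(aqueous_free_energy(w, const), aqueous_free_energy(w, const))
})

test_that("species invariants are enforced at construction", {
  mk <- function(...) {
    args <- utils::modifyList(list(
      id = "bad", formula = "CH4", charge = 0L, e_b3lyp_sb = -1, e_b3lyp_lb = -1,
      e_mp2_sb = -1, zpe = 0.1, h_thermal = 0.01, s_gas = 200, n_conf = 1L,
      dg_solv = -5, role = "normal"), list(...))
    do.call(species_thermo, args)
  }
  expect_error(mk(n_conf = 0L), "n_conf")
  expect_error(mk(zpe = -0.1), "zpe")
  expect_error(mk(formula = ""), "composition")
  expect_error(mk(role = "proton", formula = "H", charge = 0L), "proton")
  expect_s3_class(mk(), "species_thermo")
})
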