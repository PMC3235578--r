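# Independent single-expression oracles and random-record builders shared
# across the test files. These deliberately avoid every helper in the
# package's species layer: each quantity is one literal arithmetic
# expression over the raw fields.

oracle_g_gas <- function(s, hk = 2625.50, zs = 0.9806, R = 8.314, Tk = 298.15,
                         V = 24.46) {
  hk * (s$e_mp2_sb + s$e_b3lyp_lb - s$e_b3lyp_sb + zs * s$zpe + s$h_thermal) -
    Tk * (s$s_gas + R * log(s$n_conf) + R * log(1 / V)) / 1000
}

oracle_g_aq <- function(s, dgs_H = -1107, dgs_w = -16.2, ...) {
  dgs <- if (s$role == "proton") dgs_H else if (s$role == "water") dgs_w else s$dg_solv
  if (s$role == "electron") 0 else oracle_g_gas(s, ...) + dgs
}

random_species <- function(id, charge = sample(-2:2, 1), role = "normal") {
  e_sb <- -runif(1, 100, 2500)
  species_thermo(
    id = id,
    formula = c(C = sample(1:10, 1), H = sample(1:20, 1), O = sample(1:6, 1)),
    charge = charge,
    e_b3lyp_sb = e_sb,
    e_b3lyp_lb = e_sb - runif(1, 0, 1),
    e_mp2_sb = e_sb + rnorm(1),
    zpe = runif(1, 0, 1),
    h_thermal = runif(1, 0, 0.1),
    s_gas = runif(1, 100, 1000),
    n_conf = sample(1:10, 1),
    dg_solv = -runif(1, 0, 1200),
    role = role
  )
}
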