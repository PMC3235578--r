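#' Per-species quantum-thermochemistry record
#'
#' One chemical species with the raw components needed to assemble its gas
#' and aqueous free energies: electronic energies at the three model
#' chemistries (hartree), unscaled zero-point energy (hartree), thermal
#' enthalpy correction 0 -> 298 K (hartree), gas entropy (J mol^-1 K^-1),
#' conformer count for the R ln(n) mixing entropy, and a continuum solvation
#' free energy (kJ mol^-1).
#'
#' Three pseudo-species conventions are enforced through `role`:
#' * `"proton"`: composition H, charge +1; its solvation free energy is
#'   always overridden by the experimental value in [cu_constants()].
#' * `"water"`: solvation free energy overridden by the experimental value,
#'   which also carries the 55.6 M concentration convention.
#' * `"electron"`: all energy fields zero, charge -1, empty composition; a
#'   pure bookkeeping entity ignored in every energy sum.
#'
#' @param id unique species label, e.g. `"2a(H2O)2"`.
#' @param formula Hill-order formula string (see [parse_formula()]), or a
#'   named integer vector of element counts.
#' @param charge integer charge; electrons are not counted here.
#' @param e_b3lyp_sb,e_b3lyp_lb,e_mp2_sb electronic energies, hartree.
#' @param zpe unscaled zero-point energy, hartree (>= 0).
#' @param h_thermal thermal enthalpy correction, hartree.
#' @param s_gas gas-phase entropy, J mol^-1 K^-1.
#' @param n_conf conformer count used for the mixing entropy, integer >= 1.
#' @param dg_solv solvation free energy, kJ mol^-1.
#' @param role one of `"normal"`, `"proton"`, `"water"`, `"electron"`.
#' @return An object of class `species_thermo`.
#' @examples
#' sp <- species_thermo("Im", "C3H4N2", 0,
#'   e_b3lyp_sb = -226.2, e_b3lyp_lb = -226.3, e_mp2_sb = -225.6,
#'   zpe = 0.071, h_thermal = 0.004, s_gas = 288.4, n_conf = 1,
#'   dg_solv = -35.1
#' )
#' @export
species_thermo <- function(id, formula, charge,
                           e_b3lyp_sb, e_b3lyp_lb, e_mp2_sb,
                           zpe, h_thermal, s_gas, n_conf = 1L,
                           dg_solv = 0, role = c("normal", "proton", "water", "electron")) {
  role <- match.arg(role)
  composition <- if (is.character(formula)) {
    if (length(formula)) parse_formula(formula) else stats::setNames(integer(0), character(0))
  } else {
    stopifnot(is.numeric(formula))
    comp <- stats::setNames(as.integer(formula), names(formula))
    comp[comp != 0L]
  }
  # canonical (Hill) element order so equal compositions compare identical
  if (length(composition)) {
    elems <- names(composition)
    ord <- if ("C" %in% elems) {
      c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
    } else {
      sort(elems)
    }
    composition <- composition[ord]
  }
  num <- c(e_b3lyp_sb = e_b3lyp_sb, e_b3lyp_lb = e_b3lyp_lb,
           e_mp2_sb = e_mp2_sb, zpe = zpe, h_thermal = h_thermal,
           s_gas = s_gas, dg_solv = dg_solv)
  if (anyNA(num) || !all(is.finite(num))) {
    stop("species '", id, "': missing or non-finite field(s): ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  }
  n_conf <- as.integer(n_conf)
  if (is.na(n_conf) || n_conf < 1L) stop("species '", id, "': n_conf must be >= 1")
  if (zpe < 0) stop("species '", id, "': zpe must be >= 0")
  charge <- as.integer(charge)

  if (role == "proton" && !(identical(unname(composition[names(composition) == "H"]), 1L) &&
                            length(composition) == 1L && charge == 1L)) {
    stop("species '", id, "': role=proton requires composition {H:1} and charge +1")
  }
  if (role == "electron") {
    if (charge != -1L) stop("species '", id, "': role=electron requires charge -1")
    if (length(composition)) stop("species '", id, "': role=electron requires empty composition")
    if (any(num != 0) ) stop("species '", id, "': role=electron requires all energy fields 0")
  } else if (!length(composition)) {
    stop("species '", id, "': composition must be non-empty")
  }

  structure(list(
    id = as.character(id), composition = composition, charge = charge,
    e_b3lyp_sb = e_b3lyp_sb, e_b3lyp_lb = e_b3lyp_lb, e_mp2_sb = e_mp2_sb,
    zpe = zpe, h_thermal = h_thermal, s_gas = s_gas, n_conf = n_conf,
    dg_solv = dg_solv, role = role
  ), class = "species_thermo")
}

#' Proton, water and electron pseudo-species
#'
#' Convenience constructors for the three special records every species set
#' carries. The proton and electron carry no computed thermochemistry of
#' their own (the proton's aqueous free energy is entirely its experimental
#' solvation term plus whatever gas-phase convention the caller adopts); the
#' water record takes real computed components.
#'
#' @param ... fields forwarded to [species_thermo()] (water only).
#' @return `species_thermo` objects.
#' @export
proton_species <- function() {
  species_thermo("H+", c(H = 1L), 1L,
                 e_b3lyp_sb = 0, e_b3lyp_lb = 0, e_mp2_sb = 0,
                 zpe = 0, h_thermal = 0, s_gas = 108.9, n_conf = 1L,
                 dg_solv = 0, role = "proton")
}

#' @rdname proton_species
#' @export
electron_species <- function() {
  species_thermo("e-", character(0), -1L,
                 e_b3lyp_sb = 0, e_b3lyp_lb = 0, e_mp2_sb = 0,
                 zpe = 0, h_thermal = 0, s_gas = 0, n_conf = 1L,
                 dg_solv = 0, role = "electron")
}

#' @rdname proton_species
#' @export
water_species <- function(...) {
  defaults <- list(id = "H2O", formula = "H2O", charge = 0L,
                   e_b3lyp_sb = -76.4340, e_b3lyp_lb = -76.4621,
                   e_mp2_sb = -76.2096, zpe = 0.0213, h_thermal = 0.0038,
                   s_gas = 188.8, n_conf = 1L, dg_solv = -16.2, role = "water")
  args <- utils::modifyList(defaults, list(...))
  do.call(species_thermo, args)
}

#' @export
print.species_thermo <- function(x, ...) {
  cat(sprintf("<species_thermo> %s [%s%+d] role=%s n_conf=%d\n",
              x$id, format_formula(x$composition), x$charge, x$role, x$n_conf))
  invisible(x)
}

#' Composite MP2 large-basis electronic energy
#'
#' Additivity approximation for the MP2 energy in the large basis:
#' `E(MP2/LB) = E(MP2/SB) + E(B3LYP/LB) - E(B3LYP/SB)`, combining the
#' MP2 correlation treatment in the small basis with the basis-set
#' extension measured at the B3LYP level.
#'
#' @param species a [species_thermo()] record.
#' @return electronic energy, hartree.
#' @export
composite_mp2_lb <- function(species) {
  stopifnot(inherits(species, "species_thermo"))
  for (f in c("e_mp2_sb", "e_b3lyp_lb", "e_b3lyp_sb")) {
    if (is.null(species[[f]]) || !is.finite(species[[f]])) {
      stop("species '", species$id, "': missing electronic energy component '", f, "'")
    }
  }
  species$e_mp2_sb + species$e_b3lyp_lb - species$e_b3lyp_sb
}

#' Gas-phase and aqueous energetics of one species
#'
#' Assembles, in kJ mol^-1 (entropy in J mol^-1 K^-1):
#' * `h_gas = hartree_to_kjmol * (E_composite + zpe_scale*zpe + h_thermal)`
#'   (the thermal correction and entropies are deliberately not ZPE-scaled);
#' * `s_corrected = s_gas + R ln(n_conf) + R ln(1/24.46)`, i.e. the raw gas
#'   entropy plus conformational mixing and the 1 atm -> 1 M standard-state
#'   term;
#' * `g_gas = h_gas - T*s_corrected/1000`;
#' * `g_aq = g_gas + dg_solv`, where `dg_solv` is replaced by the
#'   experimental proton/water values for those roles.
#'
#' An electron contributes zero everywhere.
#'
#' @param species a [species_thermo()] record.
#' @param constants a [cu_constants()] object.
#' @return For `species_energetics`, a list with `h_gas`, `s_corrected`,
#'   `g_gas`, `g_aq`; `gas_energetics` omits `g_aq`;
#'   `aqueous_free_energy` returns the `g_aq` scalar alone.
#' @export
gas_energetics <- function(species, constants = cu_constants()) {
  stopifnot(inherits(species, "species_thermo"))
  if (species$role == "electron") {
    return(list(h_gas = 0, s_corrected = 0, g_gas = 0))
  }
  if (species$n_conf < 1L) stop("species '", species$id, "': n_conf must be >= 1")
  if (species$zpe < 0) stop("species '", species$id, "': zpe must be >= 0")
  h_gas <- constants$hartree_to_kjmol *
    (composite_mp2_lb(species) + constants$zpe_scale * species$zpe + species$h_thermal)
  s_corrected <- species$s_gas + constants$R * log(species$n_conf) +
    standard_state_entropy(constants)
  g_gas <- h_gas - constants$temperature * s_corrected / 1000
  list(h_gas = h_gas, s_corrected = s_corrected, g_gas = g_gas)
}

#' @rdname gas_energetics
#' @export
aqueous_free_energy <- function(species, constants = cu_constants()) {
  if (species$role == "electron") return(0)
  gas_energetics(species, constants)$g_gas + effective_dg_solv(species, constants)
}

#' @rdname gas_energetics
#' @export
species_energetics <- function(species, constants = cu_constants()) {
  gas <- gas_energetics(species, constants)
  c(gas, list(g_aq = if (species$role == "electron") 0 else
    gas$g_gas + effective_dg_solv(species, constants)))
}

# Solvation free energy after the experimental overrides; kJ/mol.
effective_dg_solv <- function(species, constants) {
  switch(species$role,
    proton = constants$dGsolv_proton,
    water = constants$dGsolv_water,
    electron = 0,
    species$dg_solv
  )
}
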