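#' Physical and empirical constants for the thermochemical cycle
#'
#' Bundles every constant the engine uses into one immutable-by-convention
#' object so that a whole analysis can be rerun under explicit overrides
#' (e.g. a different temperature or hartree conversion) without touching any
#' other code path.
#'
#' @param R gas constant, J mol^-1 K^-1.
#' @param temperature absolute temperature, K. 298.15 K by standard
#'   convention for "298 K" thermochemistry.
#' @param F Faraday constant, kJ mol^-1 V^-1.
#' @param dG_SHE free energy of the standard-hydrogen-electrode half
#'   reaction 1/2 H2(g) + e- -> H+(aq), kJ mol^-1, with the electron carrying
#'   no free energy.
#' @param dGsolv_proton experimental solvation free energy of the proton,
#'   kJ mol^-1; always overrides any stored per-species value.
#' @param dGsolv_water experimental solvation free energy of water,
#'   kJ mol^-1; the 55.6 M concentration of liquid water is folded into this
#'   number, so no extra concentration term is ever applied to released water.
#' @param zpe_scale multiplicative scaling of harmonic zero-point energies
#'   (dimensionless). Thermal enthalpy corrections and entropies are not
#'   scaled.
#' @param cu_redox_correction empirical correction, kJ mol^-1, added to the
#'   free energy of any half reaction taking copper from oxidation state +2
#'   to +1, once per electron; absorbs the correlation error in the second
#'   ionization energy of copper.
#' @param standard_volume molar volume of an ideal gas at 298 K, litres;
#'   the R ln(1/standard_volume) entropy term converts the 1 atm gas
#'   standard state to 1 M.
#' @param hartree_to_kjmol energy conversion, kJ mol^-1 per hartree.
#'
#' @return An object of class `cu_constants`: a named list of the above plus
#'   nothing else. Derived quantities (R*T*ln10 etc.) are computed on demand
#'   by [rt_ln10_kjmol()] and friends, never stored rounded.
#' @examples
#' const <- cu_constants()
#' rt_ln10_kjmol(const) # ~5.708 kJ/mol per log10 unit
#' @export
cu_constants <- function(R = 8.314,
                         temperature = 298.15,
                         F = 96.485,
                         dG_SHE = -418,
                         dGsolv_proton = -1107,
                         dGsolv_water = -16.2,
                         zpe_scale = 0.9806,
                         cu_redox_correction = 57,
                         standard_volume = 24.46,
                         hartree_to_kjmol = 2625.50) {
  vals <- list(
    R = R, temperature = temperature, F = F, dG_SHE = dG_SHE,
    dGsolv_proton = dGsolv_proton, dGsolv_water = dGsolv_water,
    zpe_scale = zpe_scale, cu_redox_correction = cu_redox_correction,
    standard_volume = standard_volume, hartree_to_kjmol = hartree_to_kjmol
  )
  bad <- names(vals)[!vapply(vals, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("constants must be finite numeric scalars: ", paste(bad, collapse = ", "))
  }
  if (temperature <= 0) stop("temperature must be positive")
  structure(vals, class = "cu_constants")
}

#' R*T*ln(10) in kJ mol^-1
#'
#' The free-energy cost of one log10 concentration unit; ~5.708 kJ/mol at
#' 298.15 K. Used for pH terms, log K and pKa conversions.
#' @param constants a [cu_constants()] object.
#' @return numeric scalar, kJ mol^-1.
#' @export
rt_ln10_kjmol <- function(constants = cu_constants()) {
  constants$R * constants$temperature * log(10) / 1000
}

#' Standard-state entropy correction R*ln(1/V_m)
#'
#' Entropy term converting a 1 atm ideal gas to the 1 M solution convention,
#' about -26.58 J mol^-1 K^-1 (i.e. +7.93 kJ/mol in G at 298.15 K).
#' @param constants a [cu_constants()] object.
#' @return numeric scalar, J mol^-1 K^-1 (negative).
#' @export
standard_state_entropy <- function(constants = cu_constants()) {
  constants$R * log(1 / constants$standard_volume)
}

#' @export
print.cu_constants <- function(x, ...) {
  cat("Thermochemical-cycle constants:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  cat(sprintf("  (derived) RT ln10    %.4f kJ/mol\n", rt_ln10_kjmol(x)))
  invisible(x)
}
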