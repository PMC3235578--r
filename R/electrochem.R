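#' Standard reduction potential versus SHE
#'
#' Converts the aqueous free energy of a one-electron reduction half
#' reaction (electron carrying no free energy) into a standard potential:
#' `E0 = -(dG_aq_corrected - dG_SHE)/F`, with `dG_SHE = -418 kJ/mol` for
#' 1/2 H2(g) + e- -> H+(aq). When `apply_cu_correction` is TRUE the
#' empirical `+57 kJ/mol` copper correction is added to `dG_aq` first; it
#' belongs to every half reaction taking Cu from +2 to +1 and shifts E0 by
#' exactly -0.591 V.
#'
#' @param dG_aq uncorrected aqueous free energy of the reduction, kJ mol^-1
#'   (standard state, no pH term).
#' @param apply_cu_correction logical, apply the Cu(+2 -> +1) correction.
#' @param constants a [cu_constants()] object.
#' @return potential, V vs SHE.
#' @examples
#' reduction_potential(-527.9) # 0.55 V
#' @export
reduction_potential <- function(dG_aq, apply_cu_correction = TRUE,
                                constants = cu_constants()) {
  corr <- if (apply_cu_correction) constants$cu_redox_correction else 0
  -((dG_aq + corr) - constants$dG_SHE) / constants$F
}

#' Conditional potential at a stated pH
#'
#' Nernst adjustment for a half reaction consuming `n` protons in a
#' solution buffered at the given pH under otherwise standard conditions:
#' the reaction quotient reduces to `Q = 10^(pH*n)`, so
#' `E0' = E0 - (RT/F) ln(10^(pH*n))`; at pH 7 each consumed proton lowers
#' the potential by 0.4141 V.
#'
#' @param E0 standard potential, V.
#' @param n_protons_consumed protons consumed per electron-transfer event
#'   (integer >= 0).
#' @param pH solution pH.
#' @param constants a [cu_constants()] object.
#' @return conditional potential E0', V.
#' @examples
#' conditional_potential(0.786, 1, 7) # ~0.37 V
#' @export
conditional_potential <- function(E0, n_protons_consumed, pH = 7,
                                  constants = cu_constants()) {
  if (any(n_protons_consumed < 0)) stop("n_protons_consumed must be >= 0")
  E0 - rt_ln10_kjmol(constants) * pH * n_protons_consumed / constants$F
}

#' Equilibrium constant from an aqueous free energy
#'
#' `log10 K = -dG_aq / (R T ln 10)`, with `R T ln 10 = 5.708 kJ/mol` at
#' 298.15 K. Supply the free energy at whichever standard or pH-conditional
#' state the constant should refer to.
#'
#' @param dG_aq free energy, kJ mol^-1.
#' @param constants a [cu_constants()] object.
#' @return dimensionless log10 K.
#' @examples
#' equilibrium_log10K(-36.0) # ~6.3
#' @export
equilibrium_log10K <- function(dG_aq, constants = cu_constants()) {
  -dG_aq / rt_ln10_kjmol(constants)
}

#' Acid dissociation constant from a deprotonation free energy
#'
#' `pKa = dG / (R T ln 10)` for HA(aq) -> A-(aq) + H+(aq) at standard
#' state. The input must be a standard-state free energy; pH-adjusted
#' values are never unwound here.
#'
#' @param dG_deprotonation_aq standard-state deprotonation free energy,
#'   kJ mol^-1.
#' @param constants a [cu_constants()] object.
#' @return dimensionless pKa.
#' @examples
#' pka(57.08) # ~10
#' @export
pka <- function(dG_deprotonation_aq, constants = cu_constants()) {
  dG_deprotonation_aq / rt_ln10_kjmol(constants)
}

#' Redox report for a set of half reactions
#'
#' Tabulates standard and pH-conditional potentials for reduction free
#' energies, applying the copper correction where flagged.
#'
#' @param label character vector of reaction labels.
#' @param dG_aq uncorrected aqueous reduction free energies, kJ mol^-1.
#' @param n_protons_consumed integer vector (recycled), protons consumed.
#' @param apply_cu_correction logical vector (recycled).
#' @param pH pH for the conditional column.
#' @param constants a [cu_constants()] object.
#' @return data.frame with columns `label`, `dG_aq_uncorrected`,
#'   `dG_aq_corrected`, `E0`, `n_H_consumed`, `E0_prime`, `pH`.
#' @export
redox_report <- function(label, dG_aq, n_protons_consumed = 0L,
                         apply_cu_correction = TRUE, pH = 7,
                         constants = cu_constants()) {
  n <- length(dG_aq)
  n_protons_consumed <- rep_len(as.integer(n_protons_consumed), n)
  apply_cu_correction <- rep_len(apply_cu_correction, n)
  corr <- ifelse(apply_cu_correction, constants$cu_redox_correction, 0)
  E0 <- reduction_potential(dG_aq, FALSE, constants) - corr / constants$F
  data.frame(
    label = as.character(label),
    dG_aq_uncorrected = dG_aq,
    dG_aq_corrected = dG_aq + corr,
    E0 = E0,
    n_H_consumed = n_protons_consumed,
    E0_prime = conditional_potential(E0, n_protons_consumed, pH, constants),
    pH = pH,
    stringsAsFactors = FALSE
  )
}
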