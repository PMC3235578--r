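#' Balanced chemical reaction over a species set
#'
#' Stoichiometry is stored as two named numeric vectors of positive
#' coefficients. A species appearing on both sides is auto-cancelled on
#' construction. Electrons are tracked by the integer `electrons` field
#' (reactant side), never as a stoichiometric species; each electron counts
#' -1 toward charge balance.
#'
#' @param label short reaction identifier, e.g. `"EEq12"`.
#' @param reactants,products named numeric vectors, species id -> positive
#'   coefficient.
#' @param electrons number of electrons on the reactant side (>= 0).
#' @param description free-text note (e.g. the printed equation).
#' @return An object of class `reaction`.
#' @examples
#' rxn <- reaction("hydrogen", c("H+" = 2), c("H2" = 1), electrons = 2)
#' @export
reaction <- function(label, reactants, products, electrons = 0L, description = "") {
  reactants <- tidy_side(reactants, label, "reactants")
  products <- tidy_side(products, label, "products")
  electrons <- as.integer(electrons)
  if (is.na(electrons) || electrons < 0L) stop("reaction '", label, "': electrons must be >= 0")
  # auto-cancel common species
  common <- intersect(names(reactants), names(products))
  for (sp in common) {
    k <- min(reactants[[sp]], products[[sp]])
    reactants[[sp]] <- reactants[[sp]] - k
    products[[sp]] <- products[[sp]] - k
  }
  reactants <- reactants[reactants > 0]
  products <- products[products > 0]
  structure(list(label = as.character(label), reactants = reactants,
                 products = products, electrons = electrons,
                 description = as.character(description)),
            class = "reaction")
}

tidy_side <- function(side, label, what) {
  if (is.null(side) || !length(side)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(side)) || any(!nzchar(names(side)))) {
    stop("reaction '", label, "': ", what, " must be a named vector (species id -> coefficient)")
  }
  side <- vapply(split(unname(side), names(side)), sum, numeric(1))
  if (any(side <= 0) || anyNA(side)) {
    stop("reaction '", label, "': ", what, " coefficients must be positive")
  }
  side
}

#' @export
print.reaction <- function(x, ...) {
  fmt <- function(side) {
    if (!length(side)) return("(nothing)")
    paste(ifelse(side == 1, names(side), paste(side, names(side))), collapse = " + ")
  }
  el <- if (x$electrons > 0) paste0(" + ", if (x$electrons > 1) x$electrons else "", "e-") else ""
  cat(sprintf("<reaction> %s: %s%s -> %s\n", x$label, fmt(x$reactants), el, fmt(x$products)))
  invisible(x)
}

#' Reverse a reaction
#'
#' Swaps reactants and products. Electrons stay on the (new) reactant side
#' only if there were none before; a forward reduction becomes an oxidation
#' written with the electron as a formal product, which this representation
#' cannot store, so reversal of a reaction with `electrons > 0` is refused.
#' Reaction-level thermodynamics of the reverse reaction are simply the
#' negated forward fields (see [reaction_thermo()]).
#' @param rxn a [reaction()].
#' @return the reversed `reaction`.
#' @export
reverse_reaction <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  if (rxn$electrons > 0L) {
    stop("reaction '", rxn$label, "': cannot reverse a reduction half-reaction in this representation")
  }
  reaction(paste0(rxn$label, "_rev"), rxn$products, rxn$reactants,
           electrons = 0L, description = rxn$description)
}

# Resolve ids against a species db (named list with $composition/$charge).
resolve_species <- function(ids, species_db) {
  missing <- setdiff(ids, names(species_db))
  if (length(missing)) {
    stop("unknown species id(s): ", paste(missing, collapse = ", "))
  }
  species_db[ids]
}

#' Check element and charge conservation of a reaction
#'
#' @param rxn a [reaction()].
#' @param species_db named list of species records carrying `$composition`
#'   (named integer vector) and `$charge`; [species_thermo()] objects or the
#'   lightweight records from [table1_species()] both work.
#' @return list with `element_imbalance` (named integer vector, products
#'   minus reactants, zero entries dropped), `charge_imbalance` (integer;
#'   electrons counted at -1 on the reactant side) and `balanced` (logical).
#' @examples
#' db <- table1_species()
#' rxns <- table1_reactions()
#' validate_balance(rxns[["EEq12"]], db)$balanced
#' @export
validate_balance <- function(rxn, species_db) {
  stopifnot(inherits(rxn, "reaction"))
  side_totals <- function(side) {
    comp <- stats::setNames(integer(0), character(0))
    charge <- 0
    for (sp in names(side)) {
      rec <- resolve_species(sp, species_db)[[1]]
      k <- side[[sp]]
      comp <- add_compositions(comp, rec$composition * k)
      charge <- charge + k * rec$charge
    }
    list(comp = comp, charge = charge)
  }
  r <- side_totals(rxn$reactants)
  p <- side_totals(rxn$products)
  imbalance <- add_compositions(p$comp, r$comp, sign = -1L)
  charge_imbalance <- p$charge - (r$charge - rxn$electrons)
  list(element_imbalance = imbalance,
       charge_imbalance = charge_imbalance,
       balanced = !length(imbalance) && charge_imbalance == 0)
}

#' Reaction-level thermochemistry by Hess summation
#'
#' Computes the five reaction-level columns, each as the product-side sum
#' minus the reactant-side sum of the corresponding per-species quantity:
#' gas enthalpy `dH_g`, entropy term `minus_TdS_g` (= -T * sum of corrected
#' entropies / 1000), gas free energy `dG_g` at the 1 M standard state,
#' solvation change `ddG_solv` (with the experimental proton/water
#' overrides), and the aqueous free energy `dG_aq = dG_g + ddG_solv`.
#' `dG_aq` carries no pH term and no copper redox correction; those are
#' applied explicitly by [ph_adjust()] and [reduction_potential()].
#'
#' @param rxn a balanced [reaction()].
#' @param species_db named list of [species_thermo()] records.
#' @param constants a [cu_constants()] object.
#' @param check_balance refuse unbalanced reactions (default TRUE).
#' @return object of class `reaction_thermo`: list with fields `label`,
#'   `dH_g`, `minus_TdS_g`, `dG_g`, `ddG_solv`, `dG_aq` (kJ mol^-1) and
#'   `net_protons_released` (product-side minus reactant-side protons).
#' @export
reaction_thermo <- function(rxn, species_db, constants = cu_constants(),
                            check_balance = TRUE) {
  stopifnot(inherits(rxn, "reaction"))
  if (check_balance) {
    bal <- validate_balance(rxn, species_db)
    if (!bal$balanced) {
      stop("reaction '", rxn$label, "' is not balanced; element imbalance: ",
           if (length(bal$element_imbalance)) {
             paste(names(bal$element_imbalance), bal$element_imbalance,
                   sep = ":", collapse = " ")
           } else "none",
           "; charge imbalance: ", bal$charge_imbalance)
    }
  }
  signed_sum <- function(f) {
    tot <- 0
    for (sp in names(rxn$products)) {
      tot <- tot + rxn$products[[sp]] * f(species_db[[sp]])
    }
    for (sp in names(rxn$reactants)) {
      tot <- tot - rxn$reactants[[sp]] * f(species_db[[sp]])
    }
    tot
  }
  resolve_species(c(names(rxn$reactants), names(rxn$products)), species_db)
  en <- lapply(stats::setNames(nm = union(names(rxn$reactants), names(rxn$products))),
               function(sp) species_energetics(species_db[[sp]], constants))
  dH_g <- signed_sum(function(s) en[[s$id]]$h_gas)
  minus_TdS_g <- signed_sum(function(s) {
    if (s$role == "electron") 0 else -constants$temperature * en[[s$id]]$s_corrected / 1000
  })
  dG_g <- signed_sum(function(s) en[[s$id]]$g_gas)
  ddG_solv <- signed_sum(function(s) effective_dg_solv(s, constants))
  dG_aq <- signed_sum(function(s) en[[s$id]]$g_aq)
  protons <- function(side) {
    sum(vapply(names(side), function(sp) {
      if (species_db[[sp]]$role == "proton") side[[sp]] else 0
    }, numeric(1)))
  }
  structure(list(label = rxn$label, dH_g = dH_g, minus_TdS_g = minus_TdS_g,
                 dG_g = dG_g, ddG_solv = ddG_solv, dG_aq = dG_aq,
                 net_protons_released = protons(rxn$products) - protons(rxn$reactants)),
            class = "reaction_thermo")
}

#' @export
print.reaction_thermo <- function(x, ...) {
  cat(sprintf(
    "<reaction_thermo> %s\n  dH(g) %8.1f  -TdS(g) %8.1f  dG(g) %8.1f  ddG(solv) %8.1f  dG(aq) %8.1f kJ/mol\n",
    x$label, x$dH_g, x$minus_TdS_g, x$dG_g, x$ddG_solv, x$dG_aq))
  invisible(x)
}

#' pH-conditional reaction free energy
#'
#' Adjusts a standard-state aqueous free energy for proton release into a
#' buffered solution: each released proton contributes
#' `-R*T*ln(10)*pH` (about -39.96 kJ mol^-1 at pH 7), each consumed proton
#' the opposite. `net_protons_released` may be negative.
#'
#' @param dG_aq standard-state aqueous free energy, kJ mol^-1 (no pH term).
#' @param net_protons_released product-side minus reactant-side protons.
#' @param pH solution pH in \[0, 14\].
#' @param constants a [cu_constants()] object.
#' @return adjusted free energy, kJ mol^-1.
#' @examples
#' ph_adjust(22.0, 1, 7) # ~ -18.0
#' @export
ph_adjust <- function(dG_aq, net_protons_released, pH = 7,
                      constants = cu_constants()) {
  stopifnot(is.numeric(dG_aq), is.numeric(pH))
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  dG_aq - net_protons_released * rt_ln10_kjmol(constants) * pH
}

#' Relative stability of two products sharing the same reactants
#'
#' For two formation reactions with identical reactant sides,
#' `dG_aq(A) - dG_aq(B)` measures how much less stable the product of A is
#' than the product of B. When `reaction` objects are supplied the shared
#' reactant side is verified; with raw numbers the check is skipped.
#'
#' @param rxnA,rxnB either aqueous free energies (kJ mol^-1) or lists with
#'   `dG_aq` plus an optional `reaction` element for checking.
#' @return kJ mol^-1 by which A's product is less stable than B's.
#' @examples
#' stability_difference(14.3, -18.0) # 32.3
#' @export
stability_difference <- function(rxnA, rxnB) {
  get_parts <- function(x) {
    if (is.numeric(x)) return(list(dG = x, rxn = NULL))
    list(dG = x$dG_aq, rxn = x$reaction)
  }
  a <- get_parts(rxnA); b <- get_parts(rxnB)
  if (!is.null(a$rxn) && !is.null(b$rxn)) {
    ra <- a$rxn$reactants[order(names(a$rxn$reactants))]
    rb <- b$rxn$reactants[order(names(b$rxn$reactants))]
    if (!identical(ra, rb)) {
      stop("reactions '", a$rxn$label, "' and '", b$rxn$label,
           "' do not share the same reactant side")
    }
  }
  a$dG - b$dG
}
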