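#' Specification for a seeded synthetic thermochemistry dataset
#'
#' Describes the statistical shape of a species-level input table:
#' electronic energies on the order of -10^3 hartree (so hartree-vs-kJ/mol
#' unit mistakes surface as order-of-magnitude failures), zero-point
#' energies below 1 hartree, thermal corrections below 0.1 hartree, gas
#' entropies of 100-1000 J mol^-1 K^-1, and solvation free energies whose
#' magnitude grows with the square of the charge, as continuum models
#' predict for small ions.
#'
#' @param seed integer seed; the same seed always yields a byte-identical
#'   dataset.
#' @param n_species number of normal species to generate (>= 1); the
#'   proton, water and electron pseudo-species are always appended.
#' @param charge_range integer vector `c(min, max)` of allowed charges.
#' @param element_palette elements to draw compositions from.
#' @param n_conf_max maximum conformer count.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_species = 25L,
                           charge_range = c(-2L, 2L),
                           element_palette = c("C", "H", "N", "O", "Cu"),
                           n_conf_max = 8L) {
  if (n_species < 1L) stop("n_species must be >= 1")
  stopifnot(length(charge_range) == 2L, charge_range[1] <= charge_range[2],
            n_conf_max >= 1L)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 charge_range = as.integer(charge_range),
                 element_palette = element_palette,
                 n_conf_max = as.integer(n_conf_max)),
            class = "synthetic_spec")
}

# Solvation magnitude bands by |charge|: neutral species sit well below
# singly charged ones, which sit below doubly charged ones, so the
# charge^2 ordering is a by-construction property, not a tendency.
synth_dg_solv <- function(charge) {
  base <- switch(as.character(abs(charge)),
                 "0" = stats::runif(1, 5, 90),
                 "1" = stats::runif(1, 150, 400),
                 stats::runif(1, 500, 1190))
  -base
}

#' Generate a seeded species set
#'
#' Draws `n_species` normal species plus the proton, water and electron
#' pseudo-species, each satisfying every [species_thermo()] invariant.
#' Compositions always contain hydrogen and at least one heavy atom so
#' that proton- and water-shedding reactions can be composed from them.
#'
#' @param spec a [synthetic_spec()].
#' @return named list of [species_thermo()] records.
#' @examples
#' db <- generate_species(synthetic_spec(seed = 7, n_species = 5))
#' length(db) # 5 + 3 special records
#' @export
generate_species <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- withr_seed(spec$seed, {
    lapply(seq_len(spec$n_species), function(i) {
      heavy <- setdiff(spec$element_palette, "H")
      n_heavy <- sample(1:3, 1)
      elems <- sample(heavy, n_heavy)
      comp <- stats::setNames(sample(1:12, n_heavy, replace = TRUE), elems)
      comp <- c(comp, H = sample(4:30, 1))
      charge <- sample(spec$charge_range[1]:spec$charge_range[2], 1)
      e_sb <- -stats::runif(1, 500, 2500)
      species_thermo(
        id = sprintf("syn%03d", i), formula = comp, charge = charge,
        e_b3lyp_sb = e_sb,
        e_b3lyp_lb = e_sb - stats::runif(1, 0.05, 0.6),
        e_mp2_sb = e_sb + stats::rnorm(1, 0, 0.3),
        zpe = stats::runif(1, 0.02, 1),
        h_thermal = stats::runif(1, 0.002, 0.1),
        s_gas = stats::runif(1, 100, 1000),
        n_conf = sample(seq_len(spec$n_conf_max), 1),
        dg_solv = synth_dg_solv(charge),
        role = "normal"
      )
    })
  })
  out <- stats::setNames(out, vapply(out, `[[`, character(1), "id"))
  c(out, list(`H+` = proton_species(), H2O = water_species(), `e-` = electron_species()))
}

#' Generate balanced reactions over a species set
#'
#' Each reaction draws one or two reactants from the set and forms a single
#' new product species whose composition is the reactant total minus any
#' emitted waters and protons, so element and charge balance hold by
#' construction. A requested fraction of reactions are reduction-shaped:
#' one electron on the reactant side and a copper-containing species on
#' both sides. Newly created product species are appended to the returned
#' species set with their own synthetic energetics.
#'
#' @param species_db named list of [species_thermo()] records (from
#'   [generate_species()]).
#' @param seed integer seed.
#' @param n_reactions number of reactions to build.
#' @param p_reduction fraction of reactions built as one-electron copper
#'   reductions (subject to a copper species being available).
#' @return list with `reactions` (named list of [reaction()] objects) and
#'   `species` (the input set plus generated products).
#' @export
generate_reactions <- function(species_db, seed = 1L, n_reactions = 20L,
                               p_reduction = 0.25) {
  normals <- names(species_db)[vapply(species_db, function(s) s$role == "normal", logical(1))]
  if (!length(normals)) stop("species_db contains no normal species")
  rxns <- list()
  withr_seed(seed, {
    for (k in seq_len(n_reactions)) {
      want_red <- stats::runif(1) < p_reduction
      cu_ids <- normals[vapply(normals, function(id) {
        "Cu" %in% names(species_db[[id]]$composition)
      }, logical(1))]
      if (want_red && !length(cu_ids)) want_red <- FALSE
      first <- if (want_red) sample(cu_ids, 1) else sample(normals, 1)
      ids <- unique(c(first, sample(normals, sample(0:1, 1))))
      coeffs <- stats::setNames(sample(1:2, length(ids), replace = TRUE), ids)
      tot_comp <- stats::setNames(integer(0), character(0))
      tot_charge <- 0L
      for (id in ids) {
        tot_comp <- add_compositions(tot_comp, species_db[[id]]$composition * coeffs[[id]])
        tot_charge <- tot_charge + coeffs[[id]] * species_db[[id]]$charge
      }
      products <- stats::setNames(numeric(0), character(0))
      # emit waters while H and O allow
      n_w <- sample(0:3, 1)
      avail_O <- if ("O" %in% names(tot_comp)) tot_comp[["O"]] else 0L
      avail_H <- if ("H" %in% names(tot_comp)) tot_comp[["H"]] else 0L
      n_w <- min(n_w, avail_O, (avail_H - 2L) %/% 2L)
      if (n_w > 0) {
        tot_comp <- add_compositions(tot_comp, c(H = 2L * n_w, O = n_w), sign = -1L)
        products["H2O"] <- n_w
      }
      # maybe emit a proton
      emit_h <- !want_red && stats::runif(1) < 0.4 &&
        ("H" %in% names(tot_comp)) && tot_comp[["H"]] > 1L
      if (emit_h) {
        tot_comp <- add_compositions(tot_comp, c(H = 1L), sign = -1L)
        tot_charge <- tot_charge - 1L
        products["H+"] <- 1
      }
      electrons <- if (want_red) 1L else 0L
      prod_charge <- tot_charge - electrons
      pid <- sprintf("prod%03d", k)
      e_sb <- -stats::runif(1, 500, 2500)
      species_db[[pid]] <- species_thermo(
        id = pid, formula = tot_comp, charge = prod_charge,
        e_b3lyp_sb = e_sb, e_b3lyp_lb = e_sb - stats::runif(1, 0.05, 0.6),
        e_mp2_sb = e_sb + stats::rnorm(1, 0, 0.3),
        zpe = stats::runif(1, 0.02, 1), h_thermal = stats::runif(1, 0.002, 0.1),
        s_gas = stats::runif(1, 100, 1000), n_conf = sample(1:8, 1),
        dg_solv = synth_dg_solv(prod_charge), role = "normal"
      )
      products[pid] <- 1
      rxns[[sprintf("synrxn%03d", k)]] <- reaction(
        sprintf("synrxn%03d", k), coeffs, products, electrons = electrons,
        description = if (want_red) "reduction-shaped" else "association-shaped"
      )
    }
  })
  list(reactions = rxns, species = species_db)
}

#' Independent brute-force reaction thermochemistry oracle
#'
#' Recomputes every reaction-level quantity with a deliberately naive,
#' self-contained code path: all per-species arithmetic is written out
#' inline here and shares no helper with [reaction_thermo()] or the
#' species-layer functions. Used to cross-check the engine on synthetic
#' reactions where the answer is known by construction.
#'
#' @param rxn a [reaction()].
#' @param species_db named list of [species_thermo()] records.
#' @param constants a [cu_constants()] object.
#' @return list with `dH_g`, `minus_TdS_g`, `dG_g`, `ddG_solv`, `dG_aq`.
#' @export
oracle_reaction_thermo <- function(rxn, species_db, constants = cu_constants()) {
  acc <- c(dH_g = 0, minus_TdS_g = 0, dG_g = 0, ddG_solv = 0, dG_aq = 0)
  one_side <- function(side, sgn) {
    for (id in names(side)) {
      s <- species_db[[id]]
      if (is.null(s)) stop("unknown species id: ", id)
      k <- sgn * side[[id]]
      if (s$role == "electron") next
      e_comp <- s$e_mp2_sb + s$e_b3lyp_lb - s$e_b3lyp_sb
      h <- constants$hartree_to_kjmol * (e_comp + constants$zpe_scale * s$zpe + s$h_thermal)
      s_corr <- s$s_gas + constants$R * log(s$n_conf) +
        constants$R * log(1 / constants$standard_volume)
      g <- h - constants$temperature * s_corr / 1000
      dgs <- if (s$role == "proton") constants$dGsolv_proton else
        if (s$role == "water") constants$dGsolv_water else s$dg_solv
      acc["dH_g"] <<- acc["dH_g"] + k * h
      acc["minus_TdS_g"] <<- acc["minus_TdS_g"] + k * (-constants$temperature * s_corr / 1000)
      acc["dG_g"] <<- acc["dG_g"] + k * g
      acc["ddG_solv"] <<- acc["ddG_solv"] + k * dgs
      acc["dG_aq"] <<- acc["dG_aq"] + k * (g + dgs)
    }
  }
  one_side(rxn$products, 1)
  one_side(rxn$reactants, -1)
  as.list(acc)
}

# Evaluate expr under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
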