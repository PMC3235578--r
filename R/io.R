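#' Read and write species tables
#'
#' The species table dialect is a TSV with header
#' `id formula charge e_b3lyp_sb e_b3lyp_lb e_mp2_sb zpe h_thermal s_gas
#' n_conf dg_solv role`; energies in hartree, `s_gas` in J mol^-1 K^-1,
#' `dg_solv` in kJ mol^-1, formulas in Hill order with the charge kept in
#' its own column. Unicode minus signs are accepted in every numeric cell
#' and normalized to ASCII; output always uses ASCII. Malformed rows are
#' reported with their line number and the violated constraint.
#'
#' @param path file path.
#' @param species_db named list of [species_thermo()] records (writer).
#' @param header_comment optional `#` comment line written above the
#'   header (e.g. the generating seed).
#' @return `read_species_table`: named list of [species_thermo()] records;
#'   `write_species_table`: the path, invisibly.
#' @export
read_species_table <- function(path) {
  cols <- c("id", "formula", "charge", "e_b3lyp_sb", "e_b3lyp_lb", "e_mp2_sb",
            "zpe", "h_thermal", "s_gas", "n_conf", "dg_solv", "role")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "#", check.names = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("species table '", path, "': missing column(s): ", paste(miss, collapse = ", "))
  }
  num_cols <- c("charge", "e_b3lyp_sb", "e_b3lyp_lb", "e_mp2_sb", "zpe",
                "h_thermal", "s_gas", "n_conf", "dg_solv")
  recs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- as.list(df[i, ])
    for (cc in num_cols) {
      v <- suppressWarnings(as.numeric(normalize_minus(vals[[cc]])))
      if (is.na(v)) {
        stop("species table '", path, "', row ", i, ", column '", cc,
             "': non-numeric value '", df[i, cc], "'")
      }
      vals[[cc]] <- v
    }
    recs[[i]] <- tryCatch(
      species_thermo(vals$id, vals$formula, vals$charge,
                     vals$e_b3lyp_sb, vals$e_b3lyp_lb, vals$e_mp2_sb,
                     vals$zpe, vals$h_thermal, vals$s_gas, vals$n_conf,
                     vals$dg_solv, vals$role),
      error = function(e) stop("species table '", path, "', row ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
}

#' @rdname read_species_table
#' @export
write_species_table <- function(species_db, path, header_comment = NULL) {
  df <- do.call(rbind, lapply(species_db, function(s) {
    data.frame(id = s$id, formula = format_formula(s$composition),
               charge = s$charge,
               e_b3lyp_sb = s$e_b3lyp_sb, e_b3lyp_lb = s$e_b3lyp_lb,
               e_mp2_sb = s$e_mp2_sb, zpe = s$zpe, h_thermal = s$h_thermal,
               s_gas = s$s_gas, n_conf = s$n_conf, dg_solv = s$dg_solv,
               role = s$role, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write reaction definition files
#'
#' Reactions are stored as a YAML list; each entry carries `label`,
#' `reactants` and `products` maps (species id -> coefficient), an
#' `electrons` count (reactant side) and an optional `description`.
#'
#' @param path file path.
#' @param reactions named list of [reaction()] objects (writer).
#' @return `read_reactions`: named list of [reaction()] objects.
#' @export
read_reactions <- function(path) {
  entries <- yaml::read_yaml(path)
  if (!length(entries)) return(stats::setNames(list(), character(0)))
  rxns <- lapply(entries, function(e) {
    if (is.null(e$label)) stop("reaction file '", path, "': entry without a label")
    as_side <- function(x) {
      if (is.null(x) || !length(x)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
    }
    reaction(e$label, as_side(e$reactants), as_side(e$products),
             electrons = if (is.null(e$electrons)) 0L else e$electrons,
             description = if (is.null(e$description)) "" else e$description)
  })
  stats::setNames(rxns, vapply(rxns, `[[`, character(1), "label"))
}

#' @rdname read_reactions
#' @export
write_reactions <- function(reactions, path) {
  entries <- lapply(reactions, function(r) {
    list(label = r$label,
         reactants = as.list(r$reactants),
         products = as.list(r$products),
         electrons = r$electrons,
         description = r$description)
  })
  yaml::write_yaml(unname(entries), path)
  invisible(path)
}

#' Run configuration for the analysis pipeline
#'
#' A validated bundle of run settings, serializable to/from one YAML file.
#' Unknown keys are rejected so that a typo in a config never silently
#' falls back to a default.
#'
#' @param species_file,reactions_file input paths (NULL to use the packaged
#'   dataset).
#' @param out_dir output directory for the report tables.
#' @param temperature K; `pH`; `cu_correction` logical; `digits` report
#'   rounding for the paper-rounded columns; `seed` integer;
#'   `constant_overrides` named list forwarded to [cu_constants()].
#' @param pH,cu_correction,digits,seed,constant_overrides see above.
#' @return object of class `run_config`.
#' @export
run_config <- function(species_file = NULL, reactions_file = NULL,
                       out_dir = NULL, temperature = 298.15, pH = 7,
                       cu_correction = TRUE, digits = 1, seed = 1L,
                       constant_overrides = list()) {
  cfg <- list(species_file = species_file, reactions_file = reactions_file,
              out_dir = out_dir, temperature = temperature, pH = pH,
              cu_correction = isTRUE(cu_correction), digits = digits,
              seed = as.integer(seed), constant_overrides = constant_overrides)
  if (cfg$pH < 0 || cfg$pH > 14) stop("pH must lie in [0, 14]")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read or write.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("config '", path, "': unknown key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full reaction-thermochemistry pipeline
#'
#' Reads a species table and reaction file (or operates on in-memory
#' objects), validates every reaction's balance, computes the five-column
#' reaction thermochemistry, the pH-adjusted free energies, and a redox
#' report for the electron-transfer reactions. Both unrounded and
#' report-rounded columns are returned so tolerance decisions stay
#' auditable. With `out_dir` set, TSV reports are written there.
#'
#' @param config a [run_config()].
#' @param species_db,reactions optional in-memory inputs overriding the
#'   configured paths.
#' @return list with `thermo` (data.frame, one row per reaction),
#'   `redox` (data.frame for electron-transfer rows, possibly empty),
#'   `constants` (the constants actually used) and `n_reactions`.
#' @export
run_pipeline <- function(config = run_config(), species_db = NULL, reactions = NULL) {
  stopifnot(inherits(config, "run_config"))
  const_args <- utils::modifyList(list(temperature = config$temperature),
                                  config$constant_overrides)
  constants <- do.call(cu_constants, const_args)
  if (is.null(species_db)) {
    if (is.null(config$species_file)) stop("no species input configured")
    species_db <- read_species_table(config$species_file)
  }
  if (is.null(reactions)) {
    if (is.null(config$reactions_file)) stop("no reaction input configured")
    reactions <- read_reactions(config$reactions_file)
  }
  if (!length(reactions)) {
    return(list(thermo = data.frame(), redox = data.frame(),
                constants = constants, n_reactions = 0L))
  }
  rows <- lapply(reactions, function(r) {
    th <- reaction_thermo(r, species_db, constants)
    dG_ph <- ph_adjust(th$dG_aq, th$net_protons_released, config$pH, constants)
    data.frame(label = r$label, dH_g = th$dH_g, minus_TdS_g = th$minus_TdS_g,
               dG_g = th$dG_g, ddG_solv = th$ddG_solv, dG_aq = th$dG_aq,
               net_protons_released = th$net_protons_released,
               electrons = r$electrons, dG_aq_pH = dG_ph,
               stringsAsFactors = FALSE)
  })
  thermo <- do.call(rbind, rows)
  rownames(thermo) <- NULL
  num <- c("dH_g", "minus_TdS_g", "dG_g", "ddG_solv", "dG_aq", "dG_aq_pH")
  for (cc in num) thermo[[paste0(cc, "_rounded")]] <- round_half_away(thermo[[cc]], config$digits)
  red <- thermo[thermo$electrons > 0, ]
  redox <- if (nrow(red)) {
    redox_report(red$label, red$dG_aq,
                 n_protons_consumed = pmax(0L, -red$net_protons_released),
                 apply_cu_correction = config$cu_correction, pH = config$pH,
                 constants = constants)
  } else {
    data.frame()
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(thermo, file.path(config$out_dir, "reaction_thermo.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(redox)) {
      utils::write.table(redox, file.path(config$out_dir, "redox_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(thermo = thermo, redox = redox, constants = constants,
       n_reactions = nrow(thermo))
}

# Round half away from zero at `digits` decimals (the convention used for
# comparisons against typeset tables; R's round() rounds half to even).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a complete synthetic bundle to disk
#'
#' Emits a seeded species table, reaction file, and ground-truth answer
#' table (computed with the brute-force oracle) into a directory, so the
#' whole pipeline can be exercised from files alone.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in every header.
#' @param n_species,n_reactions dataset size.
#' @return (invisibly) list of the three file paths.
#' @export
write_synthetic_bundle <- function(out_dir, seed = 1L, n_species = 25L,
                                   n_reactions = 20L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db <- generate_species(synthetic_spec(seed = seed, n_species = n_species))
  gen <- generate_reactions(db, seed = seed, n_reactions = n_reactions)
  sp_path <- file.path(out_dir, "species.tsv")
  rxn_path <- file.path(out_dir, "reactions.yaml")
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  write_species_table(gen$species, sp_path, header_comment = paste("seed:", seed))
  write_reactions(gen$reactions, rxn_path)
  truth <- do.call(rbind, lapply(gen$reactions, function(r) {
    o <- oracle_reaction_thermo(r, gen$species)
    data.frame(label = r$label, dH_g = o$dH_g, minus_TdS_g = o$minus_TdS_g,
               dG_g = o$dG_g, ddG_solv = o$ddG_solv, dG_aq = o$dG_aq,
               stringsAsFactors = FALSE)
  }))
  con <- file(truth_path, "w")
  writeLines(paste("# seed:", seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(list(species = sp_path, reactions = rxn_path, truth = truth_path))
}
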