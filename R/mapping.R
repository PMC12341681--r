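# Mapping kinetic reactions onto constraint-based reactions and translating
# steady-state kinetic fluxes (mM s^-1) into flux bounds (mmol gDW^-1 h^-1).

# Base name of a metabolite id with a trailing compartment suffix removed
# ("accoa_c" -> "accoa"); ids without a suffix pass through. Lower-cased for
# matching only; ids themselves are never rewritten.
base_species <- function(id) {
  tolower(sub("_[A-Za-z0-9]{1,2}$", "", id))
}

.small_species <- c("h", "h+", "proton", "h2o", "water")

norm_stoich <- function(st, drop_small = FALSE, merge_bicarbonate = FALSE) {
  st <- st[st != 0]
  if (drop_small) st <- st[!(base_species(names(st)) %in% .small_species)]
  if (merge_bicarbonate) {
    nm <- names(st)
    nm[base_species(nm) == "hco3"] <- sub("(?i)hco3", "co2", nm[base_species(nm) == "hco3"], perl = TRUE)
    st <- tapply(st, nm, sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[st != 0]
  }
  st[order(names(st))]
}

stoich_equal <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(names(a) == names(b)) &&
    all(abs(a - b) <= tol)
}

#' Classify a kinetic/constraint reaction pair into a mapping category
#'
#' Compares stoichiometries and reversibility flags and assigns one of the
#' mapping categories:
#' \describe{
#'   \item{C0}{identical reaction (same reactants, products, coefficients,
#'     orientation, reversibility).}
#'   \item{C1}{identical after ignoring the small species H+ and H2O.}
#'   \item{C2}{identical after additionally identifying bicarbonate (HCO3-)
#'     with CO2 (acid hydrolysis difference).}
#'   \item{C3}{same equation but the reversibility flags differ.}
#'   \item{C4}{reactants and products are swapped between the two models.}
#'   \item{C5}{not mappable one-to-one (subnetworks of different
#'     structure); a legal return, not an error.}
#' }
#' When the stoichiometries differ by small species (C1/C2) and the
#' reversibility flags also differ, the structural category (C1/C2) is
#' returned; C3 is reserved for pairs whose equations match exactly.
#'
#' @param kin_rxn,cbm_rxn reaction descriptions: lists with `stoich` (named
#'   signed numeric) and `reversible` (logical), as returned by
#'   [kin_reaction()] / [cb_reaction()].
#' @return a single string: `"C0"` ... `"C5"`.
#' @examples
#' k <- list(stoich = c(fdp_c = -1, f6p_c = 1, pi_c = 1), reversible = FALSE)
#' g <- list(stoich = c(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1),
#'           reversible = FALSE)
#' classify_pair(k, g)  # "C1"
#' @export
classify_pair <- function(kin_rxn, cbm_rxn) {
  k <- kin_rxn$stoich; b <- cbm_rxn$stoich
  if (!length(k) || !length(b)) stop("empty stoichiometry")
  rev_same <- isTRUE(kin_rxn$reversible) == isTRUE(cbm_rxn$reversible)
  k0 <- norm_stoich(k);                 b0 <- norm_stoich(b)
  k1 <- norm_stoich(k, TRUE);           b1 <- norm_stoich(b, TRUE)
  k2 <- norm_stoich(k, TRUE, TRUE);     b2 <- norm_stoich(b, TRUE, TRUE)
  if (stoich_equal(k0, b0)) return(if (rev_same) "C0" else "C3")
  if (stoich_equal(k1, b1)) return("C1")
  if (stoich_equal(k2, b2)) return("C2")
  if (stoich_equal(k2, -b2) || stoich_equal(k1, -b1) ||
      stoich_equal(k0, -b0)) return("C4")
  "C5"
}

#' Convert a kinetic flux to genome-scale model units
#'
#' The kinetic model expresses fluxes in mM s^-1, the constraint-based
#' model in mmol gDW^-1 h^-1. With a cell volume of 1.77e-3 L gDW^-1,
#' f mM s^-1 * 1.77e-3 L gDW^-1 * 3600 s h^-1 = 6.372 f mmol gDW^-1 h^-1.
#'
#' @param f flux in mM s^-1 (vectorised).
#' @param cell_volume specific cell volume in L gDW^-1; default 1.77e-3.
#' @return flux in mmol gDW^-1 h^-1.
#' @export
convert_flux_units <- function(f, cell_volume = 1.77e-3) {
  if (any(cell_volume <= 0)) stop("cell_volume must be positive")
  f * cell_volume * 3600
}

#' @rdname convert_flux_units
#' @export
flux_conversion_factor <- function(cell_volume = 1.77e-3) {
  convert_flux_units(1, cell_volume)
}

#' Kinetic flux bounds for a constraint-based reaction
#'
#' Translates a steady-state kinetic flux f into a flux-bound interval with
#' relative uncertainty d: L = c (1 - d) f, U = c (1 + d) f, where c is the
#' unit conversion factor. For category C4 (reversed orientation) the
#' interval is mirrored: L = -c (1 + d) f, U = -c (1 - d) f. The interval
#' midpoint is c f (resp. -c f), and intervals nest as d grows.
#'
#' @param f kinetic flux in mM s^-1; must be nonnegative (kinetic fluxes
#'   are positive by convention; reversed orientation is expressed through
#'   the category, not the sign).
#' @param d relative uncertainty, 0 <= d < 1 (d = 0 pins the flux).
#' @param category mapping category `"C0"` ... `"C4"`; C0-C3 translate
#'   directly, C4 mirrors the interval.
#' @param reaction_id optional constraint-model reaction id recorded in the
#'   result.
#' @param cell_volume passed to [convert_flux_units()].
#' @return a one-row `bound_assignment` data.frame with columns
#'   `reaction_id`, `lower`, `upper`, `source` (`"kinetic"`), `d`, `f`,
#'   `category`.
#' @export
kinetic_bounds <- function(f, d, category = "C0", reaction_id = NA_character_,
                           cell_volume = 1.77e-3) {
  if (f < 0) stop("kinetic flux must be nonnegative (got ", f,
                  "); reversed reactions use category C4")
  if (d < 0 || d >= 1) stop("uncertainty d must satisfy 0 <= d < 1 (got ",
                            d, ")")
  if (!category %in% paste0("C", 0:4)) {
    stop("category must be one of C0-C4 (C5 entries go through ",
         "translate_c5_subnetwork)")
  }
  cf <- convert_flux_units(f, cell_volume)
  if (category == "C4") {
    lo <- -(1 + d) * cf; hi <- -(1 - d) * cf
  } else {
    lo <- (1 - d) * cf; hi <- (1 + d) * cf
  }
  data.frame(reaction_id = reaction_id, lower = lo, upper = hi,
             source = "kinetic", d = d, f = f, category = category,
             stringsAsFactors = FALSE)
}

#' Surrogate flux-bound translation for C5 subnetwork mappings
#'
#' C5 entries map a set of kinetic reactions onto constraint-based
#' reactions of different structure, so no single kinetic flux applies.
#' This heuristic bounds each constraint-side reaction by the net
#' steady-state kinetic flux across the metabolites it shares with the
#' kinetic subnetwork's boundary: net(m) = sum_k S_kin(m, k) f(k); the
#' implied flux through constraint reaction r is net(m) / S_cbm(m, r),
#' reconciled by the median over shared metabolites. Nonnegative implied
#' fluxes are translated like C0 (see [kinetic_bounds()]); negative ones
#' are routed through the C4 (mirrored) formula.
#'
#' @param entry one mapping entry: list (or one-row data.frame) with
#'   `kinetic_ids` and `cbm_ids` (character vectors, or
#'   semicolon-separated strings).
#' @param kinetic_model the `kinetic_model` supplying stoichiometry.
#' @param constraint_model the `constraint_model` supplying stoichiometry.
#' @param fluxes named kinetic flux vector (mM s^-1) or a
#'   `steady_state_result`.
#' @param d relative uncertainty, as in [kinetic_bounds()].
#' @param cell_volume passed to [convert_flux_units()].
#' @return a `bound_assignment` data.frame, one row per constraint-side
#'   reaction. Errors if a constraint reaction shares no boundary
#'   metabolite with the kinetic subnetwork.
#' @export
translate_c5_subnetwork <- function(entry, kinetic_model, constraint_model,
                                    fluxes, d, cell_volume = 1.77e-3) {
  if (inherits(fluxes, "steady_state_result")) fluxes <- fluxes$fluxes
  split_ids <- function(x) {
    if (is.character(x) && length(x) == 1) trimws(strsplit(x, ";")[[1]]) else x
  }
  kin_ids <- split_ids(entry$kinetic_ids)
  cbm_ids <- split_ids(entry$cbm_ids)
  Sk <- kin_stoichiometry(kinetic_model)
  unknown <- setdiff(kin_ids, colnames(Sk))
  if (length(unknown)) stop("unknown kinetic reaction(s): ", toString(unknown))
  fk <- fluxes[kin_ids]
  if (anyNA(fk)) stop("missing kinetic flux for: ",
                      toString(kin_ids[is.na(fk)]))
  net <- as.numeric(Sk[, kin_ids, drop = FALSE] %*% fk)
  names(net) <- rownames(Sk)
  boundary <- names(net)[abs(net) > 1e-12]
  out <- lapply(cbm_ids, function(r) {
    st <- cb_reaction(constraint_model, r)$stoich
    shared <- intersect(boundary, names(st))
    if (!length(shared)) {
      if (length(boundary) == 0) {           # zero net flux everywhere
        return(kinetic_bounds(0, d, "C0", r, cell_volume))
      }
      stop("C5 entry: constraint reaction ", r,
           " shares no boundary metabolite with kinetic reactions ",
           toString(kin_ids))
    }
    est <- stats::median(net[shared] / st[shared])
    if (est >= 0) kinetic_bounds(est, d, "C0", r, cell_volume)
    else kinetic_bounds(-est, d, "C4", r, cell_volume)
  })
  out <- do.call(rbind, out)
  out$category <- "C5"
  out
}

#' Translate a whole mapping table into bound assignments
#'
#' Applies [kinetic_bounds()] to every one-to-one (C0-C4) mapping entry and
#' [translate_c5_subnetwork()] to C5 entries, preserving the table's row
#' order (which is also the default enrichment-sweep order).
#'
#' @param mapping a mapping data.frame with columns `kinetic_ids`,
#'   `cbm_ids`, `category` (see [read_mapping()]).
#' @param fluxes named kinetic flux vector (mM s^-1) or a
#'   `steady_state_result`.
#' @param d relative uncertainty.
#' @param kinetic_model,constraint_model required only if the table has C5
#'   entries.
#' @param cell_volume passed to [convert_flux_units()].
#' @return a `bound_assignment` data.frame (one row per constraint-side
#'   reaction).
#' @export
translate_bounds <- function(mapping, fluxes, d,
                             kinetic_model = NULL, constraint_model = NULL,
                             cell_volume = 1.77e-3) {
  if (inherits(fluxes, "steady_state_result")) fluxes <- fluxes$fluxes
  validate_mapping(mapping)
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    entry <- mapping[i, ]
    if (entry$category == "C5") {
      if (is.null(kinetic_model) || is.null(constraint_model)) {
        stop("C5 entries need kinetic_model and constraint_model")
      }
      translate_c5_subnetwork(entry, kinetic_model, constraint_model,
                              fluxes, d, cell_volume)
    } else {
      kin_id <- trimws(strsplit(entry$kinetic_ids, ";")[[1]])
      cbm_id <- trimws(strsplit(entry$cbm_ids, ";")[[1]])
      f <- fluxes[[kin_id]]
      if (is.null(f) || is.na(f)) stop("missing kinetic flux for ", kin_id)
      kinetic_bounds(f, d, entry$category, cbm_id, cell_volume)
    }
  })
  do.call(rbind, rows)
}

#' Apply bound assignments to a constraint-based model
#'
#' Returns a copy of the model with the listed reactions' bounds replaced;
#' all other reactions keep their original bounds and the input model is
#' not mutated. A `bound_source` column on the reaction table records which
#' bounds are kinetic.
#'
#' @param model a `constraint_model`.
#' @param assignments a `bound_assignment` data.frame (columns
#'   `reaction_id`, `lower`, `upper`; e.g. from [translate_bounds()]).
#' @return the modified `constraint_model`.
#' @export
apply_bounds <- function(model, assignments) {
  validate_constraint_model(model)
  if (!"bound_source" %in% names(model$reactions)) {
    model$reactions$bound_source <- "original"
  }
  if (is.null(assignments) || nrow(assignments) == 0) return(model)
  idx <- match(assignments$reaction_id, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ",
         toString(assignments$reaction_id[is.na(idx)]))
  }
  bad <- assignments$lower > assignments$upper
  if (any(bad)) {
    stop("assignment with lower > upper for: ",
         toString(assignments$reaction_id[bad]))
  }
  model$reactions$lower[idx] <- assignments$lower
  model$reactions$upper[idx] <- assignments$upper
  src <- if ("source" %in% names(assignments)) assignments$source else "kinetic"
  model$reactions$bound_source[idx] <- src
  validate_constraint_model(model)
  model
}

#' Read / write / validate a reaction mapping table
#'
#' The mapping table is a CSV with columns `kinetic_ids` and `cbm_ids`
#' (semicolon-separated reaction ids), `category` (`C0` ... `C5`) and
#' `note`. Categories C0-C4 must be one-to-one (exactly one id per side);
#' C5 entries may relate several reactions. Mapping tables are curated by
#' the user; [classify_pair()] validates individual pairs.
#'
#' @param path file path.
#' @param mapping a mapping data.frame.
#' @return `read_mapping` returns the validated data.frame;
#'   `write_mapping` returns `path` invisibly.
#' @export
read_mapping <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"note" %in% names(df)) df$note <- ""
  validate_mapping(df)
}

#' @rdname read_mapping
#' @export
write_mapping <- function(mapping, path) {
  validate_mapping(mapping)
  utils::write.csv(mapping, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname read_mapping
#' @export
validate_mapping <- function(mapping) {
  need <- c("kinetic_ids", "cbm_ids", "category")
  miss <- setdiff(need, names(mapping))
  if (length(miss)) stop("mapping lacks columns: ", toString(miss))
  ok <- mapping$category %in% paste0("C", 0:5)
  if (!all(ok)) stop("invalid category: ", toString(mapping$category[!ok]))
  n_k <- lengths(strsplit(mapping$kinetic_ids, ";"))
  n_c <- lengths(strsplit(mapping$cbm_ids, ";"))
  one <- mapping$category != "C5"
  if (any(n_k[one] != 1 | n_c[one] != 1)) {
    stop("categories C0-C4 must map exactly one reaction to one reaction")
  }
  if (any(n_k == 0 | n_c == 0)) stop("empty id list in mapping entry")
  invisible(mapping)
}
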