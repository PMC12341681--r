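#' Integrate a kinetic model to steady state
#'
#' Integrates the ODE system d[x]/dt = S f(x) (boundary species held
#' constant) from the model's initial concentrations until `t_end` and
#' checks steadiness as the largest absolute concentration derivative at
#' the final time. If the criterion is not met, the horizon is extended
#' once by a factor of 10 before the result is declared non-converged.
#'
#' @param model a `kinetic_model`.
#' @param t_end simulation horizon in seconds; default 3600.
#' @param tol steadiness tolerance in mM s^-1; default 1e-6.
#' @param atol,rtol integrator (lsoda) error-control tolerances.
#' @param extend_once logical; extend the horizon 10x once if steadiness has
#'   not been reached at `t_end` (default TRUE).
#' @return A `steady_state_result`: list with `concentrations` (mM, named),
#'   `fluxes` (mM s^-1, named, rate laws evaluated at the final state),
#'   `final_time` (s), `steadiness` (max |d[x]/dt| over non-boundary
#'   species, mM s^-1) and `converged` (logical, steadiness <= tol).
#' @examples
#' km <- kinetic_model(
#'   species = data.frame(id = "A", compartment = "c",
#'                        initial = 0, boundary = FALSE),
#'   reactions = list(
#'     list(id = "in",  stoich = c(A = 1),  rate = "k_in", params = c(k_in = 1)),
#'     list(id = "out", stoich = c(A = -1), rate = "k2 * A", params = c(k2 = 0.5))
#'   )
#' )
#' ss <- simulate_to_steady_state(km)
#' ss$concentrations  # A -> k_in / k2 = 2 mM
#' @export
simulate_to_steady_state <- function(model, t_end = 3600, tol = 1e-6,
                                     atol = 1e-10, rtol = 1e-8,
                                     extend_once = TRUE) {
  stopifnot(inherits(model, "kinetic_model"), t_end > 0)
  validate_kinetic_model(model)
  S <- kin_stoichiometry(model)
  boundary <- model$species$boundary
  y0 <- stats::setNames(model$species$initial, model$species$id)

  derivs <- function(t, y, parms) {
    y <- pmax(y, 0)                     # guard transient negative overshoot
    f <- kin_rates(model, y)
    dy <- as.numeric(S %*% f)
    dy[boundary] <- 0
    list(dy)
  }

  integrate_to <- function(y0, horizon) {
    out <- deSolve::ode(y = y0, times = c(0, horizon), func = derivs,
                        parms = NULL, method = "lsoda",
                        atol = atol, rtol = rtol)
    if (attr(out, "istate")[1] < 0 || anyNA(out[nrow(out), -1])) {
      stop("ODE integration failed; last successful time ",
           format(out[nrow(out), 1]), " s")
    }
    out[nrow(out), -1]
  }

  yT <- integrate_to(y0, t_end)
  final_time <- t_end
  steadiness_of <- function(y) {
    dy <- as.numeric(S %*% kin_rates(model, y))
    dy[boundary] <- 0
    max(abs(dy), 0)
  }
  steadiness <- steadiness_of(yT)
  if (steadiness > tol && extend_once) {
    yT <- integrate_to(yT, 9 * t_end)
    final_time <- 10 * t_end
    steadiness <- steadiness_of(yT)
  }
  neg <- yT < -1e-8
  if (any(neg)) {
    stop("negative concentration at steady state for species: ",
         toString(names(yT)[neg]))
  }
  yT <- pmax(yT, 0)
  fluxes <- kin_rates(model, yT)
  if (any(!is.finite(fluxes))) {
    stop("non-finite flux at final state for reaction(s): ",
         toString(names(fluxes)[!is.finite(fluxes)]))
  }
  structure(list(concentrations = yT, fluxes = fluxes,
                 final_time = final_time, steadiness = steadiness,
                 converged = steadiness <= tol),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("steady state at t =", x$final_time, "s;",
      if (x$converged) "converged" else "NOT converged",
      "(max |d[x]/dt| =", format(x$steadiness, digits = 3), "mM/s)\n")
  invisible(x)
}

#' Maximal rate from enzyme turnover and abundance
#'
#' Vmax = kcat * \[E\]: the maximal rate of an enzyme-catalysed reaction is
#' the product of the turnover number and the enzyme concentration.
#' Perturbing \[E\] scales Vmax proportionally, which is how enzyme
#' expression changes are emulated in the kinetic model.
#'
#' @param kcat turnover number, s^-1 (>= 0).
#' @param enzyme_conc enzyme concentration \[E\], mM (>= 0).
#' @return Vmax in mM s^-1.
#' @export
vmax_from_kcat <- function(kcat, enzyme_conc) {
  stopifnot(all(kcat >= 0), all(enzyme_conc >= 0))
  kcat * enzyme_conc
}

#' Maximal rate from per-cell enzyme activity
#'
#' Converts a measured maximal activity per cell (nmol s^-1) into a
#' volumetric Vmax (mM s^-1) by dividing by the cell volume:
#' nmol L^-1 s^-1 = 1e-6 mM s^-1, so Vmax = activity / volume * 1e-6.
#' E.g. the citramalate synthase CimA3.7 activity of 24.34e-10 nmol s^-1
#' in a 6e-16 L cell gives 4.06 mM s^-1.
#'
#' @param activity maximal activity per cell, nmol s^-1 (>= 0).
#' @param cell_volume cell volume in litres (> 0); default 6e-16.
#' @return Vmax in mM s^-1.
#' @export
compute_vmax_from_cell_activity <- function(activity, cell_volume = 6e-16) {
  stopifnot(all(activity >= 0))
  if (any(cell_volume <= 0)) stop("cell_volume must be positive")
  activity / cell_volume * 1e-6
}

#' Add the citramalate synthesis reaction to a kinetic model
#'
#' Appends CITRA_SYN: acetyl-CoA + pyruvate + H2O -> CoA + H+ + citramalate
#' with the Michaelis-Menten rate Vmax * \[AcCoA\] / (\[AcCoA\] + Km).
#' Pyruvate is assumed saturating: it appears in the stoichiometry (mass
#' balance) but not in the rate law. Citramalate (and any missing product
#' species) is added as a boundary species so the model still reaches a
#' steady state instead of accumulating product.
#'
#' @param model a `kinetic_model` containing cytoplasmic acetyl-CoA and
#'   pyruvate.
#' @param Km Michaelis constant for acetyl-CoA, mM; default 0.495.
#' @param Vmax maximal rate, mM s^-1; default 4.06 (CimA3.7; see
#'   [compute_vmax_from_cell_activity()]).
#' @param species named character vector locating the species ids in
#'   `model`: names `accoa`, `pyr`, `h2o`, `coa`, `h`, `citramalate`.
#'   Defaults follow the BiGG cytosol convention.
#' @param reaction_id id of the new reaction; default `"CITRA_SYN"`.
#' @return a modified copy of `model`.
#' @export
add_citramalate_synthesis <- function(model, Km = 0.495, Vmax = 4.06,
                                      species = c(accoa = "accoa_c",
                                                  pyr = "pyr_c",
                                                  h2o = "h2o_c",
                                                  coa = "coa_c",
                                                  h = "h_c",
                                                  citramalate = "citramalate_c"),
                                      reaction_id = "CITRA_SYN") {
  stopifnot(inherits(model, "kinetic_model"), Km > 0, Vmax >= 0)
  need <- c("accoa", "pyr", "h2o", "coa", "h", "citramalate")
  miss <- setdiff(need, names(species))
  if (length(miss)) stop("species map lacks entries: ", toString(miss))
  present <- model$species$id
  for (role in c("accoa", "pyr")) {
    if (!species[[role]] %in% present) {
      hint <- grep(substr(species[[role]], 1, 3), present,
                   value = TRUE, ignore.case = TRUE)
      stop("substrate species ", species[[role]], " (", role,
           ") not in model; candidates: ",
           if (length(hint)) toString(hint) else "(none)")
    }
  }
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (reaction_id %in% rxn_ids) stop("reaction id collision: ", reaction_id)
  # products (and water) that are absent become boundary species: constant
  # concentration, so the sink does not block the steady state
  for (sid in setdiff(species[c("h2o", "coa", "h", "citramalate")], present)) {
    model$species <- rbind(model$species,
                           data.frame(id = sid, compartment = "c",
                                      initial = if (sid == species[["h2o"]]) 1 else 0,
                                      boundary = TRUE,
                                      stringsAsFactors = FALSE))
  }
  st <- stats::setNames(c(-1, -1, -1, 1, 1, 1),
                        species[c("accoa", "pyr", "h2o", "coa", "h",
                                  "citramalate")])
  rate <- sprintf("Vmax_cs * %s / (%s + Km_cs)",
                  species[["accoa"]], species[["accoa"]])
  model$reactions <- c(model$reactions,
                       list(list(id = reaction_id, stoich = st, rate = rate,
                                 params = c(Vmax_cs = Vmax, Km_cs = Km),
                                 reversible = FALSE)))
  validate_kinetic_model(model)
  model
}

#' Growth rate from a steady-state simulation
#'
#' Reads the flux of the designated growth reaction and interprets it as a
#' specific growth rate in h^-1 (the biomass-flux convention of
#' genome-scale models; no mM s^-1 unit conversion is applied to growth).
#'
#' @param result a `steady_state_result`.
#' @param growth_reaction_id id of the growth reaction.
#' @return growth rate mu_k in h^-1.
#' @export
extract_growth_rate <- function(result, growth_reaction_id) {
  stopifnot(inherits(result, "steady_state_result"))
  if (!growth_reaction_id %in% names(result$fluxes)) {
    stop("unknown growth reaction id: ", growth_reaction_id)
  }
  unname(result$fluxes[[growth_reaction_id]])
}
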