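# Citramalate-production extension of a constraint-based model and the
# growth-interval fix that resolves the growth/product flux bifurcation.

#' Extend a constraint-based model with the citramalate pathway
#'
#' Adds four reactions: the synthase CIMA
#' (acetyl-CoA + pyruvate + H2O -> CoA + H+ + citramalate, cytosol),
#' two irreversible transport steps CitraTransp1 (cytosol -> periplasm)
#' and CitraTransp2 (periplasm -> extracellular), and the exchange
#' EX_Citramalate that removes extracellular citramalate so a steady state
#' exists. Citramalate metabolites are added in all three compartments.
#' With EX_Citramalate as the objective the LP is bounded (secretion is
#' limited by substrate uptake).
#'
#' @param model a `constraint_model` containing the cytosolic precursors.
#' @param precursors named character vector locating acetyl-CoA, pyruvate,
#'   water, CoA and protons in the cytosol; defaults follow the BiGG
#'   convention (`accoa_c`, `pyr_c`, `h2o_c`, `coa_c`, `h_c`).
#' @param compartments ids of the cytosol, periplasm and extracellular
#'   compartments, in that order; default `c("c", "p", "e")`.
#' @param bound upper bound of the added irreversible reactions; default
#'   1000.
#' @return the extended `constraint_model` (input not mutated). Errors if
#'   a precursor is missing (listing near-matching candidates) or if any
#'   added id already exists.
#' @export
extend_gem_with_citramalate <- function(model,
                                        precursors = c(accoa = "accoa_c",
                                                       pyr = "pyr_c",
                                                       h2o = "h2o_c",
                                                       coa = "coa_c",
                                                       h = "h_c"),
                                        compartments = c("c", "p", "e"),
                                        bound = 1000) {
  validate_constraint_model(model)
  need <- c("accoa", "pyr", "h2o", "coa", "h")
  miss <- setdiff(need, names(precursors))
  if (length(miss)) stop("precursor map lacks entries: ", toString(miss))
  mets <- model$metabolites$id
  absent <- precursors[!precursors %in% mets]
  if (length(absent)) {
    hints <- unlist(lapply(absent, function(p)
      grep(substr(p, 1, 3), mets, value = TRUE, ignore.case = TRUE)))
    stop("missing precursor metabolite(s): ", toString(absent),
         "; candidates: ", if (length(hints)) toString(hints) else "(none)")
  }
  new_mets <- paste0("citramalate_", compartments)
  new_rxns <- c("CIMA", "CitraTransp1", "CitraTransp2", "EX_Citramalate")
  clash <- c(intersect(new_mets, mets),
             intersect(new_rxns, model$reactions$id))
  if (length(clash)) stop("id collision with existing model: ",
                          toString(clash))

  model$metabolites <- rbind(
    model$metabolites,
    data.frame(id = new_mets, name = "(3R)-citramalate",
               compartment = compartments, stringsAsFactors = FALSE))
  extra_comp <- setdiff(compartments, model$compartments$id)
  if (length(extra_comp)) {
    model$compartments <- rbind(
      model$compartments,
      data.frame(id = extra_comp, name = extra_comp, stringsAsFactors = FALSE))
  }
  old_src <- if ("bound_source" %in% names(model$reactions))
    model$reactions$bound_source else NULL
  add <- data.frame(
    id = new_rxns,
    name = c("citramalate synthase (CimA)",
             "citramalate transport, cytosol to periplasm",
             "citramalate transport, periplasm to extracellular",
             "citramalate exchange"),
    lower = 0, upper = bound, objective_coefficient = 0,
    stringsAsFactors = FALSE)
  if (!is.null(old_src)) add$bound_source <- "original"
  model$reactions <- rbind(model$reactions, add)

  S <- rbind(model$S, matrix(0, 3, ncol(model$S),
                             dimnames = list(new_mets, colnames(model$S))))
  S <- cbind(S, matrix(0, nrow(S), 4,
                       dimnames = list(rownames(S), new_rxns)))
  cit <- new_mets
  S[precursors[["accoa"]], "CIMA"] <- -1
  S[precursors[["pyr"]], "CIMA"] <- -1
  S[precursors[["h2o"]], "CIMA"] <- -1
  S[precursors[["coa"]], "CIMA"] <- 1
  S[precursors[["h"]], "CIMA"] <- 1
  S[cit[1], "CIMA"] <- 1
  S[cit[1], "CitraTransp1"] <- -1; S[cit[2], "CitraTransp1"] <- 1
  S[cit[2], "CitraTransp2"] <- -1; S[cit[3], "CitraTransp2"] <- 1
  S[cit[3], "EX_Citramalate"] <- -1
  model$S <- S
  validate_constraint_model(model)
  model
}

#' Fix the growth rate to a kinetically derived interval
#'
#' Constrains the biomass reaction's flux to [mu_k (1 - d), mu_k (1 + d)],
#' where mu_k is the growth rate produced by the kinetic model's steady
#' state (h^-1). Fixing growth resolves the bifurcation in which FBA sends
#' all carbon either to biomass or to product: with growth pinned to a
#' positive interval, maximizing product secretion yields strictly
#' positive fluxes on both branches. The objective is left untouched (the
#' caller typically switches it to the product exchange).
#'
#' @param model a `constraint_model`.
#' @param mu_k kinetic growth rate, h^-1 (>= 0).
#' @param d relative uncertainty, 0 <= d < 1.
#' @param biomass_id biomass reaction id; by default the reaction carrying
#'   a nonzero objective coefficient, falling back to an id matching
#'   "BIOMASS" (case-insensitive).
#' @return the modified `constraint_model`. If mu_k (1 - d) exceeds the
#'   structurally attainable growth, later LPs report infeasibility; this
#'   function does not pre-empt that.
#' @export
fix_growth_interval <- function(model, mu_k, d, biomass_id = NULL) {
  validate_constraint_model(model)
  stopifnot(mu_k >= 0)
  if (d < 0 || d >= 1) stop("uncertainty d must satisfy 0 <= d < 1")
  if (is.null(biomass_id)) {
    obj <- model$reactions$id[model$reactions$objective_coefficient != 0]
    if (length(obj) == 1) {
      biomass_id <- obj
    } else {
      hit <- grep("BIOMASS", model$reactions$id, value = TRUE,
                  ignore.case = TRUE)
      if (length(hit) != 1) {
        stop("cannot identify the biomass reaction; pass biomass_id")
      }
      biomass_id <- hit
    }
  }
  apply_bounds(model, data.frame(reaction_id = biomass_id,
                                 lower = mu_k * (1 - d),
                                 upper = mu_k * (1 + d),
                                 source = "growth_interval",
                                 stringsAsFactors = FALSE))
}

#' Glucose-to-citramalate conversion efficiency
#'
#' Mass yield in grams of citramalate secreted per gram of glucose
#' consumed: (v_cit * M_cit) / (v_glc * M_glc), with molar masses
#' M_cit = 148.11 g mol^-1 (C5H8O5) and M_glc = 180.16 g mol^-1
#' (C6H12O6) by default. Both fluxes are magnitudes in mmol gDW^-1 h^-1.
#'
#' @param v_citramalate citramalate secretion flux (>= 0).
#' @param v_glucose_uptake glucose uptake flux magnitude (> 0).
#' @param m_citramalate,m_glucose molar masses, g mol^-1.
#' @return efficiency in g/g.
#' @export
conversion_efficiency <- function(v_citramalate, v_glucose_uptake,
                                  m_citramalate = 148.11,
                                  m_glucose = 180.16) {
  if (any(v_glucose_uptake <= 0)) stop("glucose uptake must be positive")
  if (any(v_citramalate < 0)) stop("citramalate flux must be nonnegative")
  (v_citramalate * m_citramalate) / (v_glucose_uptake * m_glucose)
}
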