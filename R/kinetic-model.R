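#' Construct a kinetic metabolic model
#'
#' A kinetic model couples reaction stoichiometry with explicit rate laws
#' (mass action, Michaelis-Menten, ...) over species concentrations in mM.
#' Integrating the resulting ODE system d[x]/dt = S f(x) to steady state
#' yields per-reaction fluxes in mM s^-1. Species flagged `boundary` are held
#' at their initial concentration (constant environment / sink species).
#'
#' @param species data.frame with columns `id`, `compartment`, `initial`
#'   (mM, >= 0), `boundary` (logical).
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoich` (named numeric, metabolite id -> signed coefficient),
#'   `rate` (a string: an arithmetic expression over species ids and
#'   parameter names), `params` (named numeric, local parameters; may
#'   include `Vmax` in mM s^-1), and optional `reversible` (default FALSE).
#' @param compartments data.frame with columns `id`, `name`; defaults to the
#'   distinct compartments of `species`.
#' @param parameters named numeric vector of global parameters.
#' @return An object of class `kinetic_model`.
#' @examples
#' km <- kinetic_model(
#'   species = data.frame(id = "A", compartment = "c",
#'                        initial = 0, boundary = FALSE),
#'   reactions = list(
#'     list(id = "in",  stoich = c(A = 1),  rate = "k_in", params = c(k_in = 1)),
#'     list(id = "out", stoich = c(A = -1), rate = "k2 * A", params = c(k2 = 0.5))
#'   )
#' )
#' simulate_to_steady_state(km)$fluxes
#' @export
kinetic_model <- function(species, reactions, compartments = NULL,
                          parameters = numeric(0)) {
  species <- as.data.frame(species)
  if (!"compartment" %in% names(species)) species$compartment <- "c"
  if (!"boundary" %in% names(species)) species$boundary <- FALSE
  if (!"initial" %in% names(species)) species$initial <- 0
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$params)) r$params <- numeric(0)
    if (is.null(r$reversible)) r$reversible <- FALSE
    r
  })
  if (is.null(compartments)) {
    cid <- unique(species$compartment)
    compartments <- data.frame(id = cid, name = cid, stringsAsFactors = FALSE)
  }
  model <- structure(
    list(species = species, reactions = reactions,
         compartments = as.data.frame(compartments),
         parameters = parameters),
    class = "kinetic_model"
  )
  validate_kinetic_model(model)
  model
}

#' Validate a kinetic model's invariants
#'
#' Every species referenced by a stoichiometry or rate law must be declared,
#' initial concentrations must be nonnegative, and rate laws may reference
#' only declared species and parameters.
#'
#' @param model a `kinetic_model`.
#' @return `model`, invisibly; errors name the offending reaction.
#' @export
validate_kinetic_model <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  sp <- model$species
  if (anyDuplicated(sp$id)) stop("duplicated species ids")
  if (any(sp$initial < 0)) {
    stop("negative initial concentration for species: ",
         toString(sp$id[sp$initial < 0]))
  }
  ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicated reaction ids")
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), sp$id)
    if (length(unknown)) {
      stop("reaction ", r$id, " references undeclared species: ",
           toString(unknown))
    }
    if (is.null(r$rate) || !nzchar(r$rate)) {
      stop("no rate law for reaction ", r$id)
    }
    vars <- all.vars(str2lang(r$rate))
    known <- c(sp$id, names(r$params), names(model$parameters))
    unknown <- setdiff(vars, known)
    if (length(unknown)) {
      stop("rate law of reaction ", r$id,
           " references undeclared symbols: ", toString(unknown))
    }
  }
  invisible(model)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("kinetic_model: ", length(x$reactions), " reactions, ",
      nrow(x$species), " species, ", nrow(x$compartments),
      " compartments\n", sep = "")
  nb <- sum(x$species$boundary)
  if (nb) cat(nb, "boundary species\n")
  invisible(x)
}

#' Stoichiometric matrix of a kinetic model
#'
#' @param model a `kinetic_model`.
#' @return matrix, species x reactions, signed coefficients.
#' @export
kin_stoichiometry <- function(model) {
  ids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, nrow(model$species), length(ids),
              dimnames = list(model$species$id, ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

# Evaluate all rate laws at a concentration state (named vector, mM).
# Returns fluxes in mM s^-1, named by reaction id.
kin_rates <- function(model, conc) {
  base <- as.list(c(model$parameters, conc))
  vapply(model$reactions, function(r) {
    env <- list2env(c(base, as.list(r$params)))
    v <- eval(str2lang(r$rate), envir = env)
    as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE) -> f
  stats::setNames(f, vapply(model$reactions, `[[`, "", "id"))
}

#' Extract one reaction of a kinetic model
#'
#' @param model a `kinetic_model`.
#' @param id reaction id.
#' @return the reaction's list (`id`, `stoich`, `rate`, `params`,
#'   `reversible`).
#' @export
kin_reaction <- function(model, id) {
  ids <- vapply(model$reactions, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) stop("unknown reaction id: ", id)
  model$reactions[[i]]
}
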