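#' Construct a constraint-based metabolic model
#'
#' A constraint-based model is the tuple \{R, M, S, L, U\} of reactions,
#' metabolites, stoichiometric matrix and per-reaction flux bounds, together
#' with objective weights c. Fluxes are in mmol gDW^-1 h^-1 (the biomass
#' reaction's flux is conventionally read as a specific growth rate in h^-1).
#'
#' @param reactions data.frame with columns `id`, `name`, `lower`, `upper`,
#'   `objective_coefficient`. Bounds must satisfy `lower <= upper`.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param S numeric matrix, `nrow(metabolites)` x `nrow(reactions)`, signed
#'   stoichiometric coefficients (negative = consumed). Row/column names are
#'   set from the metabolite and reaction ids.
#' @param compartments optional data.frame with columns `id`, `name`;
#'   defaults to the distinct compartments of `metabolites`.
#' @return An object of class `constraint_model`.
#' @examples
#' m <- constraint_model(
#'   reactions = data.frame(id = c("SRC", "SINK"), name = c("in", "out"),
#'                          lower = 0, upper = c(10, 1000),
#'                          objective_coefficient = c(0, 1)),
#'   metabolites = data.frame(id = "a_c", name = "A", compartment = "c"),
#'   S = matrix(c(1, -1), 1, 2)
#' )
#' run_fba(m)$objective_value
#' @export
constraint_model <- function(reactions, metabolites, S, compartments = NULL) {
  reactions <- as.data.frame(reactions)
  metabolites <- as.data.frame(metabolites)
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"objective_coefficient" %in% names(reactions)) {
    reactions$objective_coefficient <- 0
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (nrow(S) != nrow(metabolites) || ncol(S) != nrow(reactions)) {
    stop("S has dimensions ", nrow(S), "x", ncol(S),
         " but model declares ", nrow(metabolites), " metabolites and ",
         nrow(reactions), " reactions")
  }
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (is.null(compartments)) {
    cid <- unique(metabolites$compartment)
    compartments <- data.frame(id = cid, name = cid, stringsAsFactors = FALSE)
  }
  model <- structure(
    list(reactions = reactions, metabolites = metabolites, S = S,
         compartments = as.data.frame(compartments)),
    class = "constraint_model"
  )
  validate_constraint_model(model)
  model
}

#' Validate a constraint-based model's invariants
#'
#' Checks that `lower <= upper` for every reaction, that the stoichiometric
#' matrix dimensions match the reaction and metabolite lists, and that ids
#' are unique.
#'
#' @param model a `constraint_model`.
#' @return `model`, invisibly. Errors on the first violated invariant.
#' @export
validate_constraint_model <- function(model) {
  stopifnot(inherits(model, "constraint_model"))
  rx <- model$reactions
  need <- c("id", "lower", "upper", "objective_coefficient")
  miss <- setdiff(need, names(rx))
  if (length(miss)) stop("reactions table lacks columns: ", toString(miss))
  if (anyDuplicated(rx$id)) stop("duplicated reaction ids: ",
                                 toString(unique(rx$id[duplicated(rx$id)])))
  if (anyDuplicated(model$metabolites$id)) stop("duplicated metabolite ids")
  bad <- which(rx$lower > rx$upper)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         toString(rx$id[bad]))
  }
  if (!all(is.finite(rx$lower)) || !all(is.finite(rx$upper))) {
    stop("all flux bounds must be finite (use +/-1000 style defaults)")
  }
  if (nrow(model$S) != nrow(model$metabolites) ||
      ncol(model$S) != nrow(rx)) {
    stop("S has dimensions ", nrow(model$S), "x", ncol(model$S),
         " but model declares ", nrow(model$metabolites), " metabolites and ",
         nrow(rx), " reactions")
  }
  invisible(model)
}

#' @export
print.constraint_model <- function(x, ...) {
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  cat("constraint_model: ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ",
      nrow(x$compartments), " compartments\n", sep = "")
  cat("objective:", if (length(obj)) toString(obj) else "(none)", "\n")
  invisible(x)
}

#' Extract one reaction of a constraint-based model
#'
#' @param model a `constraint_model`.
#' @param id reaction id.
#' @return list with `id`, `stoich` (named vector over metabolites with
#'   nonzero coefficient), `lower`, `upper`, and `reversible`
#'   (`lower < 0`).
#' @export
cb_reaction <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  col <- model$S[, i]
  list(id = id,
       stoich = col[col != 0],
       lower = model$reactions$lower[i],
       upper = model$reactions$upper[i],
       reversible = model$reactions$lower[i] < 0)
}

#' Objective weight vector of a constraint-based model
#'
#' Resolves an objective argument (NULL = model default, a reaction id, or a
#' named weight vector) to a full per-reaction weight vector c.
#'
#' @param model a `constraint_model`.
#' @param objective NULL, a single reaction id, or a named numeric vector of
#'   weights over a subset of reactions.
#' @return numeric vector of length `nrow(model$reactions)`, named by id.
#' @export
objective_vector <- function(model, objective = NULL) {
  ids <- model$reactions$id
  if (is.null(objective)) {
    w <- model$reactions$objective_coefficient
    if (all(w == 0)) stop("model declares no objective and none was given")
  } else if (is.character(objective) && length(objective) == 1) {
    if (!objective %in% ids) stop("unknown objective reaction: ", objective)
    w <- as.numeric(ids == objective)
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    unknown <- setdiff(names(objective), ids)
    if (length(unknown)) stop("unknown reaction(s) in objective: ",
                              toString(unknown))
    w <- numeric(length(ids))
    w[match(names(objective), ids)] <- objective
  } else {
    stop("objective must be NULL, a reaction id, or a named numeric vector")
  }
  stats::setNames(w, ids)
}

#' Replace the declared objective of a model
#'
#' @param model a `constraint_model`.
#' @param objective reaction id or named weight vector (see
#'   [objective_vector()]).
#' @return a modified copy of `model`; the input is not mutated.
#' @export
set_objective <- function(model, objective) {
  w <- objective_vector(model, objective)
  model$reactions$objective_coefficient <- unname(w)
  model
}
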