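# BiGG-style JSON input/output for constraint-based models (the convention
# used by the BiGG Models database and cobrapy's JSON serializer).

#' Read a constraint-based model from BiGG JSON
#'
#' @param path JSON file path; the file must follow the BiGG convention
#'   (`metabolites`, `reactions` with `metabolites` maps, `lower_bound`,
#'   `upper_bound`, `objective_coefficient`).
#' @return a `constraint_model`. Missing bounds are an error.
#' @export
read_bigg_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || is.null(j$metabolites)) {
    stop("not a BiGG model: needs 'reactions' and 'metabolites'")
  }
  mets <- data.frame(
    id = vapply(j$metabolites, `[[`, "", "id"),
    name = vapply(j$metabolites, function(m)
      if (is.null(m$name)) m$id else m$name, ""),
    compartment = vapply(j$metabolites, function(m)
      if (is.null(m$compartment)) sub(".*_", "", m$id) else m$compartment, ""),
    stringsAsFactors = FALSE)
  n <- length(j$reactions)
  ids <- vapply(j$reactions, `[[`, "", "id")
  get_num <- function(r, field) {
    v <- r[[field]]
    if (is.null(v)) stop("missing ", field, " for reaction: ", r$id)
    as.numeric(v)
  }
  lower <- vapply(j$reactions, get_num, numeric(1), "lower_bound")
  upper <- vapply(j$reactions, get_num, numeric(1), "upper_bound")
  objective <- vapply(j$reactions, function(r)
    if (is.null(r$objective_coefficient)) 0 else
      as.numeric(r$objective_coefficient), numeric(1))
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))
  for (i in seq_len(n)) {
    st <- j$reactions[[i]]$metabolites
    if (length(st)) {
      unknown <- setdiff(names(st), mets$id)
      if (length(unknown)) {
        stop("reaction ", ids[i], " references undeclared species: ",
             toString(unknown))
      }
      S[names(st), i] <- as.numeric(unlist(st))
    }
  }
  constraint_model(
    reactions = data.frame(
      id = ids,
      name = vapply(j$reactions, function(r)
        if (is.null(r$name)) r$id else r$name, ""),
      lower = lower, upper = upper, objective_coefficient = objective,
      stringsAsFactors = FALSE),
    metabolites = mets, S = S)
}

#' Write a constraint-based model to BiGG JSON
#'
#' The output is readable by cobrapy (`cobra.io.load_json_model`) as well
#' as [read_bigg_json()].
#'
#' @param model a `constraint_model`.
#' @param path output file path.
#' @param id model id; default `"model"`.
#' @return `path`, invisibly.
#' @export
write_bigg_json <- function(model, path, id = "model") {
  validate_constraint_model(model)
  rx <- model$reactions
  reactions <- lapply(seq_len(nrow(rx)), function(i) {
    col <- model$S[, i]
    st <- as.list(col[col != 0])
    list(id = rx$id[i], name = rx$name[i],
         metabolites = if (length(st)) st else structure(list(), names = character(0)),
         lower_bound = rx$lower[i], upper_bound = rx$upper[i],
         gene_reaction_rule = "",
         objective_coefficient = rx$objective_coefficient[i])
  })
  metabolites <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  comp <- stats::setNames(as.list(model$compartments$name),
                          model$compartments$id)
  out <- list(id = id, metabolites = metabolites, reactions = reactions,
              genes = list(), compartments = comp,
              version = "1")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
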