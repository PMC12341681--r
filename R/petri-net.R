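# Petri-net view of a metabolic network: metabolites are places (circles),
# reactions are transitions (rectangles); a reactant contributes an arc
# place -> transition, a product an arc transition -> place, weighted by the
# absolute stoichiometric coefficient.

#' Export the Petri-net view of a metabolic model
#'
#' Builds the bipartite place/transition graph of a kinetic or
#' constraint-based model. The arc multiset equals the nonzero pattern of
#' the stoichiometric matrix: one arc per nonzero coefficient, directed by
#' its sign, weighted by its absolute value. No species are filtered.
#'
#' @param model a `constraint_model` or `kinetic_model`.
#' @return a `petri_net`: list with `places` (metabolite ids),
#'   `transitions` (reaction ids) and `arcs` (data.frame `from`, `to`,
#'   `weight`).
#' @seealso [petri_net_dot()]
#' @export
export_petri_net <- function(model) {
  S <- if (inherits(model, "constraint_model")) model$S
       else if (inherits(model, "kinetic_model")) kin_stoichiometry(model)
       else stop("model must be a constraint_model or kinetic_model")
  nz <- which(S != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    met <- rownames(S)[nz[, 1]]
    rxn <- colnames(S)[nz[, 2]]
    coef <- S[nz]
    arcs <- data.frame(
      from = ifelse(coef < 0, met, rxn),
      to = ifelse(coef < 0, rxn, met),
      weight = abs(coef),
      stringsAsFactors = FALSE)
  } else {
    arcs <- data.frame(from = character(), to = character(),
                       weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(places = rownames(S), transitions = colnames(S),
                 arcs = arcs),
            class = "petri_net")
}

#' Serialize a Petri net to DOT (Graphviz) text
#'
#' Places render as circles, transitions as rectangles; arc labels carry
#' the stoichiometric weight when it differs from 1.
#'
#' @param net a `petri_net` from [export_petri_net()].
#' @param name graph name; default `"metabolic_net"`.
#' @return a single string of DOT source.
#' @export
petri_net_dot <- function(net, name = "metabolic_net") {
  stopifnot(inherits(net, "petri_net"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c(
    paste0("digraph ", name, " {"),
    "  rankdir=LR;",
    paste0("  ", q(net$places), " [shape=circle];"),
    paste0("  ", q(net$transitions), " [shape=rectangle];")
  )
  if (nrow(net$arcs)) {
    lab <- ifelse(net$arcs$weight == 1, "",
                  paste0(" [label=", format(net$arcs$weight), "]"))
    lines <- c(lines,
               paste0("  ", q(net$arcs$from), " -> ", q(net$arcs$to),
                      lab, ";"))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.petri_net <- function(x, ...) {
  cat("petri_net:", length(x$places), "places,",
      length(x$transitions), "transitions,", nrow(x$arcs), "arcs\n")
  invisible(x)
}
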