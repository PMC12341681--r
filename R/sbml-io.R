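# SBML input/output. Kinetic models use SBML Level 3 core with kinetic
# laws (Level 2 kinetic-law encodings are tolerated on read); constraint-
# based models use Level 3 with the fbc (version 2) extension for bounds
# and the objective.

.sbml_core_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_attr <- function(x) format(x, scientific = TRUE, digits = 15)

#' Read a kinetic model from SBML
#'
#' Parses an SBML file with kinetic laws (Level 3, or Level 2 kinetic-law
#' encodings) into a [kinetic_model()]. Rate-law MathML is translated into
#' evaluable arithmetic expressions; local and global parameters are
#' preserved.
#'
#' @param path SBML file path.
#' @return a `kinetic_model`. Errors name the offending element on
#'   malformed input; a reaction without a kinetic law raises an explicit
#'   "no rate law" error listing the reaction id.
#' @seealso [write_kinetic_sbml()]
#' @export
read_kinetic_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model>")

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
                  xml2::xml_attr(comp_nodes, "id"),
                  xml2::xml_attr(comp_nodes, "name")),
    stringsAsFactors = FALSE)

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (!length(sp_nodes)) stop("malformed SBML: no species")
  init <- xml2::xml_attr(sp_nodes, "initialConcentration")
  init[is.na(init)] <- xml2::xml_attr(sp_nodes, "initialAmount")[is.na(init)]
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    initial = ifelse(is.na(init), 0, as.numeric(init)),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  if (anyNA(species$id)) stop("malformed SBML: species without id")

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  parameters <- parameters[!is.na(names(parameters))]

  rxn_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- lapply(rxn_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    if (is.na(rid)) stop("malformed SBML: reaction without id")
    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rn, paste0("./", tag, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (is.na(sp)) stop("malformed SBML: speciesReference without ",
                            "species in reaction ", rid)
        if (!sp %in% species$id) {
          stop("reaction ", rid, " references undeclared species: ", sp)
        }
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        st[sp] <- (if (is.na(st[sp])) 0 else st[sp]) + side * coef
      }
    }
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    if (inherits(kl, "xml_missing")) {
      stop("no rate law for reaction: ", rid)
    }
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing")) {
      stop("no rate law (empty kineticLaw) for reaction: ", rid)
    }
    rate <- mathml_to_expr(math)
    # L3 localParameter; tolerate L2 listOfParameters/parameter
    lp <- xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter")
    if (!length(lp)) lp <- xml2::xml_find_all(kl, "./listOfParameters/parameter")
    params <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                              xml2::xml_attr(lp, "id"))
    list(id = rid, stoich = st, rate = rate, params = params,
         reversible = xml2::xml_attr(rn, "reversible") %in% c("true", NA))
  })
  kinetic_model(species = species, reactions = reactions,
                compartments = compartments, parameters = parameters)
}

#' Write a kinetic model to SBML Level 3
#'
#' @param model a `kinetic_model`.
#' @param path output file path.
#' @param id model id attribute; default `"kinetic_model"`.
#' @return `path`, invisibly.
#' @export
write_kinetic_sbml <- function(model, path, id = "kinetic_model") {
  validate_kinetic_model(model)
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', .sbml_core_ns, '" level="3" version="1">')
  add('  <model id="', id, '">')
  add('    <listOfCompartments>')
  for (i in seq_len(nrow(model$compartments))) {
    add('      <compartment id="', model$compartments$id[i], '" name="',
        xml_escape(model$compartments$name[i]),
        '" size="1" constant="true"/>')
  }
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    add('      <species id="', s$id, '" compartment="', s$compartment,
        '" initialConcentration="', num_attr(s$initial),
        '" boundaryCondition="', tolower(s$boundary),
        '" hasOnlySubstanceUnits="false" constant="false"/>')
  }
  add('    </listOfSpecies>')
  if (length(model$parameters)) {
    add('    <listOfParameters>')
    for (p in names(model$parameters)) {
      add('      <parameter id="', p, '" value="',
          num_attr(model$parameters[[p]]), '" constant="true"/>')
    }
    add('    </listOfParameters>')
  }
  add('    <listOfReactions>')
  for (r in model$reactions) {
    add('      <reaction id="', r$id, '" reversible="',
        tolower(isTRUE(r$reversible)), '" fast="false">')
    for (side in c(-1, 1)) {
      sel <- r$stoich * side > 0   # side=-1 selects reactants
      if (!any(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      add('        <', tag, '>')
      for (sp in names(r$stoich)[sel]) {
        add('          <speciesReference species="', sp,
            '" stoichiometry="', num_attr(abs(r$stoich[[sp]])),
            '" constant="true"/>')
      }
      add('        </', tag, '>')
    }
    add('        <kineticLaw>')
    add('          <math xmlns="', .mathml_ns, '">',
        expr_to_mathml(r$rate), '</math>')
    if (length(r$params)) {
      add('          <listOfLocalParameters>')
      for (p in names(r$params)) {
        add('            <localParameter id="', p, '" value="',
            num_attr(r$params[[p]]), '"/>')
      }
      add('          </listOfLocalParameters>')
    }
    add('        </kineticLaw>')
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  writeLines(ln, path)
  invisible(path)
}

#' Read a constraint-based model from SBML-fbc or BiGG JSON
#'
#' Accepts SBML Level 3 with the fbc extension (bounds as parameter
#' references, objective from the active fbc objective) or a BiGG-style
#' JSON model; the dialect is chosen by file extension (`.json` vs
#' anything else). Missing bounds are an error, never silently defaulted.
#'
#' @param path model file path.
#' @return a `constraint_model`. Errors on missing bounds, an undeclared
#'   objective reaction, or `upper < lower`.
#' @seealso [write_constraint_sbml()], [read_bigg_json()]
#' @export
read_constraint_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(read_bigg_json(path))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model>")

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  if (!length(rxn_nodes)) stop("malformed SBML: no reactions")
  n <- length(rxn_nodes)
  ids <- xml2::xml_attr(rxn_nodes, "id")
  nms <- xml2::xml_attr(rxn_nodes, "name")
  lower <- upper <- rep(NA_real_, n)
  S_entries <- vector("list", n)
  for (i in seq_len(n)) {
    rn <- rxn_nodes[[i]]
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref)) {
      stop("missing flux bounds for reaction: ", ids[i])
    }
    if (!lb_ref %in% names(par_val) || !ub_ref %in% names(par_val)) {
      stop("bound parameter not declared for reaction: ", ids[i])
    }
    lower[i] <- par_val[[lb_ref]]
    upper[i] <- par_val[[ub_ref]]
    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rn, paste0("./", tag, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (!sp %in% metabolites$id) {
          stop("reaction ", ids[i], " references undeclared species: ", sp)
        }
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        st[sp] <- (if (is.na(st[sp])) 0 else st[sp]) + side * coef
      }
    }
    S_entries[[i]] <- st
  }
  # fbc elements keep their prefix namespace after xml_ns_strip; match by
  # local name so both prefixed and unprefixed dialects parse
  lo_node <- xml2::xml_find_first(
    model, "./*[local-name()='listOfObjectives']")
  active <- xml2::xml_attr(lo_node, "activeObjective")
  if (is.na(active)) stop("no active objective declared")
  obj_node <- xml2::xml_find_first(
    lo_node, paste0("./*[local-name()='objective'][@*[local-name()='id']='",
                    active, "']"))
  if (inherits(obj_node, "xml_missing")) {
    stop("unknown active objective: ", active)
  }
  fo <- xml2::xml_find_all(
    obj_node,
    "./*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
  obj_rxn <- xml2::xml_attr(fo, "reaction")
  obj_coef <- as.numeric(xml2::xml_attr(fo, "coefficient"))
  if (!all(obj_rxn %in% ids)) {
    stop("objective references unknown reaction(s): ",
         toString(setdiff(obj_rxn, ids)))
  }
  objective <- numeric(n)
  objective[match(obj_rxn, ids)] <- obj_coef

  S <- matrix(0, nrow(metabolites), n,
              dimnames = list(metabolites$id, ids))
  for (i in seq_len(n)) {
    st <- S_entries[[i]]
    if (length(st)) S[names(st), i] <- st
  }
  constraint_model(
    reactions = data.frame(id = ids,
                           name = ifelse(is.na(nms), ids, nms),
                           lower = lower, upper = upper,
                           objective_coefficient = objective,
                           stringsAsFactors = FALSE),
    metabolites = metabolites, S = S)
}

#' Write a constraint-based model to SBML Level 3 with fbc
#'
#' @param model a `constraint_model`.
#' @param path output file path.
#' @param id model id attribute; default `"constraint_model"`.
#' @return `path`, invisibly.
#' @export
write_constraint_sbml <- function(model, path, id = "constraint_model") {
  validate_constraint_model(model)
  rx <- model$reactions
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', .sbml_core_ns, '" xmlns:fbc="', .sbml_fbc_ns,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', id, '" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (i in seq_len(nrow(model$compartments))) {
    add('      <compartment id="', model$compartments$id[i], '" name="',
        xml_escape(model$compartments$name[i]),
        '" size="1" constant="true"/>')
  }
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    add('      <species id="', m$id, '" name="', xml_escape(m$name),
        '" compartment="', m$compartment, '" hasOnlySubstanceUnits="false"',
        ' boundaryCondition="false" constant="false"/>')
  }
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (i in seq_len(nrow(rx))) {
    add('      <parameter id="', rx$id[i], '_lb" value="',
        num_attr(rx$lower[i]), '" constant="true"/>')
    add('      <parameter id="', rx$id[i], '_ub" value="',
        num_attr(rx$upper[i]), '" constant="true"/>')
  }
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (i in seq_len(nrow(rx))) {
    add('      <reaction id="', rx$id[i], '" name="', xml_escape(rx$name[i]),
        '" reversible="', tolower(rx$lower[i] < 0), '" fast="false"',
        ' fbc:lowerFluxBound="', rx$id[i], '_lb"',
        ' fbc:upperFluxBound="', rx$id[i], '_ub">')
    col <- model$S[, i]
    for (side in c(-1, 1)) {
      sel <- col * side > 0
      if (!any(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      add('        <', tag, '>')
      for (sp in rownames(model$S)[sel]) {
        add('          <speciesReference species="', sp,
            '" stoichiometry="', num_attr(abs(col[[sp]])),
            '" constant="true"/>')
      }
      add('        </', tag, '>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  for (i in which(rx$objective_coefficient != 0)) {
    add('          <fbc:fluxObjective fbc:reaction="', rx$id[i],
        '" fbc:coefficient="', num_attr(rx$objective_coefficient[i]), '"/>')
  }
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  add('  </model>')
  add('</sbml>')
  writeLines(ln, path)
  invisible(path)
}
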