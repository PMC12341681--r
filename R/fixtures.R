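# Synthetic fixture generators: matched kinetic/constraint model pairs with
# closed-form ground truth, covering a linear pathway (with dead ends for
# dormancy), a growth-vs-product branch point, and one exemplar reaction
# pair per mapping category. All generators are deterministic.

write_fixture_files <- function(kinetic, gem, mapping, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(kinetic = file.path(out_dir, "kinetic.xml"),
                gem = file.path(out_dir, "gem.xml"),
                gem_json = file.path(out_dir, "gem.json"),
                mapping = file.path(out_dir, "mapping.csv"))
  write_kinetic_sbml(kinetic, paths$kinetic)
  write_constraint_sbml(gem, paths$gem)
  write_bigg_json(gem, paths$gem_json)
  write_mapping(mapping, paths$mapping)
  paths
}

#' Linear-chain fixture
#'
#' A pathway of `n` reactions, R1: -> A1, R2: A1 -> A2, ..., Rn:
#' A(n-1) -> (sink). The kinetic model has constant inflow `k_in` and
#' first-order steps, so the steady-state flux is `k_in` on every reaction
#' (closed form: \[A_i\] = k_in / k_(i+1)). The constraint model carries
#' the same reactions (sink as objective) plus two dead-end reactions that
#' can never carry flux at steady state, giving the dormancy metrics
#' signal at toy scale. The mapping labels every pair C0.
#'
#' @param n number of chain reactions (>= 2); default 3.
#' @param k_in inflow rate, mM s^-1; default 1.
#' @param rate_constants first-order constants (s^-1) of the `n - 1`
#'   downstream steps; default all 1.
#' @param uptake_cap upper bound of the inflow reaction in the constraint
#'   model, mmol gDW^-1 h^-1; default 10.
#' @param out_dir if given, the fixture is also written to disk
#'   (kinetic.xml, gem.xml, gem.json, mapping.csv).
#' @return list with `kinetic` (`kinetic_model`), `gem`
#'   (`constraint_model`), `mapping` (data.frame), `steady_flux` (the
#'   closed-form kinetic flux, = `k_in`), and `paths` when `out_dir` is
#'   given.
#' @export
make_linear_chain <- function(n = 3, k_in = 1,
                              rate_constants = rep(1, n - 1),
                              uptake_cap = 10, out_dir = NULL) {
  stopifnot(n >= 2, k_in > 0, length(rate_constants) == n - 1,
            all(rate_constants > 0))
  sp_ids <- paste0("A", seq_len(n - 1))
  rxn_ids <- paste0("R", seq_len(n))
  kin_rxns <- vector("list", n)
  kin_rxns[[1]] <- list(id = "R1", stoich = stats::setNames(1, sp_ids[1]),
                        rate = "k_in", params = c(k_in = k_in))
  for (i in 2:n) {
    from <- sp_ids[i - 1]
    st <- stats::setNames(-1, from)
    if (i < n) st <- c(st, stats::setNames(1, sp_ids[i]))
    k_name <- paste0("k", i)
    kin_rxns[[i]] <- list(id = rxn_ids[i], stoich = st,
                          rate = paste0(k_name, " * ", from),
                          params = stats::setNames(rate_constants[i - 1],
                                                   k_name))
  }
  kinetic <- kinetic_model(
    species = data.frame(id = sp_ids, compartment = "c", initial = 0,
                         boundary = FALSE, stringsAsFactors = FALSE),
    reactions = kin_rxns)

  mets <- c(sp_ids, "DEAD_sink", "DEAD_source")
  gem_ids <- c(rxn_ids, "DEADEND_FWD", "DEADEND_REV")
  S <- matrix(0, length(mets), length(gem_ids),
              dimnames = list(mets, gem_ids))
  S[sp_ids[1], "R1"] <- 1
  for (i in 2:n) {
    S[sp_ids[i - 1], rxn_ids[i]] <- -1
    if (i < n) S[sp_ids[i], rxn_ids[i]] <- 1
  }
  S[sp_ids[1], "DEADEND_FWD"] <- -1; S["DEAD_sink", "DEADEND_FWD"] <- 1
  S["DEAD_source", "DEADEND_REV"] <- -1; S[sp_ids[1], "DEADEND_REV"] <- 1
  gem <- constraint_model(
    reactions = data.frame(
      id = gem_ids, name = gem_ids,
      lower = 0,
      upper = c(uptake_cap, rep(1000, n - 1), 1000, 1000),
      objective_coefficient = as.numeric(gem_ids == rxn_ids[n]),
      stringsAsFactors = FALSE),
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             stringsAsFactors = FALSE),
    S = S)
  mapping <- data.frame(kinetic_ids = rxn_ids, cbm_ids = rxn_ids,
                        category = "C0", note = "chain step",
                        stringsAsFactors = FALSE)
  out <- list(kinetic = kinetic, gem = gem, mapping = mapping,
              steady_flux = k_in)
  if (!is.null(out_dir)) {
    out$paths <- write_fixture_files(kinetic, gem, mapping, out_dir)
  }
  out
}

#' Growth-vs-product branch fixture
#'
#' Emulates, in miniature, the competing-objective pathology of a
#' production strain. The kinetic model feeds acetyl-CoA and pyruvate at
#' `k_in` mM s^-1 and splits them between a biomass drain (BIO) and a
#' product drain (PROD) with first-order propensities, so both branch
#' fluxes are strictly positive at steady state:
#' f_BIO = k_in * biomass_yield / (biomass_yield + product_yield).
#' The constraint model routes glucose through a lumped glycolysis into
#' the same precursors (with CoA recycling, proton and water exchanges)
#' and, under plain FBA, sends all carbon to whichever branch is the
#' objective - the bifurcation. The default propensities are tuned so the
#' kinetic growth flux is 0.1 h^-1 with the glucose-scale inflow
#' 0.23 mM s^-1 (a glucose-limited chemostat at dilution 0.1 h^-1).
#' The constraint model contains the five cytosolic precursors needed by
#' [extend_gem_with_citramalate()].
#'
#' @param uptake_max glucose inflow upper bound in the constraint model,
#'   mmol gDW^-1 h^-1; default 10.
#' @param biomass_yield,product_yield first-order branch propensities
#'   (s^-1) of the kinetic model; defaults 1 and 1.3.
#' @param k_in kinetic inflow rate, mM s^-1; default 0.23.
#' @param out_dir optional output directory, as in [make_linear_chain()].
#' @return list with `kinetic`, `gem`, `mapping`, `mu_k` (closed-form
#'   kinetic growth flux), `f_prod` (closed-form product flux), and
#'   `paths` when `out_dir` is given.
#' @export
make_branch_fixture <- function(uptake_max = 10, biomass_yield = 1,
                                product_yield = 1.3, k_in = 0.23,
                                out_dir = NULL) {
  stopifnot(uptake_max > 0, biomass_yield > 0, product_yield > 0, k_in > 0)
  kinetic <- kinetic_model(
    species = data.frame(id = c("accoa_c", "pyr_c"), compartment = "c",
                         initial = 0, boundary = FALSE,
                         stringsAsFactors = FALSE),
    reactions = list(
      list(id = "SRC", stoich = c(accoa_c = 1, pyr_c = 1),
           rate = "k_in", params = c(k_in = k_in)),
      list(id = "BIO", stoich = c(accoa_c = -1, pyr_c = -1),
           rate = "kb * accoa_c", params = c(kb = biomass_yield)),
      list(id = "PROD", stoich = c(accoa_c = -1, pyr_c = -1),
           rate = "kp * accoa_c", params = c(kp = product_yield))
    ))
  mets <- c("glc_c", "accoa_c", "pyr_c", "coa_c", "h_c", "h2o_c", "prod_c")
  gem_ids <- c("SRC", "GLY", "BIO", "PROD", "EX_prod", "EX_h", "EX_h2o")
  S <- matrix(0, length(mets), length(gem_ids),
              dimnames = list(mets, gem_ids))
  S["glc_c", "SRC"] <- 1
  S[c("glc_c", "coa_c"), "GLY"] <- -1
  S[c("accoa_c", "pyr_c", "h_c"), "GLY"] <- 1
  S[c("accoa_c", "pyr_c"), "BIO"] <- -1; S["coa_c", "BIO"] <- 1
  S[c("accoa_c", "pyr_c", "h2o_c"), "PROD"] <- -1
  S[c("coa_c", "h_c", "prod_c"), "PROD"] <- 1
  S["prod_c", "EX_prod"] <- -1
  S["h_c", "EX_h"] <- -1
  S["h2o_c", "EX_h2o"] <- 1
  gem <- constraint_model(
    reactions = data.frame(
      id = gem_ids, name = gem_ids,
      lower = 0,
      upper = c(uptake_max, rep(1000, length(gem_ids) - 1)),
      objective_coefficient = as.numeric(gem_ids == "BIO"),
      stringsAsFactors = FALSE),
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             stringsAsFactors = FALSE),
    S = S)
  mapping <- data.frame(
    kinetic_ids = c("SRC", "BIO", "PROD"),
    cbm_ids = c("SRC", "BIO", "PROD"),
    category = "C0",
    note = c("curated: precursor inflow vs glucose inflow",
             "curated: biomass drain", "curated: product drain"),
    stringsAsFactors = FALSE)
  split <- biomass_yield / (biomass_yield + product_yield)
  out <- list(kinetic = kinetic, gem = gem, mapping = mapping,
              mu_k = k_in * split, f_prod = k_in * (1 - split))
  if (!is.null(out_dir)) {
    out$paths <- write_fixture_files(kinetic, gem, mapping, out_dir)
  }
  out
}

#' Category-zoo fixture
#'
#' One reaction pair per mapping category, constructed to differ exactly
#' as the category prescribes: C0 identical, C1 differing by water, C2
#' bicarbonate vs CO2, C3 differing in reversibility, C4 with reactants
#' and products swapped, and a two-to-one C5 chain (R5a: X -> Y,
#' R5b: Y -> Z vs the lumped R5: X -> Z). All kinetic species are boundary
#' species with constant rates, so the model is trivially at steady state
#' and its fluxes are the declared rate constants.
#'
#' @param out_dir optional output directory, as in [make_linear_chain()].
#' @return list with `kinetic`, `gem`, `mapping`, `fluxes` (named
#'   closed-form kinetic fluxes), and `paths` when `out_dir` is given.
#' @export
make_category_zoo <- function(out_dir = NULL) {
  fluxes <- c(R_C0 = 0.1, R_C1 = 0.2, R_C2 = 0.3, R_C3 = 0.4, R_C4 = 0.5,
              R5a = 2, R5b = 2)
  kin_sp <- c("a0_c", "b0_c", "fdp_c", "f6p_c", "pi_c", "mal_c", "nad_c",
              "nadh_c", "pyr_c", "hco3_c", "icit_c", "glx_c", "succ_c",
              "adp_c", "bpg_c", "atp_c", "pg3_c", "x5_c", "y5_c", "z5_c")
  crate <- function(id) {
    p <- paste0("f_", id)
    list(rate = p, params = stats::setNames(fluxes[[id]], p))
  }
  mk <- function(id, stoich, reversible = FALSE) {
    r <- crate(id)
    list(id = id, stoich = stoich, rate = r$rate, params = r$params,
         reversible = reversible)
  }
  kinetic <- kinetic_model(
    species = data.frame(id = kin_sp, compartment = "c", initial = 1,
                         boundary = TRUE, stringsAsFactors = FALSE),
    reactions = list(
      mk("R_C0", c(a0_c = -1, b0_c = 1)),
      mk("R_C1", c(fdp_c = -1, f6p_c = 1, pi_c = 1)),
      mk("R_C2", c(mal_c = -1, nad_c = -1, nadh_c = 1, pyr_c = 1,
                   hco3_c = 1)),
      mk("R_C3", c(icit_c = -1, glx_c = 1, succ_c = 1), reversible = TRUE),
      mk("R_C4", c(adp_c = -1, bpg_c = -1, atp_c = 1, pg3_c = 1),
         reversible = TRUE),
      mk("R5a", c(x5_c = -1, y5_c = 1)),
      mk("R5b", c(y5_c = -1, z5_c = 1))
    ))
  gem_sp <- c("a0_c", "b0_c", "fdp_c", "h2o_c", "f6p_c", "pi_c", "mal_c",
              "nad_c", "nadh_c", "pyr_c", "co2_c", "icit_c", "glx_c",
              "succ_c", "adp_c", "bpg_c", "atp_c", "pg3_c", "x5_c", "z5_c")
  gem_ids <- c("R_C0", "R_C1", "R_C2", "R_C3", "R_C4", "R5")
  S <- matrix(0, length(gem_sp), length(gem_ids),
              dimnames = list(gem_sp, gem_ids))
  S[c("a0_c"), "R_C0"] <- -1; S["b0_c", "R_C0"] <- 1
  S[c("fdp_c", "h2o_c"), "R_C1"] <- -1
  S[c("f6p_c", "pi_c"), "R_C1"] <- 1
  S[c("mal_c", "nad_c"), "R_C2"] <- -1
  S[c("nadh_c", "pyr_c", "co2_c"), "R_C2"] <- 1
  S["icit_c", "R_C3"] <- -1; S[c("glx_c", "succ_c"), "R_C3"] <- 1
  S[c("pg3_c", "atp_c"), "R_C4"] <- -1
  S[c("bpg_c", "adp_c"), "R_C4"] <- 1
  S["x5_c", "R5"] <- -1; S["z5_c", "R5"] <- 1
  lower <- c(0, 0, 0, 0, -1000, 0)   # only the swapped C4 pair is reversible
  # a reversible exchange per metabolite keeps every mapped flux vector
  # mass-balance feasible (the zoo has no closed pathway structure)
  ex_ids <- paste0("EX_", gem_sp)
  S <- cbind(S, -diag(length(gem_sp)))
  colnames(S) <- c(gem_ids, ex_ids)
  gem <- constraint_model(
    reactions = data.frame(
      id = c(gem_ids, ex_ids), name = c(gem_ids, ex_ids),
      lower = c(lower, rep(-1000, length(ex_ids))), upper = 1000,
      objective_coefficient = as.numeric(c(gem_ids, ex_ids) == "R_C0"),
      stringsAsFactors = FALSE),
    metabolites = data.frame(id = gem_sp, name = gem_sp, compartment = "c",
                             stringsAsFactors = FALSE),
    S = S)
  mapping <- data.frame(
    kinetic_ids = c("R_C0", "R_C1", "R_C2", "R_C3", "R_C4", "R5a;R5b"),
    cbm_ids = c("R_C0", "R_C1", "R_C2", "R_C3", "R_C4", "R5"),
    category = c("C0", "C1", "C2", "C3", "C4", "C5"),
    note = c("identical", "differs by H2O", "bicarbonate vs CO2",
             "reversibility differs", "sides swapped",
             "two-step chain vs lumped reaction"),
    stringsAsFactors = FALSE)
  out <- list(kinetic = kinetic, gem = gem, mapping = mapping,
              fluxes = fluxes)
  if (!is.null(out_dir)) {
    out$paths <- write_fixture_files(kinetic, gem, mapping, out_dir)
  }
  out
}
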