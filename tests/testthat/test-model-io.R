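test_that("kinetic SBML round trip preserves structure, rates and dynamics", {
  dir <- withr::local_tempdir()
  fx <- make_branch_fixture(out_dir = dir)
  back <- read_kinetic_sbml(fx$paths$kinetic)
  expect_equal(length(back$reactions), length(fx$kinetic$reactions))
  expect_equal(sort(back$species$id), sort(fx$kinetic$species$id))
  expect_equal(kin_stoichiometry(back)[rownames(kin_stoichiometry(fx$kinetic)),
                                       colnames(kin_stoichiometry(fx$kinetic))],
               kin_stoichiometry(fx$kinetic))
  # rate laws survive the MathML round trip: same steady state
  ss0 <- simulate_to_steady_state(fx$kinetic)
  ss1 <- simulate_to_steady_state(back)
  expect_equal(ss1$fluxes[names(ss0$fluxes)], ss0$fluxes, tolerance = 1e-8)
})

test_that("kinetic SBML reader reports structural defects by element", {
  dir <- withr::local_tempdir()
  fx <- make_linear_chain(3, 1, out_dir = dir)
  txt <- readLines(fx$paths$kinetic)
  # a reaction stripped of its kinetic law
  mangled <- file.path(dir, "nolaw.xml")
  drop <- grep("kineticLaw|math|localParameter|<cn>|<ci>|apply", txt)
  writeLines(txt[-drop], mangled)
  expect_error(read_kinetic_sbml(mangled), "no rate law")
  # a reaction referencing an undeclared species
  mangled2 <- file.path(dir, "ghost.xml")
  writeLines(gsub('species="A1"', 'species="GHOST"', txt), mangled2)
  expect_error(read_kinetic_sbml(mangled2), "undeclared species")
  expect_error(read_kinetic_sbml(file.path(dir, "absent.xml")), "not found")
})

test_that("constraint model round trips through SBML-fbc and BiGG JSON", {
  dir <- withr::local_tempdir()
  fx <- make_branch_fixture(out_dir = dir)
  ord <- function(m) {
    i <- order(m$reactions$id); j <- order(m$metabolites$id)
    list(S = unname(m$S[j, i]), lower = m$reactions$lower[i],
         upper = m$reactions$upper[i],
         obj = m$reactions$objective_coefficient[i])
  }
  for (p in c(fx$paths$gem, fx$paths$gem_json)) {
    back <- read_constraint_sbml(p)
    expect_equal(ord(back), ord(fx$gem), tolerance = 1e-12)
    expect_equal(back$reactions$id[back$reactions$objective_coefficient != 0],
                 "BIO")
  }
})

test_that("constraint readers refuse silent defaults and inverted bounds", {
  dir <- withr::local_tempdir()
  fx <- make_linear_chain(3, 1, out_dir = dir)
  txt <- readLines(fx$paths$gem)
  noub <- file.path(dir, "noub.xml")
  writeLines(gsub(' fbc:upperFluxBound="R1_ub"', "", txt), noub)
  expect_error(read_constraint_sbml(noub), "missing flux bounds")
  # upper below lower must be rejected, not repaired
  inv <- file.path(dir, "inverted.xml")
  writeLines(sub('id="R2_ub" value="1e\\+03"', 'id="R2_ub" value="-5"', txt),
             inv)
  expect_error(read_constraint_sbml(inv), "lower bound exceeds")
  j <- jsonlite::fromJSON(readLines(fx$paths$gem_json),
                          simplifyVector = FALSE)
  j$reactions[[1]]$lower_bound <- NULL
  nojlb <- file.path(dir, "nolb.json")
  jsonlite::write_json(j, nojlb, auto_unbox = TRUE, digits = NA)
  expect_error(read_bigg_json(nojlb), "missing lower_bound")
})

test_that("cobrapy reads the emitted BiGG JSON and agrees on the optimum", {
  dir <- withr::local_tempdir()
  fx <- make_branch_fixture(out_dir = dir)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra",
    "m = cobra.io.load_json_model(sys.argv[1])",
    "print(len(m.reactions)); print(m.optimize().objective_value)"), script)
  out <- system2("python", c(script, fx$paths$gem_json), stdout = TRUE)
  expect_equal(as.integer(out[1]), nrow(fx$gem$reactions))
  expect_equal(as.numeric(out[2]), run_fba(fx$gem)$objective_value,
               tolerance = 1e-6)
})

test_that("the Petri-net view is bipartite and mirrors the nonzero stoichiometry", {
  # the citramalate synthesis reaction alone: 6 species, 1 reaction,
  # three reactant arcs in, three product arcs out
  mets <- c("accoa_c", "pyr_c", "h2o_c", "coa_c", "h_c", "citramalate_c")
  cima <- constraint_model(
    reactions = data.frame(id = "CITRA_SYN", name = "citramalate synthase",
                           lower = 0, upper = 1000,
                           objective_coefficient = 1),
    metabolites = data.frame(id = mets, name = mets, compartment = "c"),
    S = matrix(c(-1, -1, -1, 1, 1, 1), 6, 1))
  pn <- export_petri_net(cima)
  expect_length(pn$places, 6)
  expect_length(pn$transitions, 1)
  expect_equal(sum(pn$arcs$to == "CITRA_SYN"), 3)
  expect_equal(sum(pn$arcs$from == "CITRA_SYN"), 3)

  for (model in list(make_linear_chain(3, 1)$gem,
                     make_branch_fixture()$kinetic)) {
    pn <- export_petri_net(model)
    S <- if (inherits(model, "constraint_model")) model$S
         else kin_stoichiometry(model)
    expect_equal(nrow(pn$arcs), sum(S != 0))
    # bipartite: every arc joins a place and a transition
    from_place <- pn$arcs$from %in% pn$places
    to_place <- pn$arcs$to %in% pn$places
    expect_true(all(xor(from_place, to_place)))
    expect_true(all(pn$arcs$weight > 0))
  }
  # empty model, empty graph
  empty <- constraint_model(
    reactions = data.frame(id = character(), lower = numeric(),
                           upper = numeric(),
                           objective_coefficient = numeric()),
    metabolites = data.frame(id = character(), compartment = character()),
    S = matrix(0, 0, 0))
  expect_equal(nrow(export_petri_net(empty)$arcs), 0)
})

test_that("DOT export draws places as circles and transitions as rectangles", {
  fx <- make_linear_chain(3, 1)
  dot <- petri_net_dot(export_petri_net(fx$kinetic))
  expect_match(dot, '"A1" \\[shape=circle\\];')
  expect_match(dot, '"R2" \\[shape=rectangle\\];')
  expect_match(dot, '"A1" -> "R2";')
  expect_match(dot, "^digraph", all = FALSE)
})

test_that("constraint model construction enforces the bound and shape invariants", {
  rx <- data.frame(id = c("a", "b"), lower = c(0, 0), upper = c(1, -1),
                   objective_coefficient = c(1, 0))
  mets <- data.frame(id = "m", compartment = "c")
  expect_error(constraint_model(rx, mets, matrix(c(1, -1), 1, 2)),
               "lower bound exceeds")
  rx$upper <- 1
  expect_error(constraint_model(rx, mets, matrix(1, 2, 2)), "dimensions")
  expect_error(constraint_model(rx[c(1, 1), ], mets,
                                matrix(c(1, -1), 1, 2)), "duplicated")
})
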