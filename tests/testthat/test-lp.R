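test_that("FBA recovers hand-solvable optima and reports infeasibility", {
  fx <- make_linear_chain(3, k_in = 1)
  fba <- run_fba(fx$gem)
  expect_equal(fba$status, "optimal")
  # chain throughput is forced by the single uptake cap
  expect_equal(fba$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(fba$fluxes[c("R1", "R2", "R3")]), c(10, 10, 10),
               tolerance = 1e-9)

  mb <- mini_branch_model()
  f <- run_fba(mb)
  expect_equal(f$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(f$fluxes["PROD"]), 0, tolerance = 1e-9)

  # no carbon in, no flux out
  starved <- apply_bounds(mb, data.frame(reaction_id = "IN",
                                         lower = 0, upper = 0))
  expect_equal(run_fba(starved)$objective_value, 0, tolerance = 1e-9)

  # contradictory pinning makes the LP infeasible, reported not masked
  bad <- apply_bounds(mb, data.frame(reaction_id = c("IN", "BIO"),
                                     lower = c(0, 5), upper = c(0, 5)))
  fb <- run_fba(bad)
  expect_equal(fb$status, "infeasible")
  expect_true(is.na(fb$objective_value))
  expect_null(fb$fluxes)
})

test_that("optimal FBA fluxes satisfy mass balance and bounds", {
  for (model in list(make_linear_chain(4, 2)$gem, make_branch_fixture()$gem)) {
    fba <- run_fba(model)
    expect_equal(fba$status, "optimal")
    expect_lt(max(abs(model$S %*% fba$fluxes)), 1e-8)
    expect_true(all(fba$fluxes >= model$reactions$lower - 1e-9))
    expect_true(all(fba$fluxes <= model$reactions$upper + 1e-9))
    expect_equal(sum(fba$objective * fba$fluxes), fba$objective_value)
  }
})

test_that("FBA and FVA agree with brute-force vertex enumeration", {
  models <- list(chain = make_linear_chain(3, 1)$gem,
                 mini = mini_branch_model())
  for (model in models) {
    expect_equal(run_fba(model)$objective_value, oracle_fba(model),
                 tolerance = 1e-8)
    for (q in c(1, 0.999, 0.9)) {
      fva <- run_fva(model, q = q)
      orc <- oracle_fva(model, q = q)
      expect_equal(fva$minF, unname(orc[, "minF"]), tolerance = 1e-8)
      expect_equal(fva$maxF, unname(orc[, "maxF"]), tolerance = 1e-8)
    }
  }
})

test_that("FBA matches an external LP solver on the branch fixture", {
  model <- make_branch_fixture()$gem
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "lp.json")
  jsonlite::write_json(list(S = unname(as.matrix(model$S)),
                            L = model$reactions$lower,
                            U = model$reactions$upper,
                            c = model$reactions$objective_coefficient),
                       mat, digits = NA, auto_unbox = FALSE)
  script <- file.path(dir, "solve.py")
  writeLines(c(
    "import json, sys",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "r = linprog([-x for x in d['c']], A_eq=d['S'], b_eq=[0]*len(d['S']),",
    "            bounds=list(zip(d['L'], d['U'])), method='highs')",
    "print(-r.fun)"), script)
  out <- system2("python", c(script, mat), stdout = TRUE)
  expect_equal(run_fba(model)$objective_value, as.numeric(out[1]),
               tolerance = 1e-6)
})

test_that("FVA brackets the optimum and respects bounds and q-monotonicity", {
  model <- make_branch_fixture()$gem
  fba <- run_fba(model)
  prev <- NULL
  for (q in c(0.9, 0.99, 0.999, 1)) {
    fva <- run_fva(model, q = q)
    expect_true(all(fva$minF <= fva$maxF + 1e-9))
    expect_true(all(fva$minF >= model$reactions$lower - 1e-8))
    expect_true(all(fva$maxF <= model$reactions$upper + 1e-8))
    if (q == 1) {
      v <- fba$fluxes[fva$reaction_id]
      expect_true(all(fva$minF <= v + 1e-8 & v <= fva$maxF + 1e-8))
    }
    if (!is.null(prev)) {  # FV(r) nonincreasing as q grows
      expect_true(all(fva$FV <= prev$FV + 1e-8))
    }
    prev <- fva
  }
})

test_that("FVA isolates the product branch at tight optimum fractions", {
  mb <- mini_branch_model()
  # pinned reaction: no variability at all
  pinned <- apply_bounds(mb, data.frame(reaction_id = "IN",
                                        lower = 7, upper = 7))
  fva <- run_fva(pinned, q = 0)
  expect_equal(fva$minF[fva$reaction_id == "IN"], 7, tolerance = 1e-9)
  expect_equal(fva$FV[fva$reaction_id == "IN"], 0, tolerance = 1e-9)
  # at q = 1 any product flux costs biomass, so the branch is frozen
  fva1 <- run_fva(mb, q = 1)
  expect_equal(fva1$minF[fva1$reaction_id == "PROD"], 0, tolerance = 1e-8)
  expect_equal(fva1$maxF[fva1$reaction_id == "PROD"], 0, tolerance = 1e-8)
  # at q = 0.999 exactly 0.1% of uptake may leak to product
  fva999 <- run_fva(mb, q = 0.999)
  expect_equal(fva999$maxF[fva999$reaction_id == "PROD"], 0.01,
               tolerance = 1e-8)
})

test_that("dormancy uses inclusive epsilon on both FVA extremes", {
  expect_true(is_dormant(0.005, 0.009))
  expect_false(is_dormant(-0.5, 0.2))
  expect_true(is_dormant(0.01, 0.01))     # boundary value counts
  expect_false(is_dormant(-0.011, 0))
  expect_equal(is_dormant(c(0, -0.5), c(0.009, 0.2)), c(TRUE, FALSE))
})

test_that("dormant counts reflect unreachable dead ends", {
  fx <- make_linear_chain(3, 1)
  fva <- run_fva(fx$gem, q = 1)
  expect_equal(count_dormant(fva), 2L)    # the two dead-end reactions
  dorm <- fva$reaction_id[fva$dormant]
  expect_setequal(dorm, c("DEADEND_FWD", "DEADEND_REV"))
  # pinned-positive reactions are never dormant
  mb <- mini_branch_model()
  pinned <- apply_bounds(mb, data.frame(reaction_id = c("IN", "BIO", "PROD"),
                                        lower = c(5, 2, 3),
                                        upper = c(5, 2, 3)))
  expect_equal(count_dormant(run_fva(pinned, q = 0)), 0L)
  empty <- run_fva(mb, q = 0, reactions = character(0))
  expect_equal(count_dormant(empty), 0L)
})

test_that("tightening bounds never raises the FBA optimum", {
  fx <- make_linear_chain(3, 1)
  ss <- simulate_to_steady_state(fx$kinetic)
  mu <- run_fba(fx$gem)$objective_value
  cur <- fx$gem
  asg <- translate_bounds(fx$mapping, ss, d = 0.2)
  for (i in seq_len(nrow(asg))) {
    cur <- apply_bounds(cur, asg[i, ])
    fba <- run_fba(cur)
    expect_lte(fba$objective_value, mu + 1e-9)
    mu <- fba$objective_value
  }
})
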