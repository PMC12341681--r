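test_that("all five exemplar reaction pairs classify into their categories", {
  zoo <- make_category_zoo()
  for (i in seq_len(nrow(zoo$mapping))) {
    row <- zoo$mapping[i, ]
    if (row$category == "C5") next
    k <- kin_reaction(zoo$kinetic, row$kinetic_ids)
    b <- cb_reaction(zoo$gem, row$cbm_ids)
    expect_equal(classify_pair(k, b), row$category,
                 label = paste("pair", row$kinetic_ids))
  }
  # the two-to-one subnetwork pair is not mappable one-to-one
  k5 <- kin_reaction(zoo$kinetic, "R5a")
  b5 <- cb_reaction(zoo$gem, "R5")
  expect_equal(classify_pair(k5, b5), "C5")
})

test_that("classification is symmetric for C0 and self-mirrored for C4", {
  zoo <- make_category_zoo()
  k0 <- kin_reaction(zoo$kinetic, "R_C0")
  b0 <- cb_reaction(zoo$gem, "R_C0")
  expect_equal(classify_pair(b0, k0), "C0")
  k4 <- kin_reaction(zoo$kinetic, "R_C4")
  b4 <- cb_reaction(zoo$gem, "R_C4")
  expect_equal(classify_pair(b4, k4), "C4")   # swap preserves C4
  expect_error(classify_pair(list(stoich = numeric(0), reversible = FALSE),
                             b0), "empty")
})

test_that("flux unit conversion applies the cell-volume factor 6.372", {
  expect_equal(convert_flux_units(1), 6.372)
  expect_equal(convert_flux_units(0), 0)
  expect_equal(convert_flux_units(0.23), 1.46556)   # glucose uptake
  expect_equal(flux_conversion_factor(), 6.372)
  expect_equal(convert_flux_units(1, cell_volume = 2e-3), 7.2)
  expect_error(convert_flux_units(1, cell_volume = 0), "positive")
})

test_that("kinetic bound intervals scale the converted flux by 1 -/+ d", {
  b <- kinetic_bounds(1, 0.1, "C0", "r")
  expect_equal(b$lower, 6.372 * 0.9)
  expect_equal(b$upper, 6.372 * 1.1)
  # reversed category mirrors the interval into negative flux
  b4 <- kinetic_bounds(1, 0.1, "C4", "r")
  expect_equal(b4$lower, -7.0092)
  expect_equal(b4$upper, -5.7348)
  z <- kinetic_bounds(0, 0.3, "C2")
  expect_equal(c(z$lower, z$upper), c(0, 0))
  d0 <- kinetic_bounds(2, 0, "C1")
  expect_equal(d0$lower, d0$upper)            # d = 0 pins the flux
  expect_error(kinetic_bounds(-1, 0.1), "nonnegative")
  expect_error(kinetic_bounds(1, 1), "0 <= d < 1")
  expect_error(kinetic_bounds(1, 0.1, "C5"), "C5")
})

test_that("bound intervals nest in d and are centred on the converted flux", {
  ds <- c(0, 0.01, 0.06, 0.1, 0.3, 0.5, 0.9)
  for (f in c(0.05, 1, 3.7)) {
    for (cat in c("C0", "C4")) {
      prev <- NULL
      for (d in ds) {
        b <- kinetic_bounds(f, d, cat)
        expect_equal((b$lower + b$upper) / 2,
                     if (cat == "C4") -6.372 * f else 6.372 * f,
                     tolerance = 1e-12)
        if (!is.null(prev)) {   # interval at smaller d sits inside
          expect_lte(b$lower, prev$lower + 1e-12)
          expect_gte(b$upper, prev$upper - 1e-12)
        }
        prev <- b
      }
    }
  }
})

test_that("kinetic bounds are tighter than +/-1000 defaults for moderate fluxes", {
  for (f in c(0.01, 1, 50)) {
    b <- kinetic_bounds(f, 0.5, "C0")
    expect_lt(b$upper - b$lower, 2000)
    expect_true(b$upper < 1000)
  }
})

test_that("the C5 surrogate propagates net boundary flux through lumped reactions", {
  zoo <- make_category_zoo()
  entry <- zoo$mapping[zoo$mapping$category == "C5", ]
  # chain X -> Y -> Z at flux 2 lumped into X -> Z: net flux 2
  a <- translate_c5_subnetwork(entry, zoo$kinetic, zoo$gem, zoo$fluxes,
                               d = 0.1)
  expect_equal(a$reaction_id, "R5")
  expect_equal(a$lower, 2 * 6.372 * 0.9)
  expect_equal(a$upper, 2 * 6.372 * 1.1)
  expect_equal(a$category, "C5")
  # zero net flux collapses the interval to [0, 0]
  f0 <- zoo$fluxes; f0[c("R5a", "R5b")] <- 0
  a0 <- translate_c5_subnetwork(entry, zoo$kinetic, zoo$gem, f0, d = 0.1)
  expect_equal(c(a0$lower, a0$upper), c(0, 0))
  # a constraint reaction sharing no boundary metabolite is an error
  bad <- entry; bad$cbm_ids <- "R_C0"
  expect_error(translate_c5_subnetwork(bad, zoo$kinetic, zoo$gem,
                                       zoo$fluxes, d = 0.1),
               "no boundary metabolite")
})

test_that("bound application replaces listed bounds without mutating the input", {
  fx <- make_linear_chain(3, 1)
  m0 <- fx$gem
  expect_identical(apply_bounds(m0, m0$reactions[0, c(1, 3, 4)])$reactions$lower,
                   m0$reactions$lower)
  glc <- data.frame(reaction_id = "R1", lower = 1.46556, upper = 1.46556)
  m1 <- apply_bounds(m0, glc)
  expect_equal(m0$reactions$upper[1], 10)       # original untouched
  expect_equal(m1$reactions$lower[1], 1.46556)
  fba <- run_fba(m1)
  expect_equal(unname(fba$fluxes["R1"]), 1.46556, tolerance = 1e-9)
  expect_equal(fba$objective_value, 1.46556, tolerance = 1e-9)
  expect_equal(sum(m1$reactions$bound_source == "kinetic"), 1L)
  expect_error(apply_bounds(m0, data.frame(reaction_id = "nope",
                                           lower = 0, upper = 1)),
               "unknown reaction")
  expect_error(apply_bounds(m0, data.frame(reaction_id = "R1",
                                           lower = 2, upper = 1)),
               "lower > upper")
})

test_that("whole-table translation covers every mapped reaction in row order", {
  zoo <- make_category_zoo()
  asg <- translate_bounds(zoo$mapping, zoo$fluxes, d = 0.1,
                          kinetic_model = zoo$kinetic,
                          constraint_model = zoo$gem)
  expect_equal(asg$reaction_id,
               c("R_C0", "R_C1", "R_C2", "R_C3", "R_C4", "R5"))
  expect_true(all(asg$lower <= asg$upper))
  expect_true(all(asg$source == "kinetic"))
  # C4 interval is negative, all others positive
  expect_lt(asg$upper[asg$reaction_id == "R_C4"], 0)
  expect_true(all(asg$lower[asg$reaction_id != "R_C4"] >= 0))
  enriched <- apply_bounds(zoo$gem, asg)
  expect_equal(sum(enriched$reactions$bound_source == "kinetic"), 6L)
  # applying every translated bound leaves the kinetic fluxes feasible
  expect_equal(run_fba(enriched)$status, "optimal")
})

test_that("mapping tables survive a CSV round trip and reject bad categories", {
  zoo <- make_category_zoo()
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping(zoo$mapping, path)
  back <- read_mapping(path)
  expect_equal(back$kinetic_ids, zoo$mapping$kinetic_ids)
  expect_equal(back$category, zoo$mapping$category)
  bad <- zoo$mapping; bad$category[1] <- "C9"
  expect_error(validate_mapping(bad), "invalid category")
  bad2 <- zoo$mapping; bad2$kinetic_ids[1] <- "a;b"
  expect_error(validate_mapping(bad2), "one reaction")
})
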