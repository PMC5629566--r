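test_that("inner optima match hand-derived toy7 values", {
  m <- toy7()
  w <- toy7_w()
  expect_flux_equal(inner_optimum(m, c("R1", "R3", "R5"), "biomass")$value, 5)
  expect_equal(inner_optimum(m, character(0), "room", w)$value, 0,
               tolerance = 1e-7)
  # with R1 and R4 gone no biomass precursor can be made at all
  expect_equal(inner_optimum(m, c("R1", "R4"), "biomass")$status,
               "infeasible-design")
})

test_that("banded extremes reproduce the two-stage toy7 analysis", {
  m <- toy7()
  ev <- epsilon_extreme_flux(m, c("R1", "R3"), "biomass", 0)
  expect_flux_equal(ev$worst_flux, 0)
  expect_flux_equal(ev$best_flux, 5)
  ev2 <- epsilon_extreme_flux(m, c("R1", "R3", "R5"), "biomass", 0.5,
                              sense = "min")
  expect_flux_equal(ev2$worst_flux, 2.5)
  # infeasible designs propagate their status
  ev3 <- epsilon_extreme_flux(m, c("R1", "R4"), "biomass", 0)
  expect_equal(ev3$status, "infeasible-design")
})

test_that("band nesting: worst non-increasing, best non-decreasing in epsilon", {
  suite <- random_suite(c(51, 52))
  cases <- c(list(list(model = toy7(), w = toy7_w())), suite)
  for (case in cases) {
    m <- case$model
    d <- m$reactions$id[m$reactions$knockable][1:2]
    for (inner in c("biomass", "room")) {
      evs <- lapply(c(0, 0.3, 1), function(e)
        epsilon_extreme_flux(m, d, inner, e, case$w))
      if (evs[[1]]$status != "optimal") next
      worst <- vapply(evs, `[[`, 0, "worst_flux")
      best <- vapply(evs, `[[`, 0, "best_flux")
      expect_true(all(diff(worst) <= 1e-6))
      expect_true(all(diff(best) >= -1e-6))
      expect_true(all(worst <= best + 1e-6))
    }
  }
})

test_that("at eps = 0 the band is the inner-optimal face", {
  m <- toy7()
  d <- knockout_design(c("R1", "R3"))
  ev <- epsilon_extreme_flux(m, d, "biomass", 0)
  coop <- epsilon_extreme_flux(m, d, "biomass", 0, sense = "max")$best_flux
  expect_lte(ev$worst_flux, coop + 1e-6)
  expect_equal(ev$best_flux, coop, tolerance = 1e-6)
})

test_that("at eps = 1 the biomass band reduces to threshold-constrained FVA", {
  # independent FVA: direct LPs with only the viability threshold
  fva_direct <- function(m, design, sense) {
    solve_fba(m, pessknock:::reaction_of_role(m, "target"), sense,
              design = design, enforce_biomass_min = TRUE)$objective
  }
  suite <- random_suite(c(51, 52))
  cases <- c(list(list(model = toy7())), suite)
  for (case in cases) {
    m <- case$model
    d <- m$reactions$id[m$reactions$knockable][1]
    ev <- epsilon_extreme_flux(m, d, "biomass", 1)
    if (ev$status != "optimal") next
    expect_equal(ev$worst_flux, fva_direct(m, d, "min"), tolerance = 1e-6)
    expect_equal(ev$best_flux, fva_direct(m, d, "max"), tolerance = 1e-6)
  }
})

test_that("enumeration oracle scores toy7 exactly and tie-breaks lexicographically", {
  m <- toy7()
  o3 <- pessimistic_enumeration_oracle(m, 3, "biomass", 0)
  expect_identical(o3$design$knocked, c("R1", "R3", "R5"))
  expect_flux_equal(o3$objective, 5)
  o2 <- pessimistic_enumeration_oracle(m, 2, "biomass", 0)
  expect_flux_equal(o2$objective, 0)
  # all ties at 0 resolve to the first (empty) design in enumeration order
  expect_identical(o2$design$knocked, character(0))
  # infeasible full knockouts are excluded, a feasible subset is returned
  oK <- pessimistic_enumeration_oracle(m, 5, "biomass", 0)
  expect_equal(inner_optimum(m, oK$design, "biomass")$status, "optimal")
  # combinatorial guard refuses oversized enumerations with a size report
  expect_error(
    pessimistic_enumeration_oracle(m, 3, "biomass", 0, max_designs = 4L),
    "combinatorial budget exceeded: 26")
})
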