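test_that("OptKnock reproduces the toy7 enumeration optimum", {
  m <- toy7()
  res <- solve_optknock(m, 2)
  expect_identical(res$design$knocked, c("R1", "R3"))
  expect_flux_equal(res$objective, 5)
  # without knockouts all target precursor is recycled on the optimal face
  expect_flux_equal(solve_optknock(m, 0)$objective, 0)
})

test_that("optimistic MILPs agree with the cooperative enumeration referee", {
  suite <- random_suite(c(31, 32, 33))
  cases <- c(list(list(model = toy7(), w = toy7_w())), suite)
  for (case in cases) {
    m <- case$model
    for (K in c(1, 3)) {
      expect_flux_equal(solve_optknock(m, K)$objective,
                        optimistic_oracle(m, K, "biomass"))
      expect_flux_equal(solve_room_design(m, K, case$w)$objective,
                        optimistic_oracle(m, K, "room", case$w))
    }
  }
})

test_that("cooperative consistency: re-evaluating the returned design reproduces the objective", {
  m <- toy7()
  w <- toy7_w()
  ok <- solve_optknock(m, 2)
  ev <- epsilon_extreme_flux(m, ok$design, "biomass", 0, sense = "max")
  expect_equal(ev$best_flux, ok$objective, tolerance = 1e-4)
  rm_ <- solve_room_design(m, 3, w)
  ev2 <- epsilon_extreme_flux(m, rm_$design, "room", 0, w, sense = "max")
  expect_equal(ev2$best_flux, rm_$objective, tolerance = 1e-4)
})

test_that("embedded strong duality holds at the MILP optimum", {
  m <- toy7()
  res <- solve_optknock(m, 2)
  x <- res$solution
  rxn <- m$reactions
  z <- x[paste0("z_", rxn$id)]
  dual_obj <- x[["g"]] * m$uptake_rate - x[["m_b"]] * m$biomass_min +
    sum(rxn$ub * z * x[paste0("mmax_", rxn$id)]) -
    sum(rxn$lb * z * x[paste0("mmin_", rxn$id)])
  expect_equal(unname(x[["v_BIOM"]]), unname(dual_obj), tolerance = 1e-5)
})

test_that("OptKnock objective is non-decreasing in K and knocked fluxes vanish", {
  m <- toy7()
  objs <- vapply(0:3, function(K) solve_optknock(m, K)$objective, 0)
  expect_true(all(diff(objs) >= -1e-6))
  res <- solve_optknock(m, 3)
  for (id in res$design$knocked)
    expect_lt(abs(res$solution[[paste0("v_", id)]]), 1e-6)
})
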