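test_that("FBA reproduces hand-derived toy7 optima", {
  m <- toy7()
  expect_flux_equal(solve_fba(m, "BIOM", "max")$objective, 10)
  expect_flux_equal(solve_fba(m, "BIOM", "max",
                              design = c("R1", "R3", "R5"))$objective, 5)
  m50 <- m
  m50$biomass_min <- 50
  expect_equal(solve_fba(m50, "CHEM", "max")$status, "infeasible")
})

test_that("optimal solutions satisfy mass balance, bounds, and knockouts", {
  suite <- random_suite(c(21, 22, 23))
  for (case in suite) {
    m <- case$model
    kn <- m$reactions$id[m$reactions$knockable][1]
    sol <- solve_fba(m, pessknock:::reaction_of_role(m, "target"), "max",
                     design = kn)
    expect_equal(sol$status, "optimal")
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% sol$v)), 1e-6)
    expect_true(all(sol$v >= m$reactions$lb - 1e-6 &
                      sol$v <= m$reactions$ub + 1e-6))
    expect_lt(abs(sol$v[[kn]]), 1e-6)
  }
})

test_that("wild-type reference is biomass-optimal, parsimonious, deterministic", {
  m <- toy7()
  w <- toy7_w()
  # unique parsimonious solution: direct route only
  expect_flux_equal(w$biomass, 10)
  expect_equal(unname(w$w[c("UP", "R1", "BIOM")]), c(10, 10, 10),
               tolerance = 1e-6)
  expect_equal(unname(w$w[c("R2", "R3", "R4", "R5", "WD", "CHEM")]),
               rep(0, 6), tolerance = 1e-6)
  # biomass component equals the plain FBA optimum by construction
  expect_flux_equal(unname(w$w["BIOM"]), solve_fba(m, "BIOM", "max")$objective)
  # deterministic on a fixture with a degenerate biomass optimum
  d <- make_fixture("diamond")
  expect_identical(wild_type_fluxes(d)$w, wild_type_fluxes(d)$w)
  expect_identical(wild_type_fluxes(d)$w, wild_type_fluxes(d)$w)
})

test_that("wild-type reference equals the unique FBA solution when not degenerate", {
  # knocking nothing on toy7: parsimonious stage keeps biomass at 10 and the
  # total-flux-minimal route; re-solving gives identical w
  w1 <- wild_type_fluxes(toy7())
  w2 <- wild_type_fluxes(toy7())
  expect_identical(w1$w, w2$w)
})
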