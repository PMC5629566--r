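test_that("inner ROOM dual attains the primal optimum (strong duality)", {
  m <- toy7()
  w <- toy7_w()
  # wild type needs no changes at all: both optima are zero
  expect_equal(solve_lp(build_room_inner_dual(m, w))$objective, 0,
               tolerance = 1e-7)
  d <- knockout_design(c("R1", "R3", "R5"))
  pri <- solve_lp(pessknock:::room_inner_primal(m, w, d))
  dua <- solve_lp(build_room_inner_dual(m, w, d))
  expect_equal(pri$objective, dua$objective, tolerance = 1e-6)
  expect_flux_equal(pri$objective, 1.65, tol = 1e-6)  # hand-derived
  # knocking the uptake reaction is rejected before any LP is built
  expect_error(build_room_inner_dual(m, w, knockout_design("UP")),
               "non-knockable")
})

test_that("P-ROOM and P-OptKnock reproduce hand-derived toy7 guarantees", {
  m <- toy7()
  w <- toy7_w()
  pr <- solve_p_room(m, 3, 0, w)
  expect_identical(pr$design$knocked, c("R1", "R3", "R5"))
  expect_flux_equal(pr$objective, 5)
  po0 <- solve_p_optknock(m, 3, 0)
  expect_identical(po0$design$knocked, c("R1", "R3", "R5"))
  expect_flux_equal(po0$objective, 5)
  # at eps = 0.5 the mutant may halve its growth, diverting flux to waste
  expect_flux_equal(solve_p_optknock(m, 3, 0.5)$objective, 2.5)
})

test_that("pessimistic MILPs equal the enumeration oracle on a mixed grid", {
  suite <- random_suite(c(41, 42, 43))
  cases <- c(list(list(model = toy7(), w = toy7_w())), suite)
  eps_grid <- c(0, 0.5)
  for (case in cases) {
    m <- case$model
    tab_room <- worst_case_table(m, 2, "room", eps_grid, case$w)
    tab_biom <- worst_case_table(m, 2, "biomass", eps_grid)
    for (K in c(1, 2)) for (eps in eps_grid) {
      expect_flux_equal(solve_p_room(m, K, eps, case$w)$objective,
                        oracle_from_table(tab_room, K, eps))
      expect_flux_equal(solve_p_optknock(m, K, eps)$objective,
                        oracle_from_table(tab_biom, K, eps))
    }
  }
})

test_that("epsilon widening never improves the guarantee; K never hurts it", {
  m <- toy7()
  w <- toy7_w()
  for (K in c(2, 3)) {
    pr <- vapply(c(0, 0.25, 0.5, 1), function(e)
      solve_p_room(m, K, e, w)$objective, 0)
    expect_true(all(diff(pr) <= 1e-6))
    po <- vapply(c(0, 0.25, 0.5, 1), function(e)
      solve_p_optknock(m, K, e)$objective, 0)
    expect_true(all(diff(po) <= 1e-6))
  }
  byK <- vapply(0:3, function(K) solve_p_optknock(m, K, 0.2)$objective, 0)
  expect_true(all(diff(byK) >= -1e-6))
})

test_that("optimistic designs bound their pessimistic counterparts from above", {
  m <- toy7()
  w <- toy7_w()
  for (K in c(2, 3)) {
    ok <- solve_optknock(m, K)$objective
    rm_ <- solve_room_design(m, K, w)$objective
    for (eps in c(0, 0.4)) {
      expect_gte(ok + 1e-6, solve_p_optknock(m, K, eps)$objective)
      expect_gte(rm_ + 1e-6, solve_p_room(m, K, eps, w)$objective)
    }
  }
})

test_that("designs with an infeasible inner problem are never selected", {
  # force a model in which every allowed design kills viability except one
  m <- toy7()
  # raise the viability threshold so only designs keeping full growth work
  m$biomass_min <- 9
  res <- solve_p_optknock(m, 2, 0)
  ev <- inner_optimum(m, res$design, "biomass")
  expect_equal(ev$status, "optimal")
  expect_gte(ev$value, 9 - 1e-6)
})
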