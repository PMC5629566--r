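test_that("solver backend reports optimal, infeasible, and unbounded", {
  lp <- lp_new("max")
  lp_add_vars(lp, c("x", "y"), lb = 0, ub = 10, obj = c(1, 2))
  lp_add_row(lp, c("x", "y"), c(1, 1), ub = 4)
  sol <- solve_lp(lp)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 8, tolerance = 1e-8)
  expect_equal(unname(sol$x[c("x", "y")]), c(0, 4), tolerance = 1e-8)

  bad <- lp_new("min")
  lp_add_vars(bad, "x", lb = 3, ub = 10, obj = 1)
  lp_add_row(bad, "x", 1, ub = 1)
  expect_equal(solve_lp(bad)$status, "infeasible")

  unb <- lp_new("max")
  lp_add_vars(unb, "x", lb = 0, ub = Inf, obj = 1)
  expect_true(solve_lp(unb)$status %in% c("unbounded", "infeasible"))
})

test_that("batched solving returns per-problem results in order", {
  lps <- lapply(1:4, function(k) {
    lp <- lp_new("max")
    lp_add_vars(lp, "x", lb = 0, ub = k, obj = 1)
    lp
  })
  sols <- solve_lp_batch(lps)
  expect_equal(vapply(sols, `[[`, 0, "objective"), 1:4, tolerance = 1e-9)
})

test_that("big-M linearization forces xi = z * x exactly at both z values", {
  for (zfix in c(0, 1)) {
    lp <- lp_new("max")
    lp_add_vars(lp, "z", lb = zfix, ub = zfix, integer = TRUE)
    lp_add_vars(lp, "x", lb = 0, ub = 7, obj = 1)
    xi <- lp_product(lp, "z", "x", "xi")
    lp_add_row(lp, "x", 1, lb = 3, ub = 3)
    linearize_products(lp)
    sol <- solve_lp(lp)
    expect_equal(unname(sol$x["xi"]), zfix * 3, tolerance = 1e-7)
  }
})

test_that("linearized MILP optimum equals brute force over the binary", {
  # small bilinear instances: max c1*x + c2*(z*x) + c3*z subject to a
  # budget row; the oracle solves the LP separately at z = 0 and z = 1
  set.seed(4821)
  for (rep in 1:10) {
    cf <- round(stats::runif(3, -2, 2), 2)
    cap <- round(stats::runif(1, 1, 9), 2)
    brute <- sapply(c(0, 1), function(zv) {
      lp <- lp_new("max")
      lp_add_vars(lp, "x", lb = 0, ub = 5, obj = cf[1] + cf[2] * zv)
      lp_add_row(lp, "x", 1, ub = cap)
      solve_lp(lp)$objective + cf[3] * zv
    })
    lp <- lp_new("max")
    lp_add_vars(lp, "z", lb = 0, ub = 1, obj = cf[3], integer = TRUE)
    lp_add_vars(lp, "x", lb = 0, ub = 5, obj = cf[1])
    xi <- lp_product(lp, "z", "x", "xi")
    lp_add_obj(lp, xi, cf[2])
    lp_add_row(lp, "x", 1, ub = cap)
    linearize_products(lp)
    expect_equal(solve_lp(lp)$objective, max(brute), tolerance = 1e-6)
  }
})

test_that("products with unbounded factors and no M are a configuration error", {
  lp <- lp_new("max")
  lp_add_vars(lp, "z", lb = 0, ub = 1, integer = TRUE)
  lp_add_vars(lp, "x", lb = -Inf, ub = Inf)
  lp_product(lp, "z", "x", "xi")
  cfg <- big_m_config()
  cfg$M_dual <- Inf
  expect_error(linearize_products(lp, cfg), "unbounded")
})

test_that("big-M audit flags factors near their working bound", {
  lp <- lp_new("max")
  lp_add_vars(lp, "z", lb = 1, ub = 1, integer = TRUE)
  lp_add_vars(lp, "x", lb = 0, ub = 100, obj = 1)
  lp_product(lp, "z", "x", "xi", M = 100)
  linearize_products(lp)
  sol <- solve_lp(lp)
  expect_identical(audit_big_m(lp, sol), "xi")
})
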