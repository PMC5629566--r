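test_that("toy7 fixture has the documented structure", {
  m <- toy7()
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$metabolites), 4)
  expect_false(any(m$metabolites$external))
  expect_equal(nrow(m$reactions), 9)
  expect_equal(sum(m$reactions$knockable), 5)
  for (role in c("uptake", "biomass", "target"))
    expect_equal(sum(m$reactions$role == role), 1)
  up <- m$reactions[m$reactions$role == "uptake", ]
  expect_equal(up$lb, up$ub)  # fixed uptake
  expect_equal(up$lb, 10)
  expect_length(validate_model(m), 0)
})

test_that("tabular dialect round-trips models field-by-field", {
  for (name in c("toy7", "diamond")) {
    m <- make_fixture(name)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    expect_equal(load_model(path), m)
  }
  # reversible bounds survive sign-exactly
  m <- make_fixture("random", seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2, m)
})

test_that("save_model reports unwritable paths as I/O errors", {
  expect_error(save_model(toy7(), "/nonexistent-dir/x/y.json"), "I/O error")
})

test_that("malformed inputs give typed load errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", path)
  expect_error(load_model(path), "format error")

  # reaction referencing an unknown metabolite is an integrity error
  m <- toy7()
  m$reactions$stoich[[2]] <- c(A = -1, X = 1)
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(m, path2)
  expect_error(load_model(path2), "integrity error.*X")
})

test_that("validate_model reports violations instead of raising", {
  m <- toy7()
  expect_length(validate_model(m), 0)

  m_bad <- m
  m_bad$biomass_min <- 50   # wild-type max biomass is 10
  v <- validate_model(m_bad)
  expect_match(as.character(v), "biomass target exceeds achievable maximum",
               all = FALSE)

  m_bounds <- m
  m_bounds$reactions$lb[2] <- 5
  m_bounds$reactions$ub[2] <- 1
  v2 <- validate_model(m_bounds, check_feasibility = FALSE)
  expect_match(as.character(v2), "lower_bound > upper_bound", all = FALSE)
})

test_that("random fixtures are reproducible, feasible, and bounded in size", {
  expect_identical(make_fixture("random", seed = 7),
                   make_fixture("random", seed = 7))
  for (s in c(3, 11)) {
    m <- make_fixture("random", seed = s)
    expect_lte(sum(m$reactions$knockable), 8)
    sol <- solve_fba(m, pessknock:::reaction_of_role(m, "biomass"), "max")
    expect_equal(sol$status, "optimal")
    expect_gte(sol$objective, m$biomass_min - 1e-9)
  }
})

test_that("SBML (level 3, FBC) models load with roles and bounds resolved", {
  path <- system.file("extdata", "toy7_sbml.xml", package = "pessknock")
  m <- load_model(path, "sbml", uptake = "UP", target = "CHEM",
                  uptake_rate = 10, biomass_min = 1)
  expect_equal(nrow(m$metabolites), 4)
  expect_equal(nrow(m$reactions), 9)
  expect_equal(pessknock:::reaction_of_role(m, "biomass"), "BIOM")
  expect_equal(m$reactions$ub[m$reactions$id == "R1"], 100)
  expect_equal(solve_fba(m, "BIOM", "max")$objective, 10, tolerance = 1e-6)
})

test_that("knockout designs enforce budget and knockability", {
  expect_error(knockout_design(c("R1", "R2"), budget = 1), "budget")
  expect_error(pessknock:::check_design(toy7(), c("UP")), "non-knockable")
  d <- knockout_design(c("R3", "R1"))
  expect_identical(d$knocked, c("R1", "R3"))  # canonical order
})
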