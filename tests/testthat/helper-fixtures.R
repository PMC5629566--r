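# shared fixtures and referees, memoized so each expensive object is built
# once per test run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

toy7 <- function() memo("toy7", make_fixture("toy7"))
toy7_w <- function() memo("toy7_w", wild_type_fluxes(toy7()))

# seeded random fixtures with their wild-type references, computed in one
# batched solver call
random_suite <- function(seeds) {
  key <- paste0("suite_", paste(seeds, collapse = "_"))
  memo(key, {
    models <- lapply(seeds, function(s) make_fixture("random", seed = s))
    ws <- pessknock:::wild_type_fluxes_batch(models)
    Map(list, model = models, w = ws)
  })
}

# optimistic enumeration referee: cooperative value = best target flux on
# the inner-optimal face, maximized over all designs of size <= K
optimistic_oracle <- function(model, K, inner_model, w = NULL) {
  tab <- worst_case_table(model, K, inner_model, epsilons = 0, w = w,
                          sense = "max")
  max(tab$flux, na.rm = TRUE)
}

# oracle worst-case optimum for budget K drawn from a precomputed table
oracle_from_table <- function(tab, K, eps) {
  rows <- tab$size <= K & tab$epsilon == eps
  max(replace(tab$flux[rows], is.na(tab$flux[rows]), -Inf))
}

expect_flux_equal <- function(object, expected, tol = 1e-4) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("flux %.6f vs expected %.6f", object, expected))
}
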