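# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rxn_row <- function(id, stoich, lb = 0, ub = 100, knockable = TRUE,
                    role = "internal") {
  data.frame(id = id, lb = lb, ub = ub, knockable = knockable, role = role,
             stoich = I(list(stoich)), stringsAsFactors = FALSE)
}

#' Built-in toy networks and a seeded random network generator
#'
#' Self-contained fixtures emulating the structural features of real strain
#' design instances: a fixed substrate uptake, a biomass threshold, and
#' competing secretion routes that make the cellular response non-unique
#' (the situation pessimistic design exists for).
#'
#' * `toy7`: a fixed 4-metabolite, 9-reaction network.  Substrate A enters at
#'   10 mmol/gDW/hr; B feeds biomass; C is the target chemical, which can
#'   also escape through an uncredited sink `R5`; D is a waste route.  All
#'   bounds are \[0, 100\] except the fixed uptake \[10, 10\].
#' * `diamond`: two parallel A->...->D arms with a target tap on one arm;
#'   its biomass optimum is degenerate, exercising tie-breaking.
#' * `random`: a reproducible, mass-balanced, FBA-feasible network drawn
#'   from `seed` with 3-5 internal metabolites, a conversion DAG with mixed
#'   stoichiometric yields, optional reversible steps, and an uncredited
#'   sink competing with the target (at most 8 knockable reactions).
#'
#' @param name `"toy7"`, `"diamond"`, or `"random"`.
#' @param seed integer seed (used by `"random"` only).
#' @param params optional list of overrides for `"random"`:
#'   `n_internal`, `uptake_rate`, `biomass_min`, `max_attempts`.
#' @return a [metabolic_model()].
#' @examples
#' \dontrun{
#' m <- make_fixture("toy7")
#' solve_fba(m, "BIOM", "max")$objective  # 10
#' }
#' @export
make_fixture <- function(name = c("toy7", "diamond", "random"), seed = 1L,
                         params = list()) {
  name <- match.arg(name)
  switch(name,
         toy7 = fixture_toy7(),
         diamond = fixture_diamond(),
         random = fixture_random(seed, params))
}

fixture_toy7 <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"),
                     name = c("A", "B", "C", "D"),
                     external = FALSE, stringsAsFactors = FALSE)
  rxn <- rbind(
    rxn_row("UP",   c(A = 1), lb = 10, ub = 10, knockable = FALSE, role = "uptake"),
    rxn_row("R1",   c(A = -1, B = 1)),
    rxn_row("R2",   c(A = -1, D = 1)),
    rxn_row("R3",   c(C = -1, B = 1)),
    rxn_row("R4",   c(A = -1, B = 0.5, C = 0.5)),
    rxn_row("R5",   c(C = -1)),
    rxn_row("WD",   c(D = -1), knockable = FALSE),
    rxn_row("BIOM", c(B = -1), knockable = FALSE, role = "biomass"),
    rxn_row("CHEM", c(C = -1), knockable = FALSE, role = "target"))
  metabolic_model(mets, rxn, uptake_rate = 10, biomass_min = 1, id = "toy7")
}

fixture_diamond <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"),
                     name = c("A", "B", "C", "D"),
                     external = FALSE, stringsAsFactors = FALSE)
  rxn <- rbind(
    rxn_row("UP",   c(A = 1), lb = 10, ub = 10, knockable = FALSE, role = "uptake"),
    rxn_row("L1",   c(A = -1, B = 1)),
    rxn_row("L2",   c(A = -1, C = 1)),
    rxn_row("M1",   c(B = -1, D = 1)),
    rxn_row("M2",   c(C = -1, D = 1)),
    rxn_row("BIOM", c(D = -1), knockable = FALSE, role = "biomass"),
    rxn_row("CHEM", c(C = -1), knockable = FALSE, role = "target"))
  metabolic_model(mets, rxn, uptake_rate = 10, biomass_min = 1, id = "diamond")
}

fixture_random <- function(seed, params = list()) {
  uptake_rate <- params$uptake_rate %||% 10
  biomass_min <- params$biomass_min %||% 1
  max_attempts <- params$max_attempts %||% 40L
  with_seed(as.integer(seed), {
    for (attempt in seq_len(max_attempts)) {
      m <- random_network_draw(params$n_internal, uptake_rate, biomass_min,
                               seed, attempt)
      sol <- solve_fba(m, reaction_of_role(m, "biomass"), "max")
      if (sol$status == "optimal" && sol$objective >= biomass_min - 1e-9)
        return(m)
    }
    stop("generation error: no FBA-feasible random network in ",
         max_attempts, " attempts (seed ", seed, ")")
  })
}

random_network_draw <- function(n_internal, uptake_rate, biomass_min,
                                seed, attempt) {
  n <- n_internal %||% sample(3:5, 1)
  mets <- data.frame(id = paste0("M", seq_len(n)),
                     name = paste0("M", seq_len(n)),
                     external = FALSE, stringsAsFactors = FALSE)
  rxn <- rxn_row("UP", c(M1 = 1), lb = uptake_rate, ub = uptake_rate,
                 knockable = FALSE, role = "uptake")
  coef_pool <- c(0.5, 1, 1, 1, 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # backbone i -> i+1 always present; other forward edges with prob 0.4
      if (j != i + 1 && stats::runif(1) > 0.4) next
      k <- k + 1L
      st <- stats::setNames(c(-1, sample(coef_pool, 1)),
                            c(paste0("M", i), paste0("M", j)))
      lb <- if (j != i + 1 && stats::runif(1) < 0.2) -100 else 0
      rxn <- rbind(rxn, rxn_row(paste0("C", k), st, lb = lb, ub = 100))
    }
  }
  # branching reaction with two products, mimicking split yields
  if (n >= 3) {
    k <- k + 1L
    tgt <- sample(2:n, 2)
    st <- stats::setNames(c(-1, 0.5, 0.5), c("M1", paste0("M", tgt)))
    rxn <- rbind(rxn, rxn_row(paste0("C", k), st))
  }
  biomass_met <- paste0("M", n)
  target_met <- paste0("M", sample(2:max(2, n - 1), 1))
  rxn <- rbind(
    rxn,
    rxn_row("BIOM", stats::setNames(-1, biomass_met), knockable = FALSE,
            role = "biomass"),
    rxn_row("CHEM", stats::setNames(-1, target_met), knockable = FALSE,
            role = "target"),
    # uncredited sink competing with the target reaction
    rxn_row("SINK", stats::setNames(-1, target_met)))
  if (stats::runif(1) < 0.5) {
    waste <- paste0("M", sample(2:n, 1))
    rxn <- rbind(rxn, rxn_row("WASTE", stats::setNames(-1, waste),
                              knockable = FALSE))
  }
  # cap the knockable set so exhaustive enumeration stays cheap
  kn <- which(rxn$knockable)
  if (length(kn) > 8) rxn$knockable[kn[-seq_len(8)]] <- FALSE
  metabolic_model(mets, rxn, uptake_rate = uptake_rate,
                  biomass_min = biomass_min,
                  id = sprintf("random-%d-%d", seed, attempt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
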