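# ---- worst/best-case evaluation of FIXED knockout designs ------------------
#
# The evaluator answers: given a knockout set that is already decided, what
# target flux can actually be relied on if the cell responds with *any*
# flux distribution whose inner objective is within the epsilon band of
# optimal?  It is a two-stage LP: stage 1 computes the inner optimum phi*,
# stage 2 optimizes the target flux over the banded response set.  The same
# procedure, applied to every candidate design, is the brute-force referee
# for the pessimistic MILPs.

inner_problem <- function(model, design, inner_model, w) {
  if (inner_model == "room") {
    room_inner_primal(model, w, design)
  } else {
    lp <- lp_new("max")
    fba_primal_block(lp, model, design, enforce_biomass_min = TRUE)
    lp_add_obj(lp, paste0("v_", reaction_of_role(model, "biomass")), 1)
    lp
  }
}

# epsilon-band stage-2 LP: optimize the target flux over inner-feasible
# responses whose inner objective is within the band around phi.  A 1e-7
# absolute slack absorbs LP round-off (without it stage 2 can be spuriously
# infeasible at epsilon = 0).
band_problem <- function(model, design, inner_model, epsilon, phi, w, sense) {
  lp <- lp_new(sense)
  vn <- fba_primal_block(lp, model, design, enforce_biomass_min = TRUE)
  if (inner_model == "room") {
    yn <- room_change_block(lp, model, w, vn)
    lp_add_row(lp, yn, rep(1, length(yn)),
               ub = phi * (1 + epsilon) + 1e-7)
  } else {
    lp_add_row(lp, paste0("v_", reaction_of_role(model, "biomass")), 1,
               lb = (1 - epsilon) * phi - 1e-7)
  }
  lp_add_obj(lp, paste0("v_", reaction_of_role(model, "target")), 1)
  lp
}

evaluation_result <- function(design, inner_model, epsilon, worst, best, phi,
                              status = "optimal") {
  structure(list(design = design, inner_model = inner_model,
                 epsilon = epsilon, worst_flux = worst, best_flux = best,
                 inner_optimum = phi, status = status),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, digits = 4, ...) {
  cat("Worst-case evaluation (inner model: ", x$inner_model,
      ", epsilon = ", x$epsilon, ")\n", sep = "")
  cat("  knockouts: ",
      if (length(x$design$knocked)) paste(x$design$knocked, collapse = ", ")
      else "<none>", "\n", sep = "")
  if (x$status != "optimal") {
    cat("  status: ", x$status, "\n", sep = "")
  } else {
    cat("  inner optimum phi* = ", format(x$inner_optimum, digits = digits),
        "; target flux in [",
        format(x$worst_flux, digits = digits), ", ",
        format(x$best_flux, digits = digits), "] mmol/gDW/hr\n", sep = "")
  }
  invisible(x)
}

#' Inner-model optimum for a fixed knockout design
#'
#' Computes `phi*`: the minimal sum of relaxed flux-change indicators
#' (`inner_model = "room"`) or the maximal biomass flux
#' (`inner_model = "biomass"`) a mutant carrying `design` can realize.
#'
#' @param model a [metabolic_model()].
#' @param design a [knockout_design()] or character vector of reaction ids.
#' @param inner_model `"room"` or `"biomass"`.
#' @param w wild-type reference (required for `"room"`).
#' @return list with `value` (`phi*`, `NA` when infeasible) and `status`
#'   (`"optimal"` or `"infeasible-design"` when the viability threshold is
#'   unreachable under the design).
#' @export
inner_optimum <- function(model, design, inner_model = c("room", "biomass"),
                          w = NULL) {
  inner_model <- match.arg(inner_model)
  if (inner_model == "room") w <- check_wild_type(model, w)
  design <- check_design(model, design)
  sol <- solve_lp(inner_problem(model, design, inner_model, w))
  if (sol$status != "optimal")
    return(list(value = NA_real_, status = "infeasible-design"))
  list(value = sol$objective, status = "optimal")
}

#' Extreme target flux over the epsilon-approximation band
#'
#' Stage 1 computes the inner optimum `phi*` for the fixed design; stage 2
#' minimizes and/or maximizes the target flux over all responses satisfying
#' the inner constraints plus the band on the inner objective
#' (`sum(y) <= (1 + epsilon) phi*` for ROOM;
#' `v_biomass >= max(biomass_min, (1 - epsilon) phi*)` for the biomass
#' model).  `sense = "min"` is the pessimistic evaluation — the flux the
#' design guarantees; `"max"` the optimistic one.
#'
#' @inheritParams inner_optimum
#' @param epsilon nonnegative band tolerance.
#' @param sense `"min"`, `"max"`, or `"both"`.
#' @return an `"evaluation_result"` with `worst_flux`, `best_flux` (NA when
#'   not requested), `inner_optimum`, and `status` (propagates
#'   `"infeasible-design"`).
#' @export
epsilon_extreme_flux <- function(model, design,
                                 inner_model = c("room", "biomass"),
                                 epsilon = 0, w = NULL,
                                 sense = c("both", "min", "max")) {
  inner_model <- match.arg(inner_model)
  sense <- match.arg(sense)
  stopifnot(epsilon >= 0)
  if (inner_model == "room") w <- check_wild_type(model, w)
  design <- check_design(model, design)
  phi <- inner_optimum(model, design, inner_model, w)
  if (phi$status != "optimal")
    return(evaluation_result(design, inner_model, epsilon, NA_real_,
                             NA_real_, NA_real_, "infeasible-design"))
  senses <- if (sense == "both") c("min", "max") else sense
  lps <- lapply(senses, function(s)
    band_problem(model, design, inner_model, epsilon, phi$value, w, s))
  sols <- solve_lp_batch(lps)
  out <- stats::setNames(lapply(sols, function(s)
    if (s$status == "optimal") s$objective else NA_real_), senses)
  evaluation_result(design, inner_model, epsilon,
                    worst = out$min %||% NA_real_,
                    best = out$max %||% NA_real_,
                    phi = phi$value)
}

# lexicographically ordered subsets (by size, then id order) of the
# knockable set, up to size K
design_subsets <- function(model, K) {
  ids <- sort(knockable_ids(model))
  out <- list(character(0))
  for (k in seq_len(min(K, length(ids)))) {
    cmb <- utils::combn(ids, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Worst-case scores of every candidate design (brute force)
#'
#' Enumerates all knockout subsets of size at most `K`, evaluates each with
#' the two-stage band LP at every requested `epsilon`, and returns the full
#' score table.  All stage-1 LPs, and then all stage-2 LPs, are solved in
#' batched solver calls.
#'
#' @inheritParams epsilon_extreme_flux
#' @param K knockout budget.
#' @param epsilons numeric vector of band tolerances.
#' @param sense `"min"` (pessimistic scoring, the default) or `"max"`
#'   (optimistic/cooperative scoring).
#' @param max_designs refuse (with a size report) beyond this many subsets.
#' @return data frame with columns `knocked` (comma-joined ids), `size`,
#'   `epsilon`, `phi`, `flux` (the extreme target flux in the requested
#'   sense; NA for infeasible designs).
#' @export
worst_case_table <- function(model, K, inner_model = c("room", "biomass"),
                             epsilons = 0, w = NULL, sense = c("min", "max"),
                             max_designs = 20000L) {
  inner_model <- match.arg(inner_model)
  sense <- match.arg(sense)
  if (inner_model == "room") w <- check_wild_type(model, w)
  subsets <- design_subsets(model, K)
  if (length(subsets) > max_designs)
    stop("combinatorial budget exceeded: ", length(subsets),
         " candidate designs (limit ", max_designs, ")")
  designs <- lapply(subsets, knockout_design, budget = K)
  stage1 <- lapply(designs, function(d)
    inner_problem(model, d, inner_model, w))
  sol1 <- solve_lp_batch(stage1)
  phis <- vapply(sol1, function(s)
    if (s$status == "optimal") s$objective else NA_real_, 0)
  grid <- expand.grid(d = seq_along(designs), e = seq_along(epsilons))
  feas <- !is.na(phis[grid$d])
  stage2 <- lapply(which(feas), function(k)
    band_problem(model, designs[[grid$d[k]]], inner_model,
                 epsilons[grid$e[k]], phis[grid$d[k]], w, sense))
  sol2 <- solve_lp_batch(stage2)
  flux <- rep(NA_real_, nrow(grid))
  flux[feas] <- vapply(sol2, function(s)
    if (s$status == "optimal") s$objective else NA_real_, 0)
  data.frame(
    knocked = vapply(subsets[grid$d], paste, "", collapse = ","),
    size = vapply(subsets[grid$d], length, 0L),
    epsilon = epsilons[grid$e],
    phi = phis[grid$d],
    flux = flux,
    stringsAsFactors = FALSE)
}

#' Brute-force pessimistic design (the referee for the MILPs)
#'
#' Enumerates every feasible design of size at most `K`, scores each by its
#' pessimistic (worst-case) target flux in the epsilon band, and returns
#' the argmax.  Ties are broken bit-identically by enumeration order:
#' smaller designs first, then lexicographic order of the knocked-id sets.
#'
#' @inheritParams worst_case_table
#' @param epsilon a single band tolerance.
#' @return a `"strain_design"`-like object of class
#'   `c("oracle_design", "strain_design")` with the winning design and its
#'   guaranteed worst-case flux; the full score table is attached as
#'   `$table`.
#' @export
pessimistic_enumeration_oracle <- function(model, K,
                                           inner_model = c("room", "biomass"),
                                           epsilon = 0, w = NULL,
                                           max_designs = 20000L) {
  inner_model <- match.arg(inner_model)
  tab <- worst_case_table(model, K, inner_model, epsilon, w,
                          sense = "min", max_designs = max_designs)
  if (all(is.na(tab$flux)))
    stop("no feasible design of size <= ", K)
  best <- which.max(replace(tab$flux, is.na(tab$flux), -Inf))
  knocked <- if (nzchar(tab$knocked[best]))
    strsplit(tab$knocked[best], ",", fixed = TRUE)[[1]] else character(0)
  structure(
    list(design = knockout_design(knocked, budget = K),
         objective = tab$flux[best],
         method = if (inner_model == "room") "p_room" else "p_optknock",
         epsilon = epsilon,
         model_id = model$id,
         target = reaction_of_role(model, "target"),
         solver_stats = list(status = "optimal", oracle = TRUE),
         solution = NULL,
         table = tab),
    class = c("oracle_design", "strain_design"))
}
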