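flux_solution <- function(v, objective, status) {
  structure(list(v = v, objective = objective, status = status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, digits = 4, ...) {
  cat("Flux solution: status ", x$status, sep = "")
  if (!is.na(x$objective)) cat(", objective ", format(x$objective, digits = digits), sep = "")
  cat("\n")
  if (!is.null(x$v)) {
    nz <- x$v[abs(x$v) > 1e-9]
    cat("  nonzero fluxes: ",
        paste(sprintf("%s=%.4g", names(nz), nz), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# primal FBA variable block: adds v_<id> variables with design-aware bounds,
# mass-balance rows, the fixed-uptake constraint (as bounds) and optional
# biomass threshold; returns the variable names in reaction order.
fba_primal_block <- function(lp, model, design = NULL,
                             enforce_biomass_min = TRUE, prefix = "v_") {
  design <- check_design(model, design)
  z <- design_z(model, design)
  rxn <- model$reactions
  lb <- rxn$lb * z
  ub <- rxn$ub * z
  up <- which(rxn$role == "uptake")
  lb[up] <- model$uptake_rate
  ub[up] <- model$uptake_rate
  if (enforce_biomass_min) {
    bi <- which(rxn$role == "biomass")
    lb[bi] <- max(lb[bi], model$biomass_min)
  }
  vn <- paste0(prefix, rxn$id)
  lp_add_vars(lp, vn, lb = lb, ub = ub)
  tr <- stoich_triplets(model)
  for (i in seq_along(tr$mets)) {
    sel <- tr$i == i
    lp_add_row(lp, vn[tr$j[sel]], tr$x[sel], lb = 0, ub = 0)
  }
  vn
}

#' Solve a flux balance analysis linear program
#'
#' Maximizes or minimizes the flux of one reaction subject to steady-state
#' mass balance, flux bounds (with knocked reactions forced to zero), the
#' fixed substrate uptake, and optionally the biomass viability threshold.
#'
#' @param model a [metabolic_model()].
#' @param objective_reaction reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @param design optional [knockout_design()] (or character vector of
#'   reaction ids) forcing those fluxes to zero.
#' @param enforce_biomass_min impose `v_biomass >= biomass_min`.
#' @return a `flux_solution`: named flux vector `v`, `objective`, and
#'   `status` (`"optimal"`, `"infeasible"`, `"unbounded"`, or `"error"`).
#'   Infeasibility is reported in `status`, not raised.
#' @export
solve_fba <- function(model, objective_reaction, sense = c("max", "min"),
                      design = NULL, enforce_biomass_min = TRUE) {
  sense <- match.arg(sense)
  stopifnot(objective_reaction %in% model$reactions$id)
  lp <- lp_new(sense)
  vn <- fba_primal_block(lp, model, design, enforce_biomass_min)
  lp_add_obj(lp, paste0("v_", objective_reaction), 1)
  sol <- solve_lp(lp)
  v <- if (is.null(sol$x)) NULL else {
    out <- sol$x[vn]
    names(out) <- model$reactions$id
    out
  }
  flux_solution(v, sol$objective, sol$status)
}

#' Wild-type reference flux distribution
#'
#' Computes the reference fluxes `w` that the ROOM-type inner models measure
#' deviation against.  Stage one maximizes biomass by FBA; because that
#' optimum is typically degenerate, stage two selects, among biomass-optimal
#' solutions, the one minimizing total absolute flux (parsimonious
#' tie-breaking).  This pins down a unique, solver-independent reference so
#' that all downstream ROOM/P-ROOM results are reproducible.
#'
#' @param model a [metabolic_model()].
#' @return an object of class `"wild_type_reference"`: list with `w` (named
#'   flux vector) and `biomass` (the wild-type maximum biomass flux).
#' @export
wild_type_fluxes <- function(model) {
  wild_type_fluxes_batch(list(model))[[1L]]
}

wild_type_fluxes_batch <- function(models) {
  stage1 <- lapply(models, function(m) {
    lp <- lp_new("max")
    fba_primal_block(lp, m, enforce_biomass_min = FALSE)
    lp_add_obj(lp, paste0("v_", reaction_of_role(m, "biomass")), 1)
    lp
  })
  sol1 <- solve_lp_batch(stage1)
  stage2 <- vector("list", length(models))
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (sol1[[k]]$status != "optimal")
      stop("wild-type FBA is ", sol1[[k]]$status, " for model '", m$id,
           "'; see validate_model()")
    phi <- sol1[[k]]$objective
    lp <- lp_new("min")
    vn <- fba_primal_block(lp, m, enforce_biomass_min = FALSE)
    bi <- paste0("v_", reaction_of_role(m, "biomass"))
    lp_add_row(lp, bi, 1, lb = phi - 1e-9)
    pn <- paste0("pos_", m$reactions$id)
    nn <- paste0("neg_", m$reactions$id)
    lp_add_vars(lp, pn, lb = 0, ub = Inf, obj = 1)
    lp_add_vars(lp, nn, lb = 0, ub = Inf, obj = 1)
    for (j in seq_along(vn))
      lp_add_row(lp, c(vn[j], pn[j], nn[j]), c(1, -1, 1), lb = 0, ub = 0)
    stage2[[k]] <- lp
  }
  sol2 <- solve_lp_batch(stage2)
  lapply(seq_along(models), function(k) {
    m <- models[[k]]
    if (sol2[[k]]$status != "optimal")
      stop("parsimonious stage of wild_type_fluxes failed: ",
           sol2[[k]]$status)
    w <- sol2[[k]]$x[paste0("v_", m$reactions$id)]
    names(w) <- m$reactions$id
    # snap solver round-off so w is a clean reference
    w[abs(w) < 1e-9] <- 0
    structure(list(w = w, biomass = sol1[[k]]$objective),
              class = "wild_type_reference")
  })
}

#' @export
print.wild_type_reference <- function(x, ...) {
  cat("Wild-type reference (max biomass ", format(x$biomass), ")\n", sep = "")
  nz <- x$w[abs(x$w) > 1e-9]
  cat("  nonzero fluxes: ",
      paste(sprintf("%s=%.4g", names(nz), nz), collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_wild_type <- function(model, w) {
  if (is.null(w)) return(wild_type_fluxes(model))
  if (inherits(w, "wild_type_reference")) return(w)
  stopifnot(is.numeric(w), !is.null(names(w)))
  if (!setequal(names(w), model$reactions$id))
    stop("wild-type reference does not cover the model's reactions")
  structure(list(w = w[model$reactions$id],
                 biomass = unname(w[reaction_of_role(model, "biomass")])),
            class = "wild_type_reference")
}
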