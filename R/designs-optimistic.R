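# ---- shared MILP building blocks -------------------------------------------
#
# All four design methods share the same skeleton: binary knockout variables
# z_j (z_j = 0 knocks reaction j out), a budget row, a primal flux block
# linked to z through v_min_j z_j <= v_j <= v_max_j z_j, and an embedded dual
# block of the relevant inner LP whose bilinear dual-times-z terms are big-M
# linearized.

# knockout variables + budget row; non-knockable reactions are fixed active
design_z_block <- function(lp, model, K) {
  rxn <- model$reactions
  zn <- paste0("z_", rxn$id)
  lp_add_vars(lp, zn, lb = ifelse(rxn$knockable, 0, 1), ub = 1, integer = TRUE)
  kn <- zn[rxn$knockable]
  if (length(kn))
    lp_add_row(lp, kn, rep(1, length(kn)), lb = length(kn) - K)
  zn
}

# primal flux block with *variable* z: bounds become rows v - lb z >= 0,
# v - ub z <= 0; uptake is an explicit equality (its dual appears in the
# embedded dual blocks) and the biomass threshold an explicit inequality.
linked_primal_block <- function(lp, model, zn, prefix = "v_") {
  rxn <- model$reactions
  vn <- paste0(prefix, rxn$id)
  lp_add_vars(lp, vn, lb = pmin(rxn$lb, 0), ub = pmax(rxn$ub, 0))
  tr <- stoich_triplets(model)
  for (i in seq_along(tr$mets)) {
    sel <- tr$i == i
    lp_add_row(lp, vn[tr$j[sel]], tr$x[sel], lb = 0, ub = 0)
  }
  up <- which(rxn$role == "uptake")
  bi <- which(rxn$role == "biomass")
  lp_add_row(lp, vn[up], 1, lb = model$uptake_rate, ub = model$uptake_rate)
  lp_add_row(lp, vn[bi], 1, lb = model$biomass_min)
  for (j in seq_len(nrow(rxn))) {
    if (rxn$lb[j] != 0) lp_add_row(lp, c(vn[j], zn[j]), c(1, -rxn$lb[j]), lb = 0)
    else lp_add_row(lp, vn[j], 1, lb = 0)
    if (rxn$ub[j] != 0) lp_add_row(lp, c(vn[j], zn[j]), c(1, -rxn$ub[j]), ub = 0)
    else lp_add_row(lp, vn[j], 1, ub = 0)
  }
  vn
}

# ROOM flux-change rows tying fluxes to the wild-type reference w through
# relaxed change indicators in [0, 1]
room_change_block <- function(lp, model, w, vn, prefix = "y_") {
  rxn <- model$reactions
  yn <- paste0(prefix, rxn$id)
  lp_add_vars(lp, yn, lb = 0, ub = 1)
  for (j in seq_len(nrow(rxn))) {
    wj <- w$w[[rxn$id[j]]]
    lp_add_row(lp, c(vn[j], yn[j]), c(1, -(rxn$ub[j] - wj)), ub = wj)
    lp_add_row(lp, c(vn[j], yn[j]), c(1, -(rxn$lb[j] - wj)), lb = wj)
  }
  yn
}


# product of z_j with a dual variable: a true bilinear product only for
# knockable reactions; otherwise z_j is fixed at 1 and the product is the
# variable itself (no big-M rows, nothing to audit)
z_dual_product <- function(lp, model, zn, xvars, tag, M) {
  vapply(seq_len(nrow(model$reactions)), function(j) {
    if (model$reactions$knockable[j])
      lp_product(lp, zn[j], xvars[j], paste0(tag, model$reactions$id[j]), M = M)
    else xvars[j]
  }, "")
}


# duals of the uptake reaction's bound/change constraints are pinned to
# zero: those constraints are implied by the fixed-uptake equality (whose
# own dual absorbs any multiplier mass), and leaving them free creates a
# flat dual ray that drifts to the big-M bound and amplifies solver
# round-off into the objective
lp_fix_zero <- function(lp, names) {
  idx <- lp_var_index(lp, names)
  lp$var_lb[idx] <- 0
  lp$var_ub[idx] <- 0
  invisible(lp)
}

milp_meta <- function(model) {
  list(rxn = model$reactions$id,
       glc = reaction_of_role(model, "uptake"),
       biom = reaction_of_role(model, "biomass"),
       chem = reaction_of_role(model, "target"))
}

# ---- OptKnock ---------------------------------------------------------------

# single-level OptKnock MILP: outer max of target flux; the inner
# max-biomass LP is replaced by {primal feasibility, dual feasibility,
# primal objective = dual objective}
optknock_milp <- function(model, K, config = big_m_config()) {
  M <- config$M_dual
  meta <- milp_meta(model)
  rxn <- model$reactions
  lp <- lp_new("max")
  zn <- design_z_block(lp, model, K)
  vn <- linked_primal_block(lp, model, zn)
  lp_add_obj(lp, paste0("v_", meta$chem), 1)
  # duals of the inner max-biomass LP
  tr <- stoich_triplets(model)
  un <- paste0("u_", tr$mets)
  lp_add_vars(lp, un, lb = -M, ub = M)
  lp_add_vars(lp, "g", lb = -M, ub = M)
  lp_add_vars(lp, "m_b", lb = 0, ub = M)
  mmin <- paste0("mmin_", rxn$id); mmax <- paste0("mmax_", rxn$id)
  lp_add_vars(lp, mmin, lb = 0, ub = M)
  lp_add_vars(lp, mmax, lb = 0, ub = M)
  jup <- which(rxn$role == "uptake")
  lp_fix_zero(lp, c(mmin[jup], mmax[jup]))
  # dual feasibility, one row per flux variable
  for (j in seq_len(nrow(rxn))) {
    sel <- tr$j == j
    vars <- c(un[tr$i[sel]], mmax[j], mmin[j])
    coefs <- c(tr$x[sel], 1, -1)
    if (rxn$id[j] == meta$glc) { vars <- c(vars, "g"); coefs <- c(coefs, 1) }
    if (rxn$id[j] == meta$biom) { vars <- c(vars, "m_b"); coefs <- c(coefs, -1) }
    rhs <- as.numeric(rxn$id[j] == meta$biom)
    lp_add_row(lp, vars, coefs, lb = rhs, ub = rhs)
  }
  # strong duality: inner primal objective equals inner dual objective
  xi_min <- z_dual_product(lp, model, zn, mmin, "ximin_", M)
  xi_max <- z_dual_product(lp, model, zn, mmax, "ximax_", M)
  lp_add_row(lp,
             c(paste0("v_", meta$biom), "g", "m_b", xi_max, xi_min),
             c(1, -model$uptake_rate, model$biomass_min,
               -rxn$ub, rxn$lb),
             lb = 0, ub = 0)
  linearize_products(lp, config)
  lp
}

# ---- ROOM (LP variant, optimistic) -----------------------------------------

# single-level MILP for the optimistic design with the ROOM inner model:
# inner LP minimizes the number of (relaxed) flux changes from the wild type
room_milp <- function(model, K, w, config = big_m_config()) {
  M <- config$M_dual
  meta <- milp_meta(model)
  rxn <- model$reactions
  lp <- lp_new("max")
  zn <- design_z_block(lp, model, K)
  vn <- linked_primal_block(lp, model, zn)
  yn <- room_change_block(lp, model, w, vn)
  lp_add_obj(lp, paste0("v_", meta$chem), 1)
  tr <- stoich_triplets(model)
  un <- paste0("u_", tr$mets)
  lp_add_vars(lp, un, lb = -M, ub = M)
  lp_add_vars(lp, "g", lb = -M, ub = M)
  lp_add_vars(lp, "mu_b", lb = 0, ub = M)
  mu <- list(min = paste0("mumin_", rxn$id), max = paste0("mumax_", rxn$id),
             min2 = paste0("mumin2_", rxn$id), max2 = paste0("mumax2_", rxn$id),
             a = paste0("a_", rxn$id))
  for (v in mu) lp_add_vars(lp, v, lb = 0, ub = M)
  jup <- which(rxn$role == "uptake")
  lp_fix_zero(lp, c(mu$min[jup], mu$max[jup], mu$min2[jup], mu$max2[jup]))
  wv <- w$w[rxn$id]
  # dual feasibility for the flux columns (all have zero inner objective)
  for (j in seq_len(nrow(rxn))) {
    sel <- tr$j == j
    vars <- c(un[tr$i[sel]], mu$min[j], mu$max[j], mu$max2[j], mu$min2[j])
    coefs <- c(tr$x[sel], 1, -1, -1, 1)
    if (rxn$id[j] == meta$glc) { vars <- c(vars, "g"); coefs <- c(coefs, 1) }
    if (rxn$id[j] == meta$biom) { vars <- c(vars, "mu_b"); coefs <- c(coefs, 1) }
    lp_add_row(lp, vars, coefs, lb = 0, ub = 0)
  }
  # dual feasibility for the change-indicator columns (objective coef 1)
  for (j in seq_len(nrow(rxn)))
    lp_add_row(lp, c(mu$max2[j], mu$min2[j], mu$a[j]),
               c(rxn$ub[j] - wv[j], -(rxn$lb[j] - wv[j]), -1), ub = 1)
  xi_min <- z_dual_product(lp, model, zn, mu$min, "ximin_", M)
  xi_max <- z_dual_product(lp, model, zn, mu$max, "ximax_", M)
  # strong duality: sum of change indicators equals the dual objective
  lp_add_row(lp,
             c(yn, "g", "mu_b", xi_min, xi_max, mu$max2, mu$min2, mu$a),
             c(rep(1, length(yn)), -model$uptake_rate, -model$biomass_min,
               -rxn$lb, rxn$ub, wv, -wv, rep(1, length(mu$a))),
             lb = 0, ub = 0)
  linearize_products(lp, config)
  lp
}

# ---- result container and audited solving ----------------------------------

new_strain_design <- function(model, method, K, epsilon, sol, zn) {
  knocked <- character(0)
  if (!is.null(sol$x)) {
    z <- sol$x[zn]
    knocked <- model$reactions$id[model$reactions$knockable &
                                    z[paste0("z_", model$reactions$id)] < 0.5]
  }
  structure(
    list(design = knockout_design(knocked, budget = K),
         objective = sol$objective,
         method = method,
         epsilon = epsilon,
         model_id = model$id,
         target = reaction_of_role(model, "target"),
         solver_stats = list(status = sol$status),
         solution = sol$x),
    class = "strain_design")
}

#' @export
print.strain_design <- function(x, digits = 4, ...) {
  lab <- c(optknock = "OptKnock (optimistic)",
           room = "ROOM (optimistic, LP variant)",
           p_room = "P-ROOM (pessimistic)",
           p_optknock = "P-OptKnock (pessimistic)")[x$method]
  cat(lab, " design on '", x$model_id, "'", sep = "")
  if (!is.null(x$epsilon)) cat(", epsilon = ", x$epsilon, sep = "")
  cat("\n  knockouts (K = ", x$design$budget, "): ",
      if (length(x$design$knocked)) paste(x$design$knocked, collapse = ", ")
      else "<none>", "\n", sep = "")
  kind <- if (x$method %in% c("p_room", "p_optknock")) "guaranteed worst-case"
  else "predicted (cooperative)"
  cat("  ", kind, " ", x$target, " flux: ",
      format(x$objective, digits = digits),
      " mmol/gDW/hr [", x$solver_stats$status, "]\n", sep = "")
  invisible(x)
}

#' @export
summary.strain_design <- function(object, ...) {
  print(object)
  if (!is.null(object$solver_stats$big_m))
    cat("  big-M escalations: ", object$solver_stats$big_m, "\n", sep = "")
  invisible(object)
}

#' Knockout indicator vector of a design
#'
#' Returns the binary vector `z` (1 = reaction active, 0 = knocked out) of a
#' solved design, named by reaction id.
#' @param object a `"strain_design"`.
#' @param ... unused.
#' @export
coef.strain_design <- function(object, ...) {
  z <- object$solution[startsWith(names(object$solution), "z_")]
  stats::setNames(as.numeric(z), sub("^z_", "", names(z)))
}

# solve one or more design MILPs with post-solve big-M audit + escalation
solve_design_specs <- function(specs, config = big_m_config(),
                               mip_gap = 1e-6, time_limit = NULL,
                               max_escalations = 2L) {
  build <- function(spec, cfg) {
    switch(spec$method,
           optknock = optknock_milp(spec$model, spec$K, cfg),
           room = room_milp(spec$model, spec$K, spec$w, cfg),
           p_room = p_room_milp(spec$model, spec$K, spec$epsilon, spec$w, cfg),
           p_optknock = p_optknock_milp(spec$model, spec$K, spec$epsilon, cfg))
  }
  cfgs <- rep(list(config), length(specs))
  lps <- mapply(build, specs, cfgs, SIMPLIFY = FALSE)
  sols <- solve_lp_batch(lps, mip_gap = mip_gap, time_limit = time_limit)
  esc <- integer(length(specs))
  for (round in seq_len(max_escalations)) {
    redo <- which(vapply(seq_along(specs), function(k)
      length(audit_big_m(lps[[k]], sols[[k]], cfgs[[k]])) > 0, TRUE))
    if (!length(redo)) break
    for (k in redo) {
      cfgs[[k]]$M_dual <- cfgs[[k]]$M_dual * 10
      lps[[k]] <- build(specs[[k]], cfgs[[k]])
      esc[k] <- esc[k] + 1L
    }
    sols[redo] <- solve_lp_batch(lps[redo], mip_gap = mip_gap,
                                 time_limit = time_limit)
  }
  out <- lapply(seq_along(specs), function(k) {
    spec <- specs[[k]]
    res <- new_strain_design(spec$model, spec$method, spec$K, spec$epsilon,
                             sols[[k]], paste0("z_", spec$model$reactions$id))
    res$solver_stats$big_m <- esc[k]
    flagged <- audit_big_m(lps[[k]], sols[[k]], cfgs[[k]])
    if (length(flagged)) {
      res$solver_stats$status <- "big_m_unsafe"
      warning("big-M audit failed for ", spec$method, " after ",
              max_escalations, " escalations: ",
              paste(flagged, collapse = ", "))
    }
    res
  })
  certify_designs(specs, out)
}

# The MILP objective can carry leakage of order M times the solver's
# integrality tolerance (a binary declared integral at 1 - 1e-6 relaxes a
# big-M row by M * 1e-6).  The design choice is kept, but its objective is
# re-certified exactly: the returned knockout set is scored with the
# two-stage band LP at integral z, and that certified value is reported.
certify_designs <- function(specs, results) {
  live <- which(vapply(results, function(r)
    r$solver_stats$status %in% c("optimal", "big_m_unsafe"), TRUE))
  if (!length(live)) return(results)
  inner_of <- function(method)
    if (method %in% c("room", "p_room")) "room" else "biomass"
  stage1 <- lapply(live, function(k)
    inner_problem(specs[[k]]$model, results[[k]]$design,
                  inner_of(specs[[k]]$method), specs[[k]]$w))
  sol1 <- solve_lp_batch(stage1)
  stage2 <- vector("list", length(live))
  for (i in seq_along(live)) {
    k <- live[[i]]
    if (sol1[[i]]$status != "optimal") next
    spec <- specs[[k]]
    pess <- spec$method %in% c("p_room", "p_optknock")
    stage2[[i]] <- band_problem(spec$model, results[[k]]$design,
                                inner_of(spec$method),
                                if (pess) spec$epsilon else 0,
                                sol1[[i]]$objective, spec$w,
                                if (pess) "min" else "max")
  }
  todo <- which(!vapply(stage2, is.null, TRUE))
  sol2 <- solve_lp_batch(stage2[todo])
  for (i in seq_along(todo)) {
    k <- live[[todo[i]]]
    if (sol2[[i]]$status == "optimal") {
      results[[k]]$solver_stats$milp_objective <- results[[k]]$objective
      results[[k]]$objective <- sol2[[i]]$objective
    }
  }
  results
}

#' OptKnock: optimistic knockout design for target overproduction
#'
#' Solves the bi-level program that maximizes the target-chemical flux over
#' knockout sets of size at most `K`, subject to the mutant maximizing
#' biomass (the cooperative assumption), as a single-level MILP obtained by
#' strong duality of the inner LP.  When the inner biomass optimum is
#' degenerate, the MILP inherently selects the response most favorable to
#' the target — that selection *is* the optimistic assumption.
#'
#' @param model a [metabolic_model()].
#' @param K integer knockout budget.
#' @param config a [big_m_config()].
#' @param mip_gap relative MILP optimality gap.
#' @return a `"strain_design"` object with the knockout set and the
#'   predicted (cooperative) target flux.
#' @references the approach embeds the inner LP via
#'   {primal feasibility, dual feasibility, equal objectives}.
#' @export
solve_optknock <- function(model, K, config = big_m_config(), mip_gap = 1e-6) {
  solve_design_specs(list(list(method = "optknock", model = model, K = K,
                               epsilon = NULL)),
                     config = config, mip_gap = mip_gap)[[1L]]
}

#' ROOM design: optimistic knockout design under minimal flux rerouting
#'
#' Like [solve_optknock()] but with the LP variant of ROOM as the inner
#' model: the mutant minimizes the sum of relaxed change indicators
#' `y_j in [0, 1]` that bound each flux's deviation from the wild-type
#' reference `w`.  The flux-change constraints compare fluxes to `w_j`
#' exactly (no relative significance thresholds).
#'
#' @inheritParams solve_optknock
#' @param w a `"wild_type_reference"` from [wild_type_fluxes()].
#' @return a `"strain_design"` object.
#' @export
solve_room_design <- function(model, K, w = NULL, config = big_m_config(),
                              mip_gap = 1e-6) {
  w <- check_wild_type(model, w)
  solve_design_specs(list(list(method = "room", model = model, K = K,
                               epsilon = NULL, w = w)),
                     config = config, mip_gap = mip_gap)[[1L]]
}
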