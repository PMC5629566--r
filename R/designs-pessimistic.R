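# ---- pessimistic single-level MILPs ----------------------------------------
#
# Pessimistic designs maximize the WORST-CASE target flux over all cellular
# responses whose inner objective lies within a multiplicative epsilon band
# of optimal.  The three-level structure (outer knockouts, adversarial
# response, inner-optimal certificate) collapses to one MILP by dualizing
# twice:
#
#   1. the inner-most LP (ROOM's change minimization, or biomass
#      maximization) is replaced by its dual; a band constraint ties the
#      response's inner objective to the dual objective, which the
#      adversary can drive to the exact inner optimum — this encodes the
#      epsilon-approximation set without knowing the optimum in advance;
#   2. the resulting adversarial min-LP (for fixed z) is dualized again,
#      giving a max problem that merges with the outer maximization.
#
# Because some knockout vectors z leave the mutant with no feasible flux
# distribution at all (making the second dual unbounded), a witness copy of
# the inner primal constraints (variables s, r) is kept in the MILP so that
# only designs with a live mutant are eligible.
#
# Bilinear products of binaries with duals (z*x in the objective, z*t in the
# band-derived rows) are big-M linearized and audited after solving.

# P-ROOM single-level MIP
p_room_milp <- function(model, K, epsilon, w, config = big_m_config()) {
  stopifnot(epsilon >= 0)
  M <- config$M_dual
  e1 <- 1 + epsilon
  meta <- milp_meta(model)
  rxn <- model$reactions
  nJ <- nrow(rxn)
  wv <- unname(w$w[rxn$id])
  tr <- stoich_triplets(model)

  lp <- lp_new("max")
  zn <- design_z_block(lp, model, K)

  # feasibility witnesses: a full ROOM-feasible response must exist for z
  sn <- linked_primal_block(lp, model, zn, prefix = "s_")
  rn <- room_change_block(lp, model, w, sn, prefix = "r_")

  # duals of the adversary's constraint blocks
  gn <- paste0("gam_", tr$mets)
  lp_add_vars(lp, gn, lb = -M, ub = M)
  lp_add_vars(lp, c("gam_glc"), lb = -M, ub = M)
  lp_add_vars(lp, "gam_biom", lb = 0, ub = M)
  xmin <- paste0("xmin_", rxn$id);  xmax <- paste0("xmax_", rxn$id)
  xmin2 <- paste0("xmin2_", rxn$id); xmax2 <- paste0("xmax2_", rxn$id)
  cn <- paste0("c_", rxn$id); qn <- paste0("q_", rxn$id)
  for (v in list(xmin, xmax, xmin2, xmax2, cn, qn))
    lp_add_vars(lp, v, lb = 0, ub = M)
  jup0 <- which(rxn$role == "uptake")
  lp_fix_zero(lp, c(xmin[jup0], xmax[jup0], xmin2[jup0], xmax2[jup0]))
  lp_add_vars(lp, "t", lb = 0, ub = M)
  pn <- paste0("p_", rxn$id)
  lp_add_vars(lp, pn, lb = -M, ub = M)

  # dual rows for the adversary's flux variables v_j; the target column
  # carries the adversarial objective coefficient 1
  for (j in seq_len(nJ)) {
    sel <- tr$j == j
    vars <- c(gn[tr$i[sel]], xmin[j], xmax[j], xmax2[j], xmin2[j])
    coefs <- c(tr$x[sel], 1, -1, -1, 1)
    if (rxn$id[j] == meta$glc) { vars <- c(vars, "gam_glc"); coefs <- c(coefs, 1) }
    if (rxn$id[j] == meta$biom) { vars <- c(vars, "gam_biom"); coefs <- c(coefs, 1) }
    rhs <- as.numeric(rxn$id[j] == meta$chem)
    lp_add_row(lp, vars, coefs, lb = rhs, ub = rhs)
  }
  # dual rows for the adversary's change indicators y_j
  for (j in seq_len(nJ))
    lp_add_row(lp, c(xmax2[j], xmin2[j], cn[j], "t"),
               c(rxn$ub[j] - wv[j], -(rxn$lb[j] - wv[j]), -1, -1), ub = 0)
  # dual rows for the inner-dual certificate variables (u, glc, mu, a),
  # i.e. the twice-dualized band machinery
  for (i in seq_along(tr$mets)) {
    sel <- tr$i == i
    lp_add_row(lp, pn[tr$j[sel]], tr$x[sel], lb = 0, ub = 0)
  }
  tau <- z_dual_product(lp, model, zn, rep("t", nJ), "tau_", M)
  jglc <- which(rxn$id == meta$glc); jbiom <- which(rxn$id == meta$biom)
  lp_add_row(lp, c("t", pn[jglc]), c(e1 * model$uptake_rate, 1), lb = 0, ub = 0)
  lp_add_row(lp, c("t", pn[jbiom]), c(e1 * model$biomass_min, 1), ub = 0)
  for (j in seq_len(nJ)) {
    lp_add_row(lp, c(tau[j], pn[j]), c(e1 * rxn$lb[j], 1), ub = 0)
    lp_add_row(lp, c(tau[j], pn[j]), c(-e1 * rxn$ub[j], -1), ub = 0)
    lp_add_row(lp, c("t", pn[j], qn[j]),
               c(-e1 * wv[j], -1, -(rxn$ub[j] - wv[j])), ub = 0)
    lp_add_row(lp, c("t", pn[j], qn[j]),
               c(e1 * wv[j], 1, rxn$lb[j] - wv[j]), ub = 0)
    lp_add_row(lp, c(qn[j], "t"), c(1, -e1), ub = 0)
  }
  # objective: the (second) dual objective = guaranteed worst-case target flux
  xi_min <- z_dual_product(lp, model, zn, xmin, "ximin_", M)
  xi_max <- z_dual_product(lp, model, zn, xmax, "ximax_", M)
  lp_add_obj(lp, c("gam_glc", "gam_biom"),
             c(model$uptake_rate, model$biomass_min))
  lp_add_obj(lp, xi_min, rxn$lb)
  lp_add_obj(lp, xi_max, -rxn$ub)
  lp_add_obj(lp, xmax2, -wv)
  lp_add_obj(lp, xmin2, wv)
  lp_add_obj(lp, cn, rep(-1, nJ))
  lp_add_obj(lp, qn, rep(-1, nJ))
  linearize_products(lp, config)
  lp
}

# P-OptKnock single-level MIP (same two-step dualization with the
# max-biomass inner model; the band reads v_biom >= (1 - eps) * inner opt)
p_optknock_milp <- function(model, K, epsilon, config = big_m_config()) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  M <- config$M_dual
  e1 <- 1 - epsilon
  meta <- milp_meta(model)
  rxn <- model$reactions
  nJ <- nrow(rxn)
  tr <- stoich_triplets(model)

  lp <- lp_new("max")
  zn <- design_z_block(lp, model, K)
  sn <- linked_primal_block(lp, model, zn, prefix = "s_")

  gn <- paste0("gam_", tr$mets)
  lp_add_vars(lp, gn, lb = -M, ub = M)
  lp_add_vars(lp, "gam_glc", lb = -M, ub = M)
  lp_add_vars(lp, "gam_biom", lb = 0, ub = M)
  xmin <- paste0("xmin_", rxn$id); xmax <- paste0("xmax_", rxn$id)
  lp_add_vars(lp, xmin, lb = 0, ub = M)
  lp_add_vars(lp, xmax, lb = 0, ub = M)
  jup0 <- which(rxn$role == "uptake")
  lp_fix_zero(lp, c(xmin[jup0], xmax[jup0]))
  lp_add_vars(lp, "t", lb = 0, ub = M)
  pn <- paste0("p_", rxn$id)
  lp_add_vars(lp, pn, lb = -M, ub = M)

  # dual rows for the adversary's flux variables
  for (j in seq_len(nJ)) {
    sel <- tr$j == j
    vars <- c(gn[tr$i[sel]], xmin[j], xmax[j])
    coefs <- c(tr$x[sel], 1, -1)
    if (rxn$id[j] == meta$glc) { vars <- c(vars, "gam_glc"); coefs <- c(coefs, 1) }
    if (rxn$id[j] == meta$biom) {
      vars <- c(vars, "gam_biom", "t"); coefs <- c(coefs, 1, 1)
    }
    rhs <- as.numeric(rxn$id[j] == meta$chem)
    lp_add_row(lp, vars, coefs, lb = rhs, ub = rhs)
  }
  # dual rows for the biomass-dual certificate variables
  for (i in seq_along(tr$mets)) {
    sel <- tr$i == i
    lp_add_row(lp, pn[tr$j[sel]], tr$x[sel], lb = 0, ub = 0)
  }
  tau <- z_dual_product(lp, model, zn, rep("t", nJ), "tau_", M)
  jglc <- which(rxn$id == meta$glc); jbiom <- which(rxn$id == meta$biom)
  lp_add_row(lp, c("t", pn[jglc]), c(-e1 * model$uptake_rate, 1), lb = 0, ub = 0)
  lp_add_row(lp, c("t", pn[jbiom]), c(e1 * model$biomass_min, -1), ub = 0)
  for (j in seq_len(nJ)) {
    lp_add_row(lp, c(tau[j], pn[j]), c(-e1 * rxn$ub[j], 1), ub = 0)
    lp_add_row(lp, c(tau[j], pn[j]), c(e1 * rxn$lb[j], -1), ub = 0)
  }
  xi_min <- z_dual_product(lp, model, zn, xmin, "ximin_", M)
  xi_max <- z_dual_product(lp, model, zn, xmax, "ximax_", M)
  lp_add_obj(lp, c("gam_glc", "gam_biom"),
             c(model$uptake_rate, model$biomass_min))
  lp_add_obj(lp, xi_min, rxn$lb)
  lp_add_obj(lp, xi_max, -rxn$ub)
  lp_add_obj(lp, pn[jbiom], 1)
  linearize_products(lp, config)
  lp
}

#' P-ROOM: pessimistic knockout design under minimal flux rerouting
#'
#' Finds the knockout set (at most `K` reactions) maximizing the
#' *worst-case* target flux over every cellular response whose ROOM
#' objective (sum of relaxed change indicators) is within a factor
#' `(1 + epsilon)` of the response-optimal value.  `epsilon = 0` is the pure
#' pessimistic problem: the mutant is assumed to follow the minimal-change
#' model faithfully but, among equally minimal responses, picks the one
#' least favorable to the engineering objective.  Larger `epsilon` also
#' covers responses that deviate from the model itself.  The reported
#' objective is the flux the design guarantees under any such response.
#'
#' @inheritParams solve_room_design
#' @param epsilon nonnegative tolerance of the inner-model band.
#' @return a `"strain_design"` object whose `objective` is the guaranteed
#'   worst-case target flux.
#' @export
solve_p_room <- function(model, K, epsilon = 0, w = NULL,
                         config = big_m_config(), mip_gap = 1e-6) {
  w <- check_wild_type(model, w)
  solve_design_specs(list(list(method = "p_room", model = model, K = K,
                               epsilon = epsilon, w = w)),
                     config = config, mip_gap = mip_gap)[[1L]]
}

#' P-OptKnock: pessimistic knockout design under biomass maximization
#'
#' As [solve_p_room()], with the max-biomass inner model of OptKnock: the
#' guaranteed flux is the minimum over all responses with
#' `v_biomass >= (1 - epsilon) * (max biomass for that design)` (and at
#' least the viability threshold `biomass_min`).  At `epsilon = 0` the band
#' is exactly the biomass-optimal face.
#'
#' @inheritParams solve_optknock
#' @param epsilon tolerance in `[0, 1]`.
#' @return a `"strain_design"` object.
#' @export
solve_p_optknock <- function(model, K, epsilon = 0,
                             config = big_m_config(), mip_gap = 1e-6) {
  solve_design_specs(list(list(method = "p_optknock", model = model, K = K,
                               epsilon = epsilon)),
                     config = config, mip_gap = mip_gap)[[1L]]
}

# ---- inner ROOM primal / dual LPs for a fixed design ------------------------

# inner ROOM primal LP: min sum(y) over ROOM-feasible responses for fixed z
room_inner_primal <- function(model, w, design) {
  design <- check_design(model, design)
  lp <- lp_new("min")
  vn <- fba_primal_block(lp, model, design, enforce_biomass_min = TRUE)
  yn <- room_change_block(lp, model, w, vn)
  lp_add_obj(lp, yn, rep(1, length(yn)))
  lp
}

#' Dual LP of the inner ROOM problem for a fixed design
#'
#' Builds the linear program dual to the inner flux-change minimization for
#' a fixed knockout vector z.  By strong duality its optimum equals the
#' inner primal optimum (the minimal number of relaxed flux changes a
#' mutant with this design needs); the objective carries the z-weighted
#' bound terms and the w-weighted change terms.  If the primal is
#' infeasible for this design, the returned LP is unbounded, which
#' [solve_lp()] reports and callers map to an infeasible design.
#'
#' @param model a [metabolic_model()].
#' @param w a `"wild_type_reference"` from [wild_type_fluxes()].
#' @param design a [knockout_design()] (z is held constant, so this is a
#'   plain LP).
#' @return an `"lp_program"`; solve it with [solve_lp()].  Dual variables:
#'   `u_<met>` (mass balance), `g` (fixed uptake), `mu_b` (biomass
#'   threshold), `mumin_/mumax_<rxn>` (flux bounds), `mumin2_/mumax2_<rxn>`
#'   (flux-change constraints), `a_<rxn>` (y upper bounds).
#' @export
build_room_inner_dual <- function(model, w, design = NULL) {
  w <- check_wild_type(model, w)
  design <- check_design(model, design)
  z <- design_z(model, design)
  rxn <- model$reactions
  nJ <- nrow(rxn)
  meta <- milp_meta(model)
  wv <- unname(w$w[rxn$id])
  tr <- stoich_triplets(model)
  lp <- lp_new("max")
  un <- paste0("u_", tr$mets)
  lp_add_vars(lp, un, lb = -Inf, ub = Inf)
  lp_add_vars(lp, "g", lb = -Inf, ub = Inf)
  lp_add_vars(lp, "mu_b", lb = 0)
  mmin <- paste0("mumin_", rxn$id); mmax <- paste0("mumax_", rxn$id)
  mmin2 <- paste0("mumin2_", rxn$id); mmax2 <- paste0("mumax2_", rxn$id)
  an <- paste0("a_", rxn$id)
  for (v in list(mmin, mmax, mmin2, mmax2, an)) lp_add_vars(lp, v, lb = 0)
  for (j in seq_len(nJ)) {
    sel <- tr$j == j
    vars <- c(un[tr$i[sel]], mmin[j], mmax[j], mmax2[j], mmin2[j])
    coefs <- c(tr$x[sel], 1, -1, -1, 1)
    if (rxn$id[j] == meta$glc) { vars <- c(vars, "g"); coefs <- c(coefs, 1) }
    if (rxn$id[j] == meta$biom) { vars <- c(vars, "mu_b"); coefs <- c(coefs, 1) }
    lp_add_row(lp, vars, coefs, lb = 0, ub = 0)
  }
  for (j in seq_len(nJ))
    lp_add_row(lp, c(mmax2[j], mmin2[j], an[j]),
               c(rxn$ub[j] - wv[j], -(rxn$lb[j] - wv[j]), -1), ub = 1)
  lp_add_obj(lp, c("g", "mu_b"), c(model$uptake_rate, model$biomass_min))
  lp_add_obj(lp, mmin, rxn$lb * z)
  lp_add_obj(lp, mmax, -rxn$ub * z)
  lp_add_obj(lp, mmax2, -wv)
  lp_add_obj(lp, mmin2, wv)
  lp_add_obj(lp, an, rep(-1, nJ))
  lp
}
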