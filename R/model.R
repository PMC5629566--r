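#' Construct a stoichiometric metabolic model
#'
#' The central data container: an ordered list of metabolites, an ordered
#' list of reactions with sparse stoichiometry and flux bounds, and the two
#' run parameters every design method needs — the fixed substrate uptake rate
#' and the minimum biomass flux a viable mutant must sustain.
#'
#' @param metabolites data frame with columns `id` (unique, nonempty
#'   character), `name` (character), and `external` (logical; external
#'   metabolites are excluded from mass balance).
#' @param reactions data frame with columns `id`, `lb`, `ub` (flux bounds in
#'   mmol/gDW/hr), `knockable` (logical), `role` (one of `"internal"`,
#'   `"uptake"`, `"biomass"`, `"target"`, `"exchange"`), and a list column
#'   `stoich` of named numeric vectors (metabolite id -> signed coefficient).
#' @param uptake_rate fixed uptake flux (mmol/gDW/hr) imposed on the uptake
#'   reaction.
#' @param biomass_min minimum biomass flux (mmol/gDW/hr) required of mutants.
#' @param id optional model identifier.
#' @return an object of class `"metabolic_model"`.
#' @seealso [make_fixture()], [load_model()], [validate_model()]
#' @export
metabolic_model <- function(metabolites, reactions, uptake_rate, biomass_min,
                            id = "model") {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  metabolites$id <- as.character(metabolites$id)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$external)) metabolites$external <- FALSE
  reactions$id <- as.character(reactions$id)
  reactions$stoich <- lapply(reactions$stoich, function(st)
    stats::setNames(as.numeric(st), names(st)))
  m <- structure(
    list(id = id,
         metabolites = metabolites[, c("id", "name", "external")],
         reactions = reactions[, c("id", "lb", "ub", "knockable", "role", "stoich")],
         uptake_rate = as.numeric(uptake_rate),
         biomass_min = as.numeric(biomass_min)),
    class = "metabolic_model")
  rownames(m$metabolites) <- NULL
  rownames(m$reactions) <- NULL
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ",
      nrow(x$metabolites), " metabolites (",
      sum(!x$metabolites$external), " balanced), ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$knockable), " knockable)\n", sep = "")
  cat("  uptake: ", reaction_of_role(x, "uptake"), " fixed at ",
      x$uptake_rate, " mmol/gDW/hr\n", sep = "")
  cat("  biomass: ", reaction_of_role(x, "biomass"),
      " (minimum ", x$biomass_min, ")",
      "   target: ", reaction_of_role(x, "target"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  print(object)
  cat("  roles: ", paste(sprintf("%s=%d", names(table(object$reactions$role)),
                                 table(object$reactions$role)), collapse = ", "),
      "\n", sep = "")
  rev <- sum(object$reactions$lb < 0)
  cat("  reversible reactions: ", rev, "\n", sep = "")
  invisible(object)
}

reaction_of_role <- function(model, role) {
  ids <- model$reactions$id[model$reactions$role == role]
  if (length(ids) != 1L)
    stop("model must designate exactly one '", role, "' reaction, found ",
         length(ids))
  ids
}

reaction_ids <- function(model) model$reactions$id

knockable_ids <- function(model) model$reactions$id[model$reactions$knockable]

#' Stoichiometric matrix of a model
#'
#' Rows are the balanced (non-external) metabolites, columns the reactions in
#' model order; entry (i, j) is the signed coefficient of metabolite i in
#' reaction j.
#'
#' @param model a [metabolic_model()].
#' @return a dense numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$external]
  S <- matrix(0, length(mets), nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoich[[j]]
    keep <- names(st) %in% mets
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

# sparse triplet view used by all LP builders: list(i = met index within
# balanced metabolites, j = reaction index, x = coefficient)
stoich_triplets <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$external]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoich[[j]]
    idx <- match(names(st), mets)
    keep <- !is.na(idx)
    ii <- c(ii, idx[keep]); jj <- c(jj, rep.int(j, sum(keep)))
    xx <- c(xx, unname(st[keep]))
  }
  list(i = ii, j = jj, x = xx, mets = mets)
}

#' Construct a knockout design
#'
#' A knockout design is a set of reaction ids forced to zero flux, together
#' with the budget K it must respect.  In the bi-level programs this is the
#' binary vector z, with `z[j] = 0` exactly for knocked reactions.
#'
#' @param knocked character vector of reaction ids to knock out.
#' @param budget integer knockout budget K (`|knocked| <= budget`).
#' @return an object of class `"knockout_design"`.
#' @export
knockout_design <- function(knocked = character(0), budget = length(knocked)) {
  knocked <- sort(unique(as.character(knocked)))
  if (length(knocked) > budget)
    stop("design has ", length(knocked), " knockouts but budget K = ", budget)
  structure(list(knocked = knocked, budget = as.integer(budget)),
            class = "knockout_design")
}

#' @export
print.knockout_design <- function(x, ...) {
  cat("Knockout design (K = ", x$budget, "): ",
      if (length(x$knocked)) paste(x$knocked, collapse = ", ") else "<none>",
      "\n", sep = "")
  invisible(x)
}

check_design <- function(model, design) {
  if (is.null(design)) design <- knockout_design()
  if (!inherits(design, "knockout_design"))
    design <- knockout_design(design, budget = length(design))
  bad <- setdiff(design$knocked, knockable_ids(model))
  if (length(bad))
    stop("design knocks non-knockable or unknown reaction(s): ",
         paste(bad, collapse = ", "))
  design
}

# z vector (1 = active) in reaction order for a fixed design
design_z <- function(model, design) {
  z <- rep(1, nrow(model$reactions))
  z[model$reactions$id %in% design$knocked] <- 0
  z
}

#' Validate a metabolic model
#'
#' Checks the structural invariants (unique nonempty ids, consistent bounds,
#' stoichiometry referencing known metabolites, exactly one uptake, biomass
#' and target reaction, uptake rate within the uptake reaction's bounds,
#' nonnegative biomass minimum, knockability policy) and, when the structure
#' is sound, that the wild-type FBA problem is feasible at the configured
#' uptake rate and biomass minimum.  Violations are reported, not raised.
#'
#' @param model a [metabolic_model()].
#' @param check_feasibility also solve the wild-type FBA LP to confirm the
#'   biomass minimum is achievable (requires the solver backend).
#' @return character vector of violation messages; empty when the model is
#'   valid.  Class `"model_validation"`.
#' @export
validate_model <- function(model, check_feasibility = TRUE) {
  v <- character(0)
  rxn <- model$reactions; met <- model$metabolites
  if (anyDuplicated(met$id) || any(!nzchar(met$id)))
    v <- c(v, "metabolite ids must be nonempty and unique")
  if (anyDuplicated(rxn$id) || any(!nzchar(rxn$id)))
    v <- c(v, "reaction ids must be nonempty and unique")
  bad_bounds <- rxn$id[rxn$lb > rxn$ub]
  if (length(bad_bounds))
    v <- c(v, paste0("reaction ", bad_bounds, ": lower_bound > upper_bound"))
  for (j in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[j]]
    if (!length(st))
      v <- c(v, paste0("reaction ", rxn$id[j], ": empty stoichiometry"))
    unknown <- setdiff(names(st), met$id)
    if (length(unknown))
      v <- c(v, paste0("reaction ", rxn$id[j],
                       ": stoichiometry references unknown metabolite(s) ",
                       paste(unknown, collapse = ", ")))
  }
  for (role in c("uptake", "biomass", "target")) {
    n <- sum(rxn$role == role)
    if (n != 1L)
      v <- c(v, paste0("model must designate exactly one '", role,
                       "' reaction, found ", n))
  }
  if (model$biomass_min < 0)
    v <- c(v, "biomass_min must be nonnegative")
  if (is.na(model$uptake_rate)) {
    v <- c(v, "uptake_rate is not set")
  } else if (sum(rxn$role == "uptake") == 1L) {
    up <- rxn[rxn$role == "uptake", ]
    if (model$uptake_rate < up$lb || model$uptake_rate > up$ub)
      v <- c(v, "uptake_rate outside the uptake reaction's bounds")
  }
  bad_knock <- setdiff(rxn$id[rxn$knockable & rxn$role != "internal"],
                       model$knock_whitelist)
  if (length(bad_knock))
    v <- c(v, paste0("reaction ", bad_knock, ": role '",
                     rxn$role[match(bad_knock, rxn$id)],
                     "' is knockable (policy: only internal reactions are ",
                     "knockable unless whitelisted)"))
  if (!length(v) && check_feasibility) {
    sol <- solve_fba(model, reaction_of_role(model, "biomass"), "max",
                     enforce_biomass_min = FALSE)
    if (sol$status != "optimal")
      v <- c(v, paste0("wild-type FBA is ", sol$status,
                       " at the configured uptake rate"))
    else if (sol$objective < model$biomass_min - 1e-6)
      v <- c(v, paste0("biomass target exceeds achievable maximum (",
                       format(sol$objective), " < ", model$biomass_min, ")"))
  }
  structure(v, class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  if (!length(x)) cat("Model is valid: no violations.\n")
  else cat(paste0("- ", unclass(x), collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Override the knockability of reactions
#'
#' By default only internal reactions are knockable; this whitelists or
#' blacklists specific reactions (e.g. to match an externally published
#' knockable set).
#'
#' @param model a [metabolic_model()].
#' @param whitelist,blacklist character vectors of reaction ids.
#' @return the modified model.
#' @export
set_knockable <- function(model, whitelist = character(0),
                          blacklist = character(0)) {
  idx_w <- match(whitelist, model$reactions$id)
  idx_b <- match(blacklist, model$reactions$id)
  if (anyNA(idx_w) || anyNA(idx_b)) stop("unknown reaction id")
  model$reactions$knockable[idx_w] <- TRUE
  model$reactions$knockable[idx_b] <- FALSE
  model$knock_whitelist <- union(model$knock_whitelist, whitelist)
  model
}
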