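#' Epsilon/K sweep experiments
#'
#' Runs design methods and/or worst-case evaluations of optimistic designs
#' over a grid of knockout budgets and band tolerances, reproducing the
#' standard robustness picture: pessimistic design curves decrease gently in
#' epsilon while the worst-case evaluations of optimistic designs collapse.
#'
#' Two kinds of series are supported:
#' * design methods (`"optknock"`, `"room"`, `"p_room"`, `"p_optknock"`):
#'   the design MILP is solved per (method, K, epsilon) — the optimistic
#'   methods ignore epsilon and are solved once per K;
#' * evaluation series (`"optknock_eval"`, `"room_eval"`): the optimistic
#'   design is solved once per K and its fixed knockout set is then
#'   re-evaluated pessimistically ([epsilon_extreme_flux()] with
#'   `sense = "min"`) at every epsilon.
#'
#' @param model a [metabolic_model()] (or path to a tabular model file).
#' @param methods character vector of series names (hyphens allowed).
#' @param K integer vector of knockout budgets.
#' @param epsilons numeric vector of band tolerances.
#' @param w optional wild-type reference (computed once when needed).
#' @param config a [big_m_config()].
#' @param mip_gap relative MILP gap.
#' @return a data frame of class `"sweep_table"` with columns `method`, `K`,
#'   `epsilon`, `objective`, `knocked`, `status`, and a `provenance`
#'   attribute recording the model and parameters.
#' @export
run_epsilon_sweep <- function(model,
                              methods = c("p_optknock", "p_room"),
                              K = 3, epsilons = seq(0, 0.4, by = 0.05),
                              w = NULL, config = big_m_config(),
                              mip_gap = 1e-6) {
  if (is.character(model)) model <- load_model(model)
  methods <- vapply(methods, normalize_method, "")
  needs_w <- any(methods %in% c("room", "p_room", "room_eval"))
  if (needs_w) w <- check_wild_type(model, w)

  rows <- list()
  add_row <- function(method, Kv, eps, objective, knocked, status)
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, K = Kv, epsilon = eps,
      objective = objective,
      knocked = paste(knocked, collapse = ","),
      status = status, stringsAsFactors = FALSE)

  # design series: batch every MILP in one solver call
  specs <- list(); labels <- list()
  for (method in intersect(methods, c("optknock", "room", "p_room", "p_optknock"))) {
    pess <- method %in% c("p_room", "p_optknock")
    eps_grid <- if (pess) epsilons else NA_real_
    for (Kv in K) for (eps in eps_grid) {
      specs[[length(specs) + 1L]] <- list(
        method = method, model = model, K = Kv,
        epsilon = if (pess) eps else NULL, w = w)
      labels[[length(labels) + 1L]] <- list(method = method, K = Kv, eps = eps)
    }
  }
  if (length(specs)) {
    res <- tryCatch(solve_design_specs(specs, config = config,
                                       mip_gap = mip_gap),
                    error = function(e) e)
    for (k in seq_along(specs)) {
      lab <- labels[[k]]
      if (inherits(res, "error"))
        add_row(lab$method, lab$K, lab$eps, NA_real_, character(0),
                paste("error:", conditionMessage(res)))
      else
        add_row(lab$method, lab$K, lab$eps, res[[k]]$objective,
                res[[k]]$design$knocked, res[[k]]$solver_stats$status)
    }
  }

  # evaluation series: optimistic design once per K, then banded worst case
  for (method in intersect(methods, c("optknock_eval", "room_eval"))) {
    base <- sub("_eval$", "", method)
    inner <- if (base == "room") "room" else "biomass"
    for (Kv in K) {
      des <- tryCatch(
        design_strain(model, base, Kv, w = w, config = config,
                      mip_gap = mip_gap),
        error = function(e) e)
      if (inherits(des, "error")) {
        for (eps in epsilons)
          add_row(method, Kv, eps, NA_real_, character(0),
                  paste("error:", conditionMessage(des)))
        next
      }
      for (eps in epsilons) {
        ev <- epsilon_extreme_flux(model, des$design, inner, eps, w,
                                   sense = "min")
        add_row(method, Kv, eps,
                if (ev$status == "optimal") ev$worst_flux else NA_real_,
                des$design$knocked, ev$status)
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    model_id = model$id,
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    uptake_rate = model$uptake_rate,
    biomass_min = model$biomass_min,
    package = as.character(utils::packageVersion("pessknock")))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Write a sweep table as TSV with a provenance header
#'
#' @param x a `"sweep_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(x, path) {
  prov <- attr(x, "provenance")
  hdr <- vapply(names(prov), function(n)
    sprintf("# %s: %s", n, paste(prov[[n]], collapse = " ")), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sweep table written by [write_sweep_table()]
#' @param path TSV path.
#' @return a `"sweep_table"` data frame.
#' @export
read_sweep_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  out <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out$knocked <- as.character(out$knocked)
  out$knocked[is.na(out$knocked)] <- ""
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' @export
print.sweep_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    cat("Epsilon/K sweep on '", prov$model_id, "' (",
        prov$n_metabolites, " metabolites, ", prov$n_reactions,
        " reactions)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot sweep series (target flux versus epsilon)
#'
#' One line per (method, K) group, mirroring the usual presentation of
#' robustness sweeps: pessimistic design objectives against the worst-case
#' evaluations of optimistic designs.
#'
#' @param x a `"sweep_table"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_table <- function(x, ...) {
  df <- x[!is.na(x$epsilon) & !is.na(x$objective), , drop = FALSE]
  if (!nrow(df)) stop("no epsilon-dependent series to plot")
  groups <- unique(df[, c("method", "K")])
  eps <- sort(unique(df$epsilon))
  ymat <- sapply(seq_len(nrow(groups)), function(g) {
    sel <- df$method == groups$method[g] & df$K == groups$K[g]
    df$objective[sel][match(eps, df$epsilon[sel])]
  })
  graphics::matplot(eps, ymat, type = "b", pch = 19, lty = 1,
                    xlab = "epsilon (band tolerance)",
                    ylab = "target flux (mmol/gDW/hr)", ...)
  graphics::legend("topright",
                   legend = sprintf("%s K=%d", groups$method, groups$K),
                   col = seq_len(nrow(groups)), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
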