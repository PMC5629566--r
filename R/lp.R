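#' Create an empty linear/mixed-integer program
#'
#' A mutable builder (an environment) for LPs and MILPs.  Variables are
#' referenced by name; constraints are stored as sparse triplets with a lower
#' and upper row bound, so equalities, inequalities and ranges share one form.
#' Bilinear binary-times-continuous products can be registered with
#' [lp_product()] and are turned into exact big-M linearizations by
#' [linearize_products()].
#'
#' @param sense `"max"` or `"min"`.
#' @return An object of class `"lp_program"`.
#' @seealso [lp_add_vars()], [lp_add_row()], [solve_lp()]
#' @export
lp_new <- function(sense = c("max", "min")) {
  sense <- match.arg(sense)
  lp <- new.env(parent = emptyenv())
  lp$sense <- sense
  lp$var_name <- character(0)
  lp$var_lb <- numeric(0)
  lp$var_ub <- numeric(0)
  lp$var_obj <- numeric(0)
  lp$var_int <- logical(0)
  lp$ri <- list(); lp$ci <- list(); lp$cx <- list()
  lp$row_lb <- list(); lp$row_ub <- list()
  lp$nrow <- 0L
  lp$products <- list()
  class(lp) <- "lp_program"
  lp
}

#' Add variables to a program
#'
#' @param lp an [lp_new()] program.
#' @param names character vector of new, unique variable names.
#' @param lb,ub bounds, recycled over `names`.
#' @param obj objective coefficients, recycled.
#' @param integer logical, recycled; `TRUE` marks an integer variable.
#' @return `lp`, invisibly.
#' @export
lp_add_vars <- function(lp, names, lb = 0, ub = Inf, obj = 0, integer = FALSE) {
  n <- length(names)
  if (anyDuplicated(c(lp$var_name, names)))
    stop("duplicate variable name in lp_add_vars()")
  lp$var_name <- c(lp$var_name, names)
  lp$var_lb <- c(lp$var_lb, rep_len(as.numeric(lb), n))
  lp$var_ub <- c(lp$var_ub, rep_len(as.numeric(ub), n))
  lp$var_obj <- c(lp$var_obj, rep_len(as.numeric(obj), n))
  lp$var_int <- c(lp$var_int, rep_len(as.logical(integer), n))
  invisible(lp)
}

lp_var_index <- function(lp, names) {
  idx <- match(names, lp$var_name)
  if (anyNA(idx))
    stop("unknown variable(s): ", paste(names[is.na(idx)], collapse = ", "))
  idx
}

#' Add one linear constraint row
#'
#' The row reads `lb <= sum(coefs * vars) <= ub`; use `lb == ub` for an
#' equality.
#'
#' @param lp an [lp_new()] program.
#' @param vars variable names (or integer indices) with nonzero coefficients.
#' @param coefs numeric coefficients, same length as `vars`.
#' @param lb,ub scalar row bounds.
#' @return `lp`, invisibly.
#' @export
lp_add_row <- function(lp, vars, coefs, lb = -Inf, ub = Inf) {
  idx <- if (is.numeric(vars)) as.integer(vars) else lp_var_index(lp, vars)
  stopifnot(length(idx) == length(coefs))
  keep <- coefs != 0
  lp$nrow <- lp$nrow + 1L
  k <- length(lp$ri) + 1L
  lp$ri[[k]] <- rep.int(lp$nrow, sum(keep))
  lp$ci[[k]] <- idx[keep]
  lp$cx[[k]] <- as.numeric(coefs[keep])
  lp$row_lb[[k]] <- as.numeric(lb)
  lp$row_ub[[k]] <- as.numeric(ub)
  invisible(lp)
}

#' Add modifications to the linear objective
#'
#' Adds `coefs` onto the objective coefficients of `vars`.
#' @inheritParams lp_add_row
#' @return `lp`, invisibly.
#' @export
lp_add_obj <- function(lp, vars, coefs) {
  idx <- if (is.numeric(vars)) as.integer(vars) else lp_var_index(lp, vars)
  lp$var_obj[idx] <- lp$var_obj[idx] + as.numeric(coefs)
  invisible(lp)
}

#' Register a bilinear binary-by-continuous product
#'
#' Creates an auxiliary variable that will equal `z * x` once
#' [linearize_products()] has been applied, and returns its name so the
#' caller can use it in rows and the objective.  `z` must be a binary
#' variable of the program; `x` a continuous one.
#'
#' @param lp an [lp_new()] program.
#' @param z,x names of the binary and continuous factor.
#' @param name name for the auxiliary product variable.
#' @param M optional bound magnitude for `|x|`; when `NA` the value is taken
#'   from the [big_m_config()] passed to [linearize_products()], or from
#'   finite bounds of `x`.
#' @return the auxiliary variable name, invisibly.
#' @export
lp_product <- function(lp, z, x, name = paste0("prod_", z, "_", x), M = NA_real_) {
  zi <- lp_var_index(lp, z)
  xi <- lp_var_index(lp, x)
  if (!lp$var_int[zi]) stop("product factor ", z, " is not an integer variable")
  lp_add_vars(lp, name, lb = -Inf, ub = Inf)
  lp$products[[length(lp$products) + 1L]] <-
    list(z = z, x = x, xi = name, M = M)
  invisible(name)
}

#' Big-M configuration for product linearization
#'
#' @param M_flux bound magnitude used for flux-by-binary products (derived
#'   from model bounds by the MILP builders when `NULL`).
#' @param M_dual bound magnitude for dual-by-binary products.  Duals of the
#'   embedded inner problems have no a-priori bound, so this is a working
#'   bound whose activity is audited after every solve (see `audit_margin`)
#'   and escalated when nearly active.
#' @param audit_margin fraction of `M` above which a factor value flags the
#'   relaxation as unsafe.
#' @return a list of class `"big_m_config"`.
#' @export
big_m_config <- function(M_flux = NULL, M_dual = 1e4, audit_margin = 0.95) {
  stopifnot(is.null(M_flux) || M_flux > 0, M_dual > 0,
            audit_margin > 0, audit_margin <= 1)
  structure(list(M_flux = M_flux, M_dual = M_dual, audit_margin = audit_margin),
            class = "big_m_config")
}

#' Linearize registered bilinear products with big-M rows
#'
#' Each registered product `xi = z * x` (binary `z`, continuous `x` with
#' `|x| <= M`) is replaced exactly by the four rows
#' `xi <= M z`, `xi >= -M z`, `xi <= x + M (1 - z)`, `xi >= x - M (1 - z)`.
#' The resulting program has the same optimum as the bilinear one whenever no
#' `|x|` exceeds its `M` (checked after solving by [audit_big_m()]).
#'
#' @param lp an [lp_new()] program with products registered via [lp_product()].
#' @param config a [big_m_config()]; supplies `M` for products registered
#'   without one.
#' @return `lp`, invisibly, with linearization rows appended.
#' @export
linearize_products <- function(lp, config = big_m_config()) {
  for (pr in lp$products) {
    if (isTRUE(pr$done)) next
    M <- pr$M
    if (is.na(M)) {
      xb <- max(abs(lp$var_lb[lp_var_index(lp, pr$x)]),
                abs(lp$var_ub[lp_var_index(lp, pr$x)]))
      M <- if (is.finite(xb)) xb else config$M_dual
    }
    if (!is.finite(M))
      stop("unbounded continuous factor ", pr$x, " and no configured M")
    z <- pr$z; x <- pr$x; xi <- pr$xi
    lp_add_row(lp, c(xi, z), c(1, -M), ub = 0)          # xi <=  M z
    lp_add_row(lp, c(xi, z), c(1,  M), lb = 0)          # xi >= -M z
    lp_add_row(lp, c(xi, x, z), c(1, -1,  M), ub = M)   # xi <= x + M(1-z)
    lp_add_row(lp, c(xi, x, z), c(1, -1, -M), lb = -M)  # xi >= x - M(1-z)
    pr$done <- TRUE
  }
  lp$products <- lapply(lp$products, function(pr) { pr$done <- TRUE; pr })
  invisible(lp)
}

#' Audit big-M activity at a solution
#'
#' Checks every linearized product's continuous factor against
#' `audit_margin * M`.  A factor near its working bound while its binary is
#' active means the big-M relaxation may have truncated the true optimum
#' and must be escalated.  (With the binary at 0 the product is exactly
#' zero whatever the factor's magnitude, so large factors there are just
#' degenerate rays of the dual and are ignored.)
#'
#' @param lp the solved program.
#' @param solution a solution from [solve_lp()].
#' @param config a [big_m_config()].
#' @return character vector of flagged product variable names (empty if safe).
#' @export
audit_big_m <- function(lp, solution, config = big_m_config()) {
  if (is.null(solution$x) || !length(lp$products)) return(character(0))
  flagged <- character(0)
  for (pr in lp$products) {
    M <- pr$M
    if (is.na(M)) {
      xb <- max(abs(lp$var_lb[lp_var_index(lp, pr$x)]),
                abs(lp$var_ub[lp_var_index(lp, pr$x)]))
      M <- if (is.finite(xb)) xb else config$M_dual
    }
    if (solution$x[[pr$z]] > 0.5 &&
        abs(solution$x[[pr$x]]) > config$audit_margin * M)
      flagged <- c(flagged, pr$xi)
  }
  flagged
}

lp_build <- function(lp, mip_gap = NULL, time_limit = NULL) {
  # infinities cannot ride in JSON numbers; arrays containing them are
  # emitted as lists with "inf"/"-inf" strings, finite arrays stay numeric
  fmt <- function(v) {
    v <- as.numeric(v)
    if (all(is.finite(v))) return(I(v))
    out <- as.list(v)
    out[v == Inf] <- "inf"
    out[v == -Inf] <- "-inf"
    out
  }
  list(
    sense = lp$sense,
    n = length(lp$var_name),
    obj = I(as.numeric(lp$var_obj)),
    lb = fmt(lp$var_lb),
    ub = fmt(lp$var_ub),
    integer = I(as.integer(lp$var_int)),
    ai = I(as.integer(unlist(lp$ri))),
    aj = I(as.integer(unlist(lp$ci))),
    ax = I(as.numeric(unlist(lp$cx))),
    clb = fmt(unlist(lp$row_lb)),
    cub = fmt(unlist(lp$row_ub)),
    mip_gap = mip_gap,
    time_limit = time_limit
  )
}

backend_python <- function() {
  py <- getOption("pessknock.python", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py))
    stop("no python interpreter found on PATH; the HiGHS/SciPy solver ",
         "backend requires one (see SystemRequirements)")
  py
}

#' Solve a batch of programs in one solver invocation
#'
#' All problems are serialized to JSON and handed to the HiGHS backend
#' (`scipy.optimize.milp`) in a single Python process, so grouping
#' independent problems amortizes the interpreter start-up cost.
#'
#' @param lps list of [lp_new()] programs.
#' @param mip_gap relative MIP gap for integer programs.
#' @param time_limit optional per-problem limit in seconds.
#' @return list of solutions, each a list with `status` (one of `optimal`,
#'   `infeasible`, `unbounded`, `time_limit`, `error`), `objective`, and `x`
#'   (named numeric vector, or `NULL`).
#' @export
solve_lp_batch <- function(lps, mip_gap = 1e-6, time_limit = NULL) {
  stopifnot(is.list(lps))
  if (!length(lps)) return(list())
  payload <- lapply(lps, function(lp) {
    gap <- if (any(lp$var_int)) mip_gap else NULL
    lp_build(lp, mip_gap = gap, time_limit = time_limit)
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_backend.py", package = "pessknock")
  if (!nzchar(script)) stop("milp_backend.py not found in installed package")
  status <- system2(backend_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(fout))
    stop("solver backend failed (exit status ", status, ")")
  raw <- jsonlite::read_json(fout)
  mapply(function(res, lp) {
    x <- NULL
    if (!is.null(res$x)) {
      x <- as.numeric(unlist(res$x))
      names(x) <- lp$var_name
    }
    list(status = res$status,
         objective = if (is.null(res$objective)) NA_real_ else as.numeric(res$objective),
         x = x)
  }, raw, lps, SIMPLIFY = FALSE)
}

#' Solve a single program
#' @inheritParams solve_lp_batch
#' @param lp an [lp_new()] program.
#' @return a single solution (see [solve_lp_batch()]).
#' @export
solve_lp <- function(lp, mip_gap = 1e-6, time_limit = NULL) {
  solve_lp_batch(list(lp), mip_gap = mip_gap, time_limit = time_limit)[[1L]]
}
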