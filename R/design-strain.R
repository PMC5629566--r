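#' Design a knockout strain (central fitting interface)
#'
#' One entry point over the four bi-level design methods.  `"optknock"` and
#' `"room"` are optimistic: they report the target flux assuming the mutant
#' cooperates by picking, among responses optimal for its own survival
#' objective, the one best for production.  `"p_optknock"` and `"p_room"`
#' are their pessimistic counterparts: they maximize the flux guaranteed
#' under *any* response whose survival objective is within the
#' `epsilon`-approximation band of optimal.
#'
#' @param model a [metabolic_model()].
#' @param method one of `"optknock"`, `"room"`, `"p_optknock"`, `"p_room"`
#'   (hyphenated spellings accepted).
#' @param K integer knockout budget.
#' @param epsilon band tolerance (pessimistic methods only).
#' @param w wild-type reference for ROOM-family methods; computed by
#'   [wild_type_fluxes()] when omitted.
#' @param config a [big_m_config()].
#' @param mip_gap relative MILP optimality gap.
#' @return a `"strain_design"` object; see [solve_optknock()] and friends.
#' @examples
#' \dontrun{
#' m <- make_fixture("toy7")
#' design_strain(m, "p_optknock", K = 3, epsilon = 0)
#' }
#' @export
design_strain <- function(model, method = c("optknock", "room", "p_optknock",
                                            "p_room"),
                          K, epsilon = 0, w = NULL,
                          config = big_m_config(), mip_gap = 1e-6) {
  method <- normalize_method(if (is.character(method) && length(method) > 1)
    method[1] else method)
  switch(method,
         optknock = solve_optknock(model, K, config, mip_gap),
         room = solve_room_design(model, K, w, config, mip_gap),
         p_room = solve_p_room(model, K, epsilon, w, config, mip_gap),
         p_optknock = solve_p_optknock(model, K, epsilon, config, mip_gap))
}

normalize_method <- function(method) {
  m <- gsub("-", "_", tolower(method))
  ok <- c("optknock", "room", "p_room", "p_optknock",
          "optknock_eval", "room_eval")
  if (!m %in% ok)
    stop("unknown method '", method, "'; expected one of ",
         paste(gsub("_", "-", ok), collapse = ", "))
  m
}
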