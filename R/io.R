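#' Write a model to the tabular JSON dialect
#'
#' One UTF-8 JSON document with `metabolites`, `reactions` (stoichiometry as
#' metabolite-id -> coefficient mapping), and `parameters`.  Fluxes and
#' bounds are in mmol/gDW/hr.  Files written here reload with [load_model()]
#' to a field-by-field identical model.
#'
#' @param model a validated [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    id = model$id,
    parameters = list(uptake_rate = model$uptake_rate,
                      biomass_min = model$biomass_min),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           external = model$metabolites$external[i])),
    reactions = lapply(seq_len(nrow(model$reactions)), function(j)
      list(id = model$reactions$id[j],
           stoichiometry = as.list(model$reactions$stoich[[j]]),
           lower_bound = model$reactions$lb[j],
           upper_bound = model$reactions$ub[j],
           knockable = model$reactions$knockable[j],
           role = model$reactions$role[j]))
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("I/O error writing model to '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

#' Read a model from SBML (Level 3 + FBC) or the tabular JSON dialect
#'
#' For SBML, flux bounds are resolved through the FBC `lowerFluxBound` /
#' `upperFluxBound` parameter references and the active FBC objective marks
#' the biomass reaction; the uptake and target reactions are not encoded in
#' FBC and must be supplied via `uptake` and `target` (configuration
#' overrides also work for the JSON dialect).  Knockability follows the
#' conservative default policy: internal reactions only.
#'
#' @param path file path.
#' @param format `"tabular"` (JSON dialect of [save_model()]) or `"sbml"`.
#' @param uptake,biomass,target optional reaction ids overriding (or, for
#'   SBML, supplying) the role designations.
#' @param uptake_rate,biomass_min optional parameter overrides
#'   (mmol/gDW/hr); required for SBML, which does not carry them.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("tabular", "sbml"),
                       uptake = NULL, biomass = NULL, target = NULL,
                       uptake_rate = NULL, biomass_min = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  model <- switch(format,
                  tabular = load_model_tabular(path),
                  sbml = load_model_sbml(path))
  for (role in c("uptake", "biomass", "target")) {
    id <- switch(role, uptake = uptake, biomass = biomass, target = target)
    if (!is.null(id)) {
      j <- match(id, model$reactions$id)
      if (is.na(j)) stop("configuration error: no reaction '", id, "' for role ", role)
      model$reactions$role[model$reactions$role == role] <- "internal"
      model$reactions$role[j] <- role
      model$reactions$knockable[j] <- FALSE
    }
  }
  if (!is.null(uptake_rate)) model$uptake_rate <- as.numeric(uptake_rate)
  if (!is.null(biomass_min)) model$biomass_min <- as.numeric(biomass_min)
  for (role in c("uptake", "biomass", "target"))
    if (sum(model$reactions$role == role) != 1L)
      stop("configuration error: model does not designate exactly one '",
           role, "' reaction; pass the id explicitly")
  violations <- validate_model(model, check_feasibility = FALSE)
  integrity <- grep("unknown metabolite", violations, value = TRUE)
  if (length(integrity))
    stop("integrity error: ", paste(integrity, collapse = "; "))
  model
}

load_model_tabular <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("format error parsing '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("format error in '", path, "': missing '", field, "' in ", where,
           call. = FALSE)
    x[[field]]
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(need(m, "id", "metabolite")), ""),
    name = vapply(doc$metabolites, function(m)
      as.character(if (is.null(m$name)) m$id else m$name), ""),
    external = vapply(doc$metabolites, function(m) isTRUE(m$external), TRUE),
    stringsAsFactors = FALSE)
  rx <- doc$reactions
  rxn <- data.frame(
    id = vapply(rx, function(r) as.character(need(r, "id", "reaction")), ""),
    lb = vapply(rx, function(r) as.numeric(need(r, "lower_bound", "reaction")), 0),
    ub = vapply(rx, function(r) as.numeric(need(r, "upper_bound", "reaction")), 0),
    knockable = vapply(rx, function(r) isTRUE(r$knockable), TRUE),
    role = vapply(rx, function(r)
      as.character(if (is.null(r$role)) "internal" else r$role), ""),
    stringsAsFactors = FALSE)
  rxn$stoich <- lapply(rx, function(r) {
    st <- need(r, "stoichiometry", paste0("reaction '", r$id, "'"))
    out <- vapply(st, as.numeric, 0)
    names(out) <- names(st)
    out
  })
  pars <- doc$parameters
  metabolic_model(mets, rxn,
                  uptake_rate = as.numeric(need(pars, "uptake_rate", "parameters")),
                  biomass_min = as.numeric(need(pars, "biomass_min", "parameters")),
                  id = if (is.null(doc$id)) basename(path) else doc$id)
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("format error parsing '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("format error in '", path, "': no species found")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    external = xml2::xml_attr(sp, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- as.numeric(xml2::xml_attr(pars, "value"))
  names(parval) <- xml2::xml_attr(pars, "id")
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("format error in '", path, "': no reactions found")
  get_bound <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr, ns = ns)
    if (is.na(ref)) return(default)
    if (!ref %in% names(parval))
      stop("format error: flux bound parameter '", ref, "' undefined")
    unname(parval[[ref]])
  }
  stoich_of <- function(node) {
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      if (!length(nodes)) return(numeric(0))
      k <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      k[is.na(k)] <- 1
      out <- sign * k
      names(out) <- xml2::xml_attr(nodes, "species")
      out
    }
    st <- c(coef(reac, -1), coef(prod, 1))
    # merge duplicated species (appearing on both sides)
    tapply_sum <- tapply(st, names(st), sum)
    out <- as.numeric(tapply_sum)
    names(out) <- names(tapply_sum)
    out[order(match(names(out), names(st)))]
  }
  rxn <- data.frame(
    id = xml2::xml_attr(rx, "id"),
    lb = vapply(rx, get_bound, 0, attr = "fbc:lowerFluxBound", default = -1000),
    ub = vapply(rx, get_bound, 0, attr = "fbc:upperFluxBound", default = 1000),
    knockable = NA,
    role = "internal",
    stringsAsFactors = FALSE)
  rxn$stoich <- lapply(rx, stoich_of)
  # exchange reactions: single-sided stoichiometry or any external metabolite
  one_sided <- vapply(rxn$stoich, function(st)
    all(st > 0) || all(st < 0), TRUE)
  rxn$role[one_sided] <- "exchange"
  obj_rx <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective//fbc:fluxObjective", ns)
  if (inherits(obj_rx, "xml_missing"))
    stop("configuration error: SBML file has no FBC objective to mark the ",
         "biomass reaction")
  biomass_id <- xml2::xml_attr(obj_rx, "fbc:reaction", ns = ns)
  if (is.na(biomass_id)) biomass_id <- xml2::xml_attr(obj_rx, "reaction")
  rxn$role[rxn$id == biomass_id] <- "biomass"
  rxn$knockable <- rxn$role == "internal"
  metabolic_model(mets, rxn, uptake_rate = NA_real_, biomass_min = 0,
                  id = xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id"))
}
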