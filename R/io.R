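#' Write a model to the package's JSON dialect
#'
#' The dialect mirrors the in-memory types: `name`, `metabolites` (id, name,
#' compartment, is_external), `reactions` (id, stoichiometry map, reversible,
#' lb, ub, role, deletable) and `precursors`. [load_model()] round-trips it
#' exactly.
#'
#' @param model An `od_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "od_model"))
  obj <- list(
    name = model$name,
    metabolites = model$metabolites[, c("id", "name", "compartment", "is_external")],
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id, stoichiometry = as.list(model$stoich[[r$id]]),
           reversible = r$reversible, lb = r$lb, ub = r$ub,
           role = r$role, deletable = r$deletable)
    }),
    precursors = as.list(model$precursors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a stoichiometric model
#'
#' Reads either the package JSON dialect or an SBML Level 3 document with the
#' `fbc` extension. SBML has no notion of uptake/biomass/target roles: the
#' biomass reaction is taken from the active fbc objective when present, and
#' the remaining roles come from a sidecar config ([read_roles_config()])
#' passed as `roles`. Species with `boundaryCondition="true"` become external
#' metabolites.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`.
#' @param roles Optional named list / sidecar config with elements
#'   `substrate_uptake`, `biomass_reaction`, `target_reaction`, `precursors`,
#'   `non_deletable`.
#' @return A validated `od_model`.
#' @export
load_model <- function(path, format = c("json", "sbml"), roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    od_stop(sprintf("model file not found: %s", path), "od_format_error")
  model <- if (format == "json") load_model_json(path) else load_model_sbml(path)
  if (!is.null(roles)) model <- apply_roles(model, roles)
  validate_model(model)
  model
}

load_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) od_stop(sprintf("JSON parse failure in %s: %s",
                                                      path, conditionMessage(e)),
                                              "od_format_error"))
  for (f in c("metabolites", "reactions"))
    if (is.null(obj[[f]]))
      od_stop(sprintf("JSON model missing required field '%s'", f), "od_format_error")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               is_external = isTRUE(m$is_external), stringsAsFactors = FALSE)))
  rxns <- lapply(obj$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry))
      od_stop("JSON reaction missing 'id' or 'stoichiometry'", "od_format_error")
    st <- unlist(r$stoichiometry)
    reaction(r$id, st, reversible = isTRUE(r$reversible),
             lb = r$lb %||% if (isTRUE(r$reversible)) -1000 else 0,
             ub = r$ub %||% 1000, role = r$role %||% "internal",
             deletable = r$deletable %||% identical(r$role %||% "internal", "internal"))
  })
  sto_model(mets, rxns, precursors = as.character(unlist(obj$precursors)),
            name = obj$name %||% "model")
}

sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) od_stop(sprintf("SBML parse failure in %s: %s",
                                                      path, conditionMessage(e)),
                                              "od_format_error"))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]],
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), xml2::xml_attr(sp, "id"),
                  xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    is_external = xml2::xml_attr(sp, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  if (anyDuplicated(mets$id))
    od_stop(sprintf("SBML duplicate species id: %s",
                    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")),
            "od_format_error")

  biomass_id <- NULL
  obj_flux <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (!inherits(obj_flux, "xml_missing"))
    biomass_id <- xml2::xml_attr(obj_flux, "reaction")

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(ids))
    od_stop(sprintf("SBML duplicate reaction id: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "od_format_error")
  rxns <- lapply(seq_along(rx_nodes), function(i) {
    node <- rx_nodes[[i]]
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf("./s:%s/s:speciesReference", side), ns)
      if (!length(refs)) next
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      met <- xml2::xml_attr(refs, "species")
      for (k in seq_along(met)) {
        prev <- if (met[k] %in% names(st)) st[[met[k]]] else 0
        st[met[k]] <- prev + coef[k]
      }
    }
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lbp <- sbml_attr(node, "lowerFluxBound"); ubp <- sbml_attr(node, "upperFluxBound")
    lb <- if (!is.null(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else if (rev) -1000 else 0
    ub <- if (!is.null(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000
    role <- if (!is.null(biomass_id) && identical(ids[i], biomass_id)) "biomass" else "internal"
    reaction(ids[i], st, reversible = rev, lb = lb, ub = ub, role = role,
             deletable = role == "internal")
  })
  mname <- sbml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id") %||% "sbml_model"
  sto_model(mets, rxns, name = mname)
}

#' Read a sidecar role-designation config
#'
#' A flat YAML file with keys `substrate_uptake`, `biomass_reaction`,
#' `target_reaction`, `precursors` (list) and `non_deletable` (list). Explicit
#' designation is required because SBML carries no uptake/biomass/target
#' semantics.
#'
#' @param path YAML file path.
#' @return Named list usable as the `roles` argument of [load_model()].
#' @export
read_roles_config <- function(path) {
  if (!file.exists(path))
    od_stop(sprintf("roles config not found: %s", path), "od_format_error")
  yaml::read_yaml(path)
}

apply_roles <- function(model, roles) {
  set_role <- function(model, id, role) {
    if (is.null(id)) return(model)
    j <- match(id, model$reactions$id)
    if (is.na(j))
      od_stop(sprintf("role config names unknown reaction '%s'", id), "od_format_error")
    model$reactions$role[j] <- role
    model$reactions$deletable[j] <- FALSE
    model
  }
  model <- set_role(model, roles$substrate_uptake, "uptake")
  model <- set_role(model, roles$biomass_reaction, "biomass")
  model <- set_role(model, roles$target_reaction, "target")
  nd <- as.character(unlist(roles$non_deletable))
  model$reactions$deletable[model$reactions$id %in% nd] <- FALSE
  pre <- as.character(unlist(roles$precursors))
  if (length(pre)) {
    bad <- setdiff(pre, model$metabolites$id)
    if (length(bad))
      od_stop(sprintf("role config names unknown precursor metabolite(s): %s",
                      paste(bad, collapse = ", ")), "od_format_error")
    model$precursors <- pre
    model$metabolites$is_precursor <- model$metabolites$id %in% pre
  }
  model
}

#' The canonical twelve biomass-precursor metabolites
#'
#' The twelve central metabolites from which all biomass components derive:
#' glucose 6-phosphate, fructose 6-phosphate, ribose 5-phosphate, erythrose
#' 4-phosphate, glyceraldehyde 3-phosphate, 3-phosphoglycerate,
#' phosphoenolpyruvate, pyruvate, acetyl-CoA, alpha-ketoglutarate,
#' succinyl-CoA and oxaloacetate. Shipped as a default configuration for
#' genome-scale work; the id dialect follows common core-model conventions
#' and should be remapped to the model at hand.
#'
#' @return Character vector of 12 metabolite ids.
#' @export
canonical_precursors <- function() {
  c("g6p_c", "f6p_c", "r5p_c", "e4p_c", "g3p_c", "3pg_c",
    "pep_c", "pyr_c", "accoa_c", "akg_c", "succoa_c", "oaa_c")
}
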