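#' Construct a reaction description
#'
#' A reaction is a signed stoichiometric mapping over metabolite ids together
#' with reversibility, flux bounds and a role tag. Roles single out the
#' substrate uptake, biomass and target-product reactions that all downstream
#' analyses (mode partitioning, cut sets, valves) key on.
#'
#' @param id Reaction identifier, unique within a model.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed, positive = produced). Metabolites
#'   flagged external in the model are ignored in the mass balance, so an
#'   uptake reaction is written simply as `c(A = 1)`.
#' @param reversible Logical; reversible reactions are split into a
#'   forward/backward pair before mode enumeration.
#' @param lb,ub Flux bounds (mmol gDW^-1 h^-1).
#' @param role One of `"internal"`, `"uptake"`, `"exchange"`, `"biomass"`,
#'   `"target"`.
#' @param deletable Whether the reaction may appear in a cut set. Defaults to
#'   `TRUE` for internal reactions and `FALSE` for all tagged roles.
#' @return A list of class `od_reaction`.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lb = if (reversible) -1000 else 0, ub = 1000,
                     role = c("internal", "uptake", "exchange", "biomass", "target"),
                     deletable = NULL) {
  role <- match.arg(role)
  if (is.null(deletable)) deletable <- role == "internal"
  stopifnot(is.character(id), length(id) == 1L, is.numeric(stoichiometry),
            !is.null(names(stoichiometry)))
  if (lb > ub)
    od_stop(sprintf("reaction '%s': lower bound %g exceeds upper bound %g", id, lb, ub),
            "od_validation_error")
  if (!reversible && lb < 0)
    od_stop(sprintf("reaction '%s': irreversible but lower bound %g < 0", id, lb),
            "od_validation_error")
  structure(list(id = id, stoichiometry = stoichiometry, reversible = reversible,
                 lb = lb, ub = ub, role = role, deletable = deletable),
            class = "od_reaction")
}

#' Construct a stoichiometric model
#'
#' Assembles the balanced stoichiometry matrix `S` (rows = internal
#' metabolites, columns = reactions) from per-reaction stoichiometries and
#' validates the result. External metabolites never enter the balance.
#'
#' @param metabolites Data frame with columns `id` and optionally `name`,
#'   `compartment`, `is_external`; or a character vector of internal
#'   metabolite ids.
#' @param reactions List of [reaction()] objects.
#' @param precursors Character vector of biomass-precursor metabolite ids.
#' @param name Model name.
#' @return An object of class `od_model` with elements `metabolites`
#'   (data frame), `reactions` (data frame of id/reversible/lb/ub/role/
#'   deletable), `stoich` (named list of stoichiometries), `S` (matrix) and
#'   `precursors`.
#' @export
sto_model <- function(metabolites, reactions, precursors = character(), name = "model") {
  if (is.character(metabolites))
    metabolites <- data.frame(id = metabolites, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  mets <- data.frame(
    id = as.character(metabolites$id),
    name = as.character(metabolites$name %||% metabolites$id),
    compartment = as.character(metabolites$compartment %||% rep("c", nrow(metabolites))),
    is_external = as.logical(metabolites$is_external %||% rep(FALSE, nrow(metabolites))),
    stringsAsFactors = FALSE)
  mets$is_precursor <- mets$id %in% precursors

  stopifnot(is.list(reactions), all(vapply(reactions, inherits, TRUE, "od_reaction")))
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  rxns <- data.frame(
    id = rxn_ids,
    reversible = vapply(reactions, `[[`, TRUE, "reversible"),
    lb = vapply(reactions, `[[`, 0, "lb"),
    ub = vapply(reactions, `[[`, 0, "ub"),
    role = vapply(reactions, `[[`, "", "role"),
    deletable = vapply(reactions, `[[`, TRUE, "deletable"),
    stringsAsFactors = FALSE)
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn_ids

  internal <- mets$id[!mets$is_external]
  S <- matrix(0, nrow = length(internal), ncol = length(rxn_ids),
              dimnames = list(internal, rxn_ids))
  for (j in seq_along(stoich)) {
    st <- stoich[[j]]
    keep <- intersect(names(st), internal)
    S[keep, j] <- st[keep]
  }

  model <- structure(list(name = name, metabolites = mets, reactions = rxns,
                          stoich = stoich, S = S,
                          precursors = intersect(precursors, mets$id)),
                     class = "od_model")
  validate_model(model)
  model
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, bound consistency, role uniqueness (at most one
#' biomass and one target reaction), consistency of `S` with the per-reaction
#' stoichiometries, and that every internal metabolite participates in at
#' least one reaction.
#'
#' @param model An `od_model`.
#' @return The model, invisibly, or an error of class `od_validation_error`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "od_model"))
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id))
    od_stop(sprintf("duplicate metabolite id: %s",
                    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")),
            "od_validation_error")
  if (anyDuplicated(rxns$id))
    od_stop(sprintf("duplicate reaction id: %s",
                    paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")),
            "od_validation_error")
  if (any(rxns$lb > rxns$ub))
    od_stop(sprintf("lb > ub for reaction(s): %s",
                    paste(rxns$id[rxns$lb > rxns$ub], collapse = ", ")),
            "od_validation_error")
  bad <- !rxns$reversible & rxns$lb < 0
  if (any(bad))
    od_stop(sprintf("irreversible reaction(s) with negative lower bound: %s",
                    paste(rxns$id[bad], collapse = ", ")), "od_validation_error")
  for (r in c("biomass", "target"))
    if (sum(rxns$role == r) > 1L)
      od_stop(sprintf("more than one reaction tagged '%s': %s", r,
                      paste(rxns$id[rxns$role == r], collapse = ", ")),
              "od_validation_error")
  internal <- mets$id[!mets$is_external]
  if (!identical(rownames(model$S), internal) ||
      !identical(colnames(model$S), rxns$id))
    od_stop("stoichiometry matrix dimnames inconsistent with tables", "od_validation_error")
  orphan <- internal[rowSums(model$S != 0) == 0L]
  if (length(orphan))
    od_stop(sprintf("internal metabolite(s) appear in no reaction: %s",
                    paste(orphan, collapse = ", ")), "od_validation_error")
  unknown <- setdiff(unlist(lapply(model$stoich, names)), mets$id)
  if (length(unknown))
    od_stop(sprintf("reactions reference undeclared metabolite(s): %s",
                    paste(unknown, collapse = ", ")), "od_validation_error")
  invisible(model)
}

role_id <- function(model, role) {
  ids <- model$reactions$id[model$reactions$role == role]
  if (!length(ids)) NULL else ids[[1L]]
}

#' Look up the uptake, biomass or target reaction of a model
#'
#' @param model An `od_model`.
#' @return Named list with elements `uptake`, `biomass`, `target`
#'   (reaction ids or `NULL` when untagged).
#' @export
model_roles <- function(model) {
  list(uptake = role_id(model, "uptake"),
       biomass = role_id(model, "biomass"),
       target = role_id(model, "target"))
}

#' @export
print.od_model <- function(x, ...) {
  cat(sprintf("<od_model '%s': %d internal metabolites, %d reactions>\n",
              x$name, nrow(x$S), ncol(x$S)))
  r <- model_roles(x)
  cat(sprintf("  uptake: %s | biomass: %s | target: %s\n",
              r$uptake %||% "-", r$biomass %||% "-", r$target %||% "-"))
  if (length(x$precursors))
    cat("  precursors:", paste(x$precursors, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in fixture networks
#'
#' Deterministic, fully specified toy models used throughout the test-suite
#' and examples:
#' \describe{
#'   \item{branched_toy}{The canonical branched network: substrate A feeds
#'     two biomass routes (A->B->C->E and A->B->D->E, E drained by the
#'     biomass reaction) and an independent product branch A->P->T. It has
#'     exactly three elementary flux modes and an orthogonality score of
#'     0.8.}
#'   \item{branched_toy_redundant}{As above plus a redundant shunt
#'     v9: A->C, which adds a fourth (biomass) mode and lowers the score.}
#'   \item{linear_chain}{A single route to biomass and no route to the
#'     target: the product-only mode set is empty.}
#'   \item{diamond_coupled}{Biomass and product branch only after a shared
#'     linear trunk, so every biomass mode shares at least two internal
#'     reactions with every product mode.}
#'   \item{mini_glycolysis}{A lumped glycolysis-like network (reversible
#'     phosphoglucose isomerase, C3/C4 split to succinate, fractional
#'     biomass drain on G6P/PEP/PYR) with precursor tags.}
#' }
#'
#' Uptake reactions carry the default substrate uptake rate of
#' 20 mmol gDW^-1 h^-1; internal reactions are bounded at 1000.
#'
#' @param name Fixture name (see above).
#' @return An `od_model`.
#' @export
build_fixture <- function(name = c("branched_toy", "branched_toy_redundant",
                                   "linear_chain", "diamond_coupled",
                                   "mini_glycolysis")) {
  valid <- eval(formals(build_fixture)$name)
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    od_stop(sprintf("unknown fixture '%s'; valid names: %s",
                    paste(name, collapse = ","), paste(valid, collapse = ", ")),
            "od_validation_error")

  up <- function(met, id = "R_up") reaction(id, stats::setNames(1, met), role = "uptake",
                                            lb = 0, ub = 20, deletable = FALSE)
  if (name %in% c("branched_toy", "branched_toy_redundant")) {
    rx <- list(
      up("A"),
      reaction("v1", c(A = -1, B = 1)),
      reaction("v2", c(B = -1, C = 1)),
      reaction("v3", c(B = -1, D = 1)),
      reaction("v4", c(C = -1, E = 1)),
      reaction("v5", c(D = -1, E = 1)),
      reaction("v_bio", c(E = -1), role = "biomass", deletable = FALSE),
      reaction("v7", c(A = -1, P = 1)),
      reaction("v8", c(P = -1), role = "target", deletable = FALSE))
    if (name == "branched_toy_redundant")
      rx <- append(rx, list(reaction("v9", c(A = -1, C = 1))))
    return(sto_model(c("A", "B", "C", "D", "E", "P"), rx, name = name))
  }
  if (name == "linear_chain") {
    rx <- list(
      up("A"),
      reaction("v1", c(A = -1, B = 1)),
      reaction("v_bio", c(B = -1), role = "biomass", deletable = FALSE),
      reaction("v_t", c(T1 = -1), role = "target", deletable = FALSE))
    return(sto_model(c("A", "B", "T1"), rx, name = name))
  }
  if (name == "diamond_coupled") {
    rx <- list(
      up("A"),
      reaction("v1", c(A = -1, B = 1)),
      reaction("v2", c(B = -1, C = 1)),
      reaction("v_bio", c(C = -1), role = "biomass", deletable = FALSE),
      reaction("v3", c(C = -1, P = 1)),
      reaction("v_t", c(P = -1), role = "target", deletable = FALSE))
    return(sto_model(c("A", "B", "C", "P"), rx, name = name))
  }
  # mini_glycolysis
  rx <- list(
    up("G6P", id = "GLC_up"),
    reaction("pgi", c(G6P = -1, F6P = 1), reversible = TRUE, lb = -1000),
    reaction("fba", c(F6P = -1, GAP = 2)),
    reaction("gapA", c(GAP = -1, PEP = 1)),
    reaction("pyk", c(PEP = -1, PYR = 1)),
    reaction("ppc", c(PEP = -1, SUC = 1)),
    reaction("EX_suc", c(SUC = -1), role = "target", deletable = FALSE),
    reaction("v_bio", c(G6P = -0.2, PEP = -0.3, PYR = -0.5), role = "biomass",
             deletable = FALSE))
  sto_model(c("G6P", "F6P", "GAP", "PEP", "PYR", "SUC"), rx,
            precursors = c("G6P", "PEP", "PYR"), name = "mini_glycolysis")
}
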