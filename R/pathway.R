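#' Describe a pathway modification of a base model
#'
#' Captures the reaction additions, removals and bound overrides that graft a
#' substrate-utilisation pathway (or a pre-applied set of knockouts, e.g. the
#' standard fermentative deletions) onto a base network.
#'
#' @param name Config name.
#' @param added_reactions List of [reaction()] objects to add.
#' @param removed_reaction_ids Character vector of reaction ids to remove.
#' @param bound_overrides Named list, reaction id -> `c(lb, ub)`.
#' @return A list of class `od_pathway_config`.
#' @export
pathway_config <- function(name = "pathway", added_reactions = list(),
                           removed_reaction_ids = character(),
                           bound_overrides = list()) {
  stopifnot(all(vapply(added_reactions, inherits, TRUE, "od_reaction")),
            is.character(removed_reaction_ids))
  structure(list(name = name, added_reactions = added_reactions,
                 removed_reaction_ids = removed_reaction_ids,
                 bound_overrides = bound_overrides),
            class = "od_pathway_config")
}

#' Apply a pathway configuration to a model
#'
#' Returns a new model with the config's additions, removals and bound
#' overrides applied; the input model is not modified. Metabolites referenced
#' only by added reactions are created as internal metabolites.
#'
#' @param model An `od_model`.
#' @param cfg An [pathway_config()] object.
#' @return A new, validated `od_model`.
#' @export
apply_pathway <- function(model, cfg) {
  stopifnot(inherits(model, "od_model"), inherits(cfg, "od_pathway_config"))
  add_ids <- vapply(cfg$added_reactions, `[[`, "", "id")
  clash <- intersect(add_ids, model$reactions$id)
  if (length(clash))
    od_stop(sprintf("added reaction id(s) already present: %s",
                    paste(clash, collapse = ", ")), "od_validation_error")
  missing_rm <- setdiff(cfg$removed_reaction_ids, model$reactions$id)
  if (length(missing_rm))
    od_stop(sprintf("cannot remove unknown reaction(s): %s",
                    paste(missing_rm, collapse = ", ")), "od_validation_error")
  roles <- model$reactions$role[match(cfg$removed_reaction_ids, model$reactions$id)]
  if (any(roles %in% c("biomass", "target")))
    od_stop("refusing to remove the biomass or target reaction", "od_validation_error")

  keep <- !(model$reactions$id %in% cfg$removed_reaction_ids)
  rxns <- vector("list", sum(keep) + length(cfg$added_reactions))
  k <- 0L
  for (i in which(keep)) {
    r <- model$reactions[i, ]
    k <- k + 1L
    rxns[[k]] <- reaction(r$id, model$stoich[[r$id]], reversible = r$reversible,
                          lb = r$lb, ub = r$ub, role = r$role, deletable = r$deletable)
  }
  for (ar in cfg$added_reactions) { k <- k + 1L; rxns[[k]] <- ar }

  for (id in names(cfg$bound_overrides)) {
    j <- which(vapply(rxns, `[[`, "", "id") == id)
    if (!length(j))
      od_stop(sprintf("bound override for unknown reaction '%s'", id),
              "od_validation_error")
    bo <- cfg$bound_overrides[[id]]
    rxns[[j]]$lb <- bo[[1L]]; rxns[[j]]$ub <- bo[[2L]]
  }

  met_ids <- unique(c(model$metabolites$id,
                      unlist(lapply(rxns, function(r) names(r$stoichiometry)))))
  mets <- model$metabolites[match(met_ids, model$metabolites$id), ]
  new <- is.na(mets$id)
  mets$id[new] <- met_ids[new]
  mets$name[new] <- met_ids[new]
  mets$compartment[new] <- "c"
  mets$is_external[new] <- FALSE
  # drop metabolites left orphaned by removals
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- mets[mets$id %in% used, , drop = FALSE]
  sto_model(mets, rxns, precursors = intersect(model$precursors, mets$id),
            name = paste(model$name, cfg$name, sep = "+"))
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reversible reaction `r` is replaced by an irreversible forward copy
#' `r` and a backward copy `r__rev` with negated stoichiometry. Mode
#' enumeration and hitting-set machinery require an all-irreversible network;
#' two-cycle modes running a pair in a futile loop are removed downstream.
#'
#' @param model An `od_model`.
#' @return List with `model` (all-irreversible `od_model`) and `mapping`
#'   (data frame with columns `split_id`, `orig_id`, `direction`), one row per
#'   split column; empty mapping when nothing was reversible.
#' @export
split_reversible <- function(model) {
  stopifnot(inherits(model, "od_model"))
  rev_idx <- which(model$reactions$reversible)
  map <- data.frame(split_id = character(), orig_id = character(),
                    direction = character(), stringsAsFactors = FALSE)
  if (!length(rev_idx)) return(list(model = model, mapping = map))
  rxns <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoich[[r$id]]
    if (!r$reversible) {
      rxns <- append(rxns, list(reaction(r$id, st, lb = r$lb, ub = r$ub,
                                         role = r$role, deletable = r$deletable)))
    } else {
      bwd_id <- paste0(r$id, "__rev")
      rxns <- append(rxns, list(
        reaction(r$id, st, lb = 0, ub = max(r$ub, 0),
                 role = r$role, deletable = r$deletable),
        reaction(bwd_id, -st, lb = 0, ub = max(-r$lb, 0),
                 role = r$role, deletable = r$deletable)))
      map <- rbind(map, data.frame(split_id = c(r$id, bwd_id),
                                   orig_id = r$id,
                                   direction = c("fwd", "bwd"),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- sto_model(model$metabolites, rxns, precursors = model$precursors,
                   name = model$name)
  list(model = out, mapping = map)
}
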