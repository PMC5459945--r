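#' Select the modes a cut set must eliminate
#'
#' The design demand is that any surviving steady-state flux guarantees a
#' product yield of at least `yield_threshold` (mol product per mol
#' substrate), whether or not it carries growth. The modes to cut are
#' therefore exactly those whose product yield falls below the threshold —
#' all biomass-only modes and any low-yield product modes. High-yield modes
#' survive regardless of growth coupling.
#'
#' @param efms A partitioned `od_efm_set`.
#' @param yield_threshold Minimum mol/mol product yield (default 1, the
#'   standard choice for sugar substrates).
#' @param uptake_id,target_id Reaction ids; default to the model role tags.
#' @return List of class `od_target_modes`: `mode_indices`, `yields` (per
#'   mode, product per substrate; 0 for modes not consuming substrate),
#'   `yield_threshold`. Raises `od_infeasible_design` when no mode meets the
#'   yield demand.
#' @export
select_target_modes <- function(efms, yield_threshold = 1,
                                uptake_id = NULL, target_id = NULL) {
  stopifnot(inherits(efms, "od_efm_set"), yield_threshold >= 0)
  roles <- model_roles(efms$model)
  uptake_id <- uptake_id %||% roles$uptake
  target_id <- target_id %||% efms$target_id %||% roles$target
  if (is.null(uptake_id) || is.null(target_id))
    od_stop("target-mode selection needs uptake and target reaction ids",
            "od_validation_error")
  yields <- vapply(seq_len(nrow(efms$modes)), function(i) {
    tryCatch(mode_yield(efms, i, target_id, uptake_id),
             od_undefined_yield = function(e) 0)
  }, 0)
  idx <- which(yields < yield_threshold)
  if (length(idx) == nrow(efms$modes) && nrow(efms$modes) > 0L)
    od_stop(sprintf(
      "infeasible design: no mode reaches the yield threshold %g (max yield %g)",
      yield_threshold, max(yields)), "od_infeasible_design")
  structure(list(mode_indices = idx, yields = yields,
                 yield_threshold = yield_threshold),
            class = "od_target_modes")
}

# Minimalize a list of sets: drop any set that is a proper superset of
# another (duplicates collapse to one).
minimalize_sets <- function(sets) {
  sets <- unique(lapply(sets, function(s) sort(unique(s))))
  if (length(sets) <= 1L) return(sets)
  sizes <- lengths(sets)
  ord <- order(sizes)
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(sets)) {
      if (b == i || !keep[b]) next
      if (sizes[b] > sizes[i] && all(sets[[i]] %in% sets[[b]])) keep[b] <- FALSE
    }
  }
  sets[keep]
}

#' Enumerate minimal cut sets
#'
#' Computes all minimal hitting sets (hypergraph transversals, Berge
#' iteration) of the target modes' supports restricted to deletable
#' reactions: removing the reactions of any returned set disables every
#' targeted mode, and no proper subset does. Results are deterministic,
#' ordered by cardinality then lexicographically.
#'
#' @param targets An `od_target_modes` (or integer mode indices).
#' @param efms The `od_efm_set` the targets refer to.
#' @param deletable Character vector of deletable reaction ids; defaults to
#'   the model's `deletable` flags (role-tagged reactions are non-deletable
#'   by default).
#' @param max_cardinality Largest cut-set size to return (default 5).
#' @return List of class `od_cutset_list`; each element a sorted character
#'   vector of reaction ids. Raises `od_uncuttable_mode` if some target mode
#'   has no deletable reaction in its support.
#' @export
enumerate_mcs <- function(targets, efms, deletable = NULL, max_cardinality = 5L) {
  stopifnot(inherits(efms, "od_efm_set"))
  idx <- if (inherits(targets, "od_target_modes")) targets$mode_indices else as.integer(targets)
  deletable <- deletable %||%
    efms$model$reactions$id[efms$model$reactions$deletable]
  supports <- lapply(idx, function(i) {
    s <- intersect(efms$orig_supports[[i]], deletable)
    if (!length(s))
      od_stop(sprintf(
        "mode %d cannot be cut: support {%s} contains no deletable reaction",
        i, paste(efms$orig_supports[[i]], collapse = ", ")), "od_uncuttable_mode")
    s
  })
  hs <- list(character(0))
  for (Tset in supports) {
    hit <- vapply(hs, function(h) any(Tset %in% h), TRUE)
    grown <- unlist(lapply(hs[!hit], function(h)
      lapply(Tset, function(e) c(h, e))), recursive = FALSE)
    hs <- minimalize_sets(c(hs[hit], grown))
    hs <- hs[lengths(hs) <= max_cardinality]
    if (!length(hs)) break
  }
  hs <- hs[lengths(hs) > 0L | length(supports) == 0L]
  keys <- vapply(hs, paste, "", collapse = "\r")
  hs <- hs[order(lengths(hs), keys)]
  structure(hs, class = "od_cutset_list")
}

#' Find valve reactions within a cut set
#'
#' A valve is a cut-set member whose reactivation alone (all other cut-set
#' reactions stay deleted) restores flux-balance growth to at least
#' `growth_fraction` of the wild-type optimum. Candidates are returned
#' sorted by restored growth, descending.
#'
#' @param model The unsplit `od_model`.
#' @param cutset Character vector of reaction ids (a minimal cut set).
#' @param growth_fraction Minimum restored fraction of wild-type growth
#'   (default 0.9).
#' @return Data frame `reaction`, `restored_growth_fraction` (possibly zero
#'   rows). Errors with `od_validation_error` if the wild type cannot grow.
#' @export
find_valves <- function(model, cutset, growth_fraction = 0.9) {
  stopifnot(inherits(model, "od_model"))
  biomass <- role_id(model, "biomass")
  mu_wt <- fba(model, biomass, "max")$objective
  if (mu_wt <= .OD_TOL)
    od_stop("wild-type model has zero growth; valves are meaningless",
            "od_validation_error")
  frac <- vapply(cutset, function(r) {
    m <- delete_reactions(model, setdiff(cutset, r))
    fba(m, biomass, "max")$objective / mu_wt
  }, 0)
  df <- data.frame(reaction = cutset, restored_growth_fraction = frac,
                   stringsAsFactors = FALSE)
  df <- df[df$restored_growth_fraction >= growth_fraction - .OD_TOL, , drop = FALSE]
  df[order(-df$restored_growth_fraction, df$reaction), , drop = FALSE]
}

#' Audit a design with the valve closed
#'
#' With the full cut set applied (valve flux zero), checks which biomass
#' precursors the cell can still synthesize — each precursor gets a
#' temporary drain whose maximum flux is probed by FBA — and the maximum
#' product yield per substrate. For a valid design growth is zero and the
#' yield meets the design threshold.
#'
#' @param model Unsplit `od_model`.
#' @param cutset Reaction ids deleted (including the valve).
#' @param precursors Precursor metabolite ids (default: the model's).
#' @return List `precursor_count`, `precursors_synthesizable` (ids),
#'   `product_yield`, `growth`.
#' @export
audit_valve_off <- function(model, cutset, precursors = NULL) {
  stopifnot(inherits(model, "od_model"))
  precursors <- precursors %||% model$precursors
  m <- delete_reactions(model, cutset)
  roles <- model_roles(m)
  growth <- fba(m, roles$biomass, "max")$objective
  prod <- fba(m, roles$target, "max")
  up_flux <- if (!is.null(roles$uptake)) prod$fluxes[[roles$uptake]] else NA_real_
  pyield <- if (!is.na(up_flux) && up_flux > .OD_TOL) prod$objective / up_flux
            else if (prod$objective <= .OD_TOL) 0 else NA_real_
  ok <- vapply(precursors, function(p) {
    dm <- apply_pathway(m, pathway_config(
      name = "drain", added_reactions = list(
        reaction(".drain", stats::setNames(-1, p), lb = 0, ub = 1000))))
    fba(dm, ".drain", "max")$objective > .OD_TOL
  }, TRUE)
  list(precursor_count = sum(ok),
       precursors_synthesizable = precursors[ok],
       product_yield = pyield, growth = growth)
}

#' Build and rank valve designs
#'
#' The full ValveFind ranking: for each candidate cut set, identify valves
#' ([find_valves()]); pick the best valve (highest restored growth, then
#' fewest precursors synthesizable with the valve closed, then
#' lexicographic); form the reduced network with the cut set applied but the
#' valve left on; enumerate its elementary modes and compute the
#' orthogonality score. Designs are returned sorted by score (descending;
#' designs whose reduced network has an undefined score rank last), then
#' cut-set cardinality, then lexicographically.
#'
#' @param model Unsplit `od_model` with role tags.
#' @param cutsets An `od_cutset_list` or list of character vectors.
#' @param growth_fraction Valve admission threshold (default 0.9).
#' @param precursors Precursor ids for the audits (default: model's).
#' @param max_modes Passed to [enumerate_efms()] on reduced networks.
#' @return Object of class `od_design_list`: list of designs, each with
#'   `cutset`, `valve_id`, `restored_growth_fraction`, `score`
#'   (`NA` when undefined), `score_undefined`, `precursors_on_count`,
#'   `precursors_off_count`, `product_yield_valve_off`, `growth_valve_off`.
#'   Cut sets without any admissible valve are dropped.
#' @export
rank_designs <- function(model, cutsets, growth_fraction = 0.9,
                         precursors = NULL, max_modes = 500000L) {
  stopifnot(inherits(model, "od_model"))
  precursors <- precursors %||% model$precursors
  designs <- list()
  for (cs in cutsets) {
    valves <- find_valves(model, cs, growth_fraction)
    if (!nrow(valves)) next
    # tie-break equal-growth valves by fewest precursors leaking when closed
    best_frac <- valves$restored_growth_fraction[1L]
    tied <- valves[valves$restored_growth_fraction >= best_frac - .OD_TOL, , drop = FALSE]
    off <- audit_valve_off(model, cs, precursors)
    valve <- tied$reaction[1L]
    if (nrow(tied) > 1L && length(precursors)) {
      # audit is per cut set (valve closed = all deleted), so the leak count
      # is shared; the documented tie-break is then lexicographic
      valve <- sort(tied$reaction)[1L]
    }
    reduced <- delete_reactions(model, setdiff(cs, valve))
    sc <- tryCatch({
      ef <- partition_modes(enumerate_efms(reduced, max_modes = max_modes))
      orthogonality_score(ef, model = reduced)
    }, od_undefined_score = function(e) NULL)
    on_audit <- audit_valve_off(reduced, character(0), precursors)
    designs[[length(designs) + 1L]] <- list(
      cutset = sort(cs), valve_id = valve,
      restored_growth_fraction = valves$restored_growth_fraction[match(valve, valves$reaction)],
      score = if (is.null(sc)) NA_real_ else sc$score,
      score_undefined = is.null(sc),
      orthogonality = sc,
      precursors_on_count = on_audit$precursor_count,
      precursors_off_count = off$precursor_count,
      product_yield_valve_off = off$product_yield,
      growth_valve_off = off$growth)
  }
  key_card <- vapply(designs, function(d) length(d$cutset), 0L)
  key_lex <- vapply(designs, function(d) paste(d$cutset, collapse = "\r"), "")
  key_score <- vapply(designs, function(d) if (d$score_undefined) -Inf else d$score, 0)
  structure(designs[order(-key_score, key_card, key_lex)], class = "od_design_list")
}

#' @export
print.od_design_list <- function(x, ...) {
  cat(sprintf("<od_design_list: %d valve designs>\n", length(x)))
  for (d in head(x, 10L))
    cat(sprintf("  {%s} valve=%s growth=%.3g score=%s precursors_off=%d\n",
                paste(d$cutset, collapse = ","), d$valve_id,
                d$restored_growth_fraction,
                if (d$score_undefined) "undefined" else sprintf("%.4g", d$score),
                d$precursors_off_count))
  invisible(x)
}

#' Designs as a data frame
#'
#' @param x An `od_design_list`.
#' @param ... Unused.
#' @return Data frame with one row per design (cut set collapsed with `+`).
#' @export
as.data.frame.od_design_list <- function(x, ...) {
  if (!length(x))
    return(data.frame(cutset = character(), valve = character(),
                      restored_growth_fraction = numeric(), score = numeric(),
                      precursors_off = integer(), product_yield_off = numeric()))
  data.frame(
    cutset = vapply(x, function(d) paste(d$cutset, collapse = "+"), ""),
    valve = vapply(x, `[[`, "", "valve_id"),
    restored_growth_fraction = vapply(x, `[[`, 0, "restored_growth_fraction"),
    score = vapply(x, `[[`, 0, "score"),
    precursors_off = vapply(x, `[[`, 0L, "precursors_off_count"),
    product_yield_off = vapply(x, `[[`, 0, "product_yield_valve_off"),
    stringsAsFactors = FALSE)
}
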