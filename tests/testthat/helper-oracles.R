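`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used to derive expected values. These deliberately
# avoid the package's enumeration/optimisation code paths: the EFM oracle is
# an exhaustive subset test, the cut-set oracle a brute-force hitting-set
# search, the cost oracle a dense grid scan.

# All elementary flux modes of a model by exhaustive support enumeration:
# a reaction subset is a mode support iff the restricted stoichiometry has a
# one-dimensional null space whose basis vector is strictly one-signed, and
# no qualifying proper subset exists. Feasible only for <= ~12 reactions.
oracle_efms <- function(model, tol = 1e-9) {
  sp <- split_reversible(model)
  S <- sp$model$S
  n <- ncol(S)
  ids <- colnames(S)
  stopifnot(n <= 14)
  cand <- list()
  for (mask in seq_len(2^n - 1)) {
    sub <- which(bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) != 0)
    Ssub <- S[, sub, drop = FALSE]
    nullsp <- MASS::Null(t(Ssub))
    if (NCOL(nullsp) != 1L) next
    v <- nullsp[, 1]
    if (all(v > tol) || all(v < -tol)) cand[[length(cand) + 1L]] <- ids[sub]
  }
  # support minimality
  keep <- vapply(seq_along(cand), function(i)
    !any(vapply(seq_along(cand), function(j)
      j != i && length(cand[[j]]) < length(cand[[i]]) &&
        all(cand[[j]] %in% cand[[i]]), TRUE)), TRUE)
  cand <- cand[keep]
  # drop futile two-cycles introduced by reversible splitting
  if (nrow(sp$mapping)) {
    twocyc <- vapply(cand, function(s)
      length(s) == 2L && all(s %in% sp$mapping$split_id) &&
        length(unique(sp$mapping$orig_id[match(s, sp$mapping$split_id)])) == 1L,
      TRUE)
    cand <- cand[!twocyc]
  }
  lapply(cand, sort)
}

support_sets_equal <- function(a, b) {
  norm <- function(x) sort(vapply(lapply(x, sort), paste, "", collapse = "|"))
  identical(norm(a), norm(b))
}

# All minimal hitting sets of `supports` over `universe`, up to max_card,
# by exhaustive combination search in order of increasing cardinality.
oracle_hitting_sets <- function(supports, universe, max_card) {
  found <- list()
  hits_all <- function(s) all(vapply(supports, function(T) any(T %in% s), TRUE))
  for (k in seq_len(max_card)) {
    for (idx in utils::combn(length(universe), k, simplify = FALSE)) {
      s <- universe[idx]
      if (!hits_all(s)) next
      if (any(vapply(found, function(f) all(f %in% s), TRUE))) next
      found[[length(found) + 1L]] <- sort(s)
    }
  }
  found
}

# Minimum pathway protein cost over a dense log-concentration grid
# (pts points per metabolite dimension), scanned in chunks along the first
# dimension. Returns the grid minimum (an upper bound on the true optimum).
oracle_grid_cost <- function(reactions, kinetics, state, pts = 50) {
  mets <- sort(unique(unlist(lapply(reactions, names))))
  nm <- length(mets)
  expand <- function(b) if (length(b) == 1L) stats::setNames(rep(b, nm), mets) else b[mets]
  lb <- log(expand(state$conc_lb)); ub <- log(expand(state$conc_ub))
  axes <- lapply(seq_len(nm), function(i) seq(lb[i], ub[i], length.out = pts))
  if (is.null(names(kinetics)))
    names(kinetics) <- vapply(kinetics, `[[`, "", "reaction_id")

  eval_block <- function(X) {           # X: rows = points, cols = mets
    total <- numeric(nrow(X))
    ok <- rep(TRUE, nrow(X))
    for (id in names(reactions)) {
      st <- reactions[[id]]
      dg <- state$reaction_dg0[[id]] + state$RT * as.numeric(X[, names(st), drop = FALSE] %*% st)
      ok <- ok & dg < 0
      eta_t <- 1 - exp(dg / state$RT)
      eta_s <- rep(1, nrow(X))
      for (s in names(st)[st < 0]) {
        ratio <- exp(X[, s]) / (kinetics[[id]]$km[[s]] * 1e-3)
        eta_s <- eta_s * ratio / (1 + ratio)
      }
      kin <- kinetics[[id]]
      total <- total + kin$enzyme_mass / (kin$kcat * eta_s * pmax(eta_t, 1e-300))
    }
    total[!ok] <- Inf
    total
  }

  best <- Inf
  rest <- as.matrix(do.call(expand.grid, axes[-1, drop = FALSE]))
  if (nm == 1L) rest <- matrix(numeric(0), nrow = 1, ncol = 0)
  for (x1 in axes[[1]]) {
    X <- cbind(x1, rest)
    colnames(X) <- mets
    best <- min(best, min(eval_block(X)))
  }
  best
}

toy_with_roles <- function() build_fixture("branched_toy")

# branched_toy deletable set used throughout: everything except the
# non-deletable uptake/biomass/target plus the product branch kept intact.
toy_deletable <- function(model = build_fixture("branched_toy"))
  setdiff(model$reactions$id, c("R_up", "v_bio", "v8"))

# A strongly growth-coupled variant of diamond_coupled: the biomass drain
# co-produces the product precursor, so every growing mode also secretes
# product and the biomass-only set S_x is empty.
build_strong_coupling <- function() {
  base <- build_fixture("diamond_coupled")
  cfg <- pathway_config(
    name = "coupled_biomass",
    added_reactions = list(reaction("v_bio2", c(C = -1, P = 0.5),
                                    role = "biomass", deletable = FALSE)),
    removed_reaction_ids = character(0))
  m <- apply_pathway(sto_model(
    base$metabolites,
    lapply(which(base$reactions$id != "v_bio"), function(i) {
      r <- base$reactions[i, ]
      reaction(r$id, base$stoich[[r$id]], reversible = r$reversible,
               lb = r$lb, ub = r$ub, role = r$role, deletable = r$deletable)
    }),
    precursors = base$precursors, name = "strong_coupling"), cfg)
  m
}
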