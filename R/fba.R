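# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Flux-balance problems (A x = 0) are maximally degenerate, so the
# anti-cycling rule is not optional here. Problems are fixture-scale
# (tens of variables), where a dense tableau is perfectly adequate.
#
# simplex_bland: min costs'x s.t. A x = b (b >= 0 after flipping), x >= 0.
simplex_pivot <- function(Tb, basis, costs, n) {
  m <- nrow(Tb)
  repeat {
    cb <- costs[basis]
    red <- costs[seq_len(n)] - as.numeric(crossprod(Tb[, seq_len(n), drop = FALSE], cb))
    enter <- which(red < -1e-9)
    if (!length(enter)) return(list(Tb = Tb, basis = basis, status = "optimal"))
    j <- min(enter)                                  # Bland: lowest index enters
    col <- Tb[, j]
    pos <- which(col > 1e-9)
    if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
    ratios <- Tb[pos, n + 1L] / col[pos]
    cand <- pos[ratios <= min(ratios) + 1e-12]
    i <- cand[which.min(basis[cand])]                # Bland: lowest basis index leaves
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    upd <- which(abs(Tb[, j]) > 0 & seq_len(m) != i)
    if (length(upd))
      Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, j], Tb[i, ])
    basis[i] <- j
  }
}

simplex_bland <- function(costs, A, b) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]; b[flip] <- -b[flip]
  # phase 1: artificials on every row
  Tb <- cbind(A, diag(1, m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  r1 <- simplex_pivot(Tb, basis, c(rep(0, n), rep(1, m)), n + m)
  if (sum(r1$Tb[r1$basis > n, n + m + 1L]) > 1e-7)
    return(list(status = "infeasible"))
  Tb <- r1$Tb; basis <- r1$basis
  # pivot zero-level artificials out; drop rows that prove redundant
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    piv <- which(abs(Tb[i, seq_len(n)]) > 1e-9)
    if (!length(piv)) { drop_rows <- c(drop_rows, i); next }
    j <- piv[1L]
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    for (k in seq_len(nrow(Tb))) if (k != i) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
    basis[i] <- j
  }
  if (length(drop_rows)) { Tb <- Tb[-drop_rows, , drop = FALSE]; basis <- basis[-drop_rows] }
  Tb <- Tb[, c(seq_len(n), n + m + 1L), drop = FALSE]       # drop artificial columns
  r2 <- simplex_pivot(Tb, basis, costs, n)
  if (r2$status != "optimal") return(list(status = r2$status))
  x <- numeric(n)
  x[r2$basis] <- r2$Tb[, n + 1L]
  list(status = "optimal", x = x)
}

# Bounded LP front end: optimise obj'x s.t. Aeq x = beq, lb <= x <= ub.
# Variables are shifted to y = x - lb >= 0 and upper bounds become slack
# rows y + s = ub - lb. All bounds must be finite.
solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  n <- length(obj)
  beq2 <- beq - as.numeric(Aeq %*% lb)
  keep <- apply(Aeq, 1, function(r) any(abs(r) > .OD_TOL))
  if (any(abs(beq2[!keep]) > 1e-7))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  Aeq <- Aeq[keep, , drop = FALSE]; beq2 <- beq2[keep]
  ubs <- ub - lb
  # fixed variables (ub == lb) are forced to zero after the shift: drop
  # their columns from the balance so they can never enter the basis
  free <- which(ubs > .OD_TOL)
  nf <- length(free)
  Aeq[, setdiff(seq_len(n), free)] <- 0
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), nf)),
             cbind(diag(1, n)[free, , drop = FALSE], diag(1, nf)))
  bvec <- c(beq2, ubs[free])
  obj2 <- obj
  obj2[setdiff(seq_len(n), free)] <- 0       # fixed vars contribute via lb only
  costs <- c(if (maximize) -obj2 else obj2, rep(0, nf))
  res <- simplex_bland(costs, A, bvec)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, x = NULL))
  x <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * x), x = x)
}

lp_bounds <- function(model) {
  list(lb = model$reactions$lb, ub = model$reactions$ub)
}

#' Flux balance analysis
#'
#' Solves `max/min v_obj` subject to `S v = 0` and `lb <= v <= ub` with a
#' deterministic two-phase simplex. All reaction bounds are finite, so the
#' problem is always bounded.
#'
#' @param model An `od_model`.
#' @param objective_id Reaction id to optimise (defaults to the biomass
#'   reaction).
#' @param sense `"max"` or `"min"`.
#' @param fixed Optional named numeric of fluxes to pin (`lb = ub = value`).
#' @return List with `objective` (optimal flux) and `fluxes` (named optimal
#'   flux vector). Infeasibility raises an error of class
#'   `od_lp_infeasible`.
#' @export
fba <- function(model, objective_id = NULL, sense = c("max", "min"), fixed = NULL) {
  stopifnot(inherits(model, "od_model"))
  sense <- match.arg(sense)
  objective_id <- objective_id %||% role_id(model, "biomass")
  if (is.null(objective_id) || !objective_id %in% model$reactions$id)
    od_stop(sprintf("objective reaction '%s' not in model", objective_id %||% "<none>"),
            "od_validation_error")
  b <- lp_bounds(model)
  if (!is.null(fixed)) {
    j <- match(names(fixed), model$reactions$id)
    if (anyNA(j)) od_stop("fixed flux names unknown reaction", "od_validation_error")
    b$lb[j] <- b$ub[j] <- as.numeric(fixed)
  }
  obj <- as.numeric(model$reactions$id == objective_id)
  sol <- solve_lp(obj, model$S, rep(0, nrow(model$S)), b$lb, b$ub,
                  maximize = sense == "max")
  if (sol$status != "optimal")
    od_stop(sprintf("FBA %s of '%s': %s", sense, objective_id, sol$status),
            "od_lp_infeasible")
  list(objective = sol$objective,
       fluxes = stats::setNames(sol$x, model$reactions$id))
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable steady-state flux per reaction, optionally
#' with other fluxes pinned (e.g. biomass at its optimum).
#'
#' @param model An `od_model`.
#' @param reaction_ids Reactions to scan (default: all).
#' @param fixed Optional named numeric of pinned fluxes.
#' @return Data frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reaction_ids = NULL, fixed = NULL) {
  stopifnot(inherits(model, "od_model"))
  reaction_ids <- reaction_ids %||% model$reactions$id
  res <- lapply(reaction_ids, function(id) {
    c(fba(model, id, "min", fixed = fixed)$objective,
      fba(model, id, "max", fixed = fixed)$objective)
  })
  data.frame(reaction = reaction_ids,
             min = vapply(res, `[[`, 0, 1L),
             max = vapply(res, `[[`, 0, 2L))
}

set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  j <- match(id, model$reactions$id)
  if (anyNA(j)) od_stop(sprintf("unknown reaction '%s'", id), "od_validation_error")
  if (!is.null(lb)) model$reactions$lb[j] <- lb
  if (!is.null(ub)) model$reactions$ub[j] <- ub
  model
}

delete_reactions <- function(model, ids) set_bounds(model, ids, lb = 0, ub = 0)

#' Valve-throttled production envelopes
#'
#' For each valve opening fraction `f`, caps the valve reaction's upper
#' bound at `f` times its wild-type reference flux (the FVA maximum of the
#' valve at the wild-type growth optimum) and sweeps biomass flux from 0 to
#' its constrained maximum, recording the minimum and maximum product flux
#' at each point. Throttling the single valve reaction shrinks the
#' attainable (biomass, product) region toward the high-yield zero-growth
#' edge; envelopes at smaller fractions are nested inside larger ones.
#'
#' @param model An `od_model` with biomass and target roles.
#' @param valve_id Reaction id of the valve.
#' @param fractions Valve openings in \[0, 1\] (default the standard sweep
#'   1, 0.5, 0.2, 0.1, 0.05).
#' @param n_points Grid points along the biomass axis (default 50).
#' @param basis `"yield"` reports axes per mol substrate uptaken (dividing
#'   fluxes by the uptake bound); `"flux"` reports raw fluxes.
#' @return List of class `od_envelope_set`; one element per fraction, each a
#'   list with `valve_fraction`, `points` (data frame `biomass`,
#'   `product_min`, `product_max`) and `area` (trapezoidal area between the
#'   product bounds over the biomass axis).
#' @export
production_envelope <- function(model, valve_id,
                                fractions = c(1, 0.5, 0.2, 0.1, 0.05),
                                n_points = 50L, basis = c("yield", "flux")) {
  stopifnot(inherits(model, "od_model"), all(fractions >= 0), all(fractions <= 1))
  basis <- match.arg(basis)
  roles <- model_roles(model)
  if (is.null(roles$biomass) || is.null(roles$target))
    od_stop("envelope requires tagged biomass and target reactions", "od_validation_error")
  mu_wt <- fba(model, roles$biomass, "max")$objective
  vstar <- fba(model, valve_id, "max",
               fixed = stats::setNames(mu_wt, roles$biomass))$objective
  scale <- if (basis == "yield") {
    if (is.null(roles$uptake))
      od_stop("yield basis requires a tagged uptake reaction", "od_validation_error")
    model$reactions$ub[model$reactions$id == roles$uptake]
  } else 1

  out <- lapply(fractions, function(f) {
    m <- set_bounds(model, valve_id, ub = f * vstar)
    mu_max <- fba(m, roles$biomass, "max")$objective
    grid <- if (mu_max > .OD_TOL) seq(0, mu_max, length.out = n_points) else 0
    pts <- t(vapply(grid, function(mu) {
      fx <- stats::setNames(mu, roles$biomass)
      c(fba(m, roles$target, "min", fixed = fx)$objective,
        fba(m, roles$target, "max", fixed = fx)$objective)
    }, numeric(2)))
    df <- data.frame(biomass = grid / scale,
                     product_min = pts[, 1] / scale,
                     product_max = pts[, 2] / scale)
    area <- if (nrow(df) > 1L)
      sum(diff(df$biomass) * (head(df$product_max - df$product_min, -1) +
                              tail(df$product_max - df$product_min, -1)) / 2)
    else 0
    list(valve_fraction = f, points = df, area = area)
  })
  structure(out, class = "od_envelope_set")
}

#' @export
print.od_envelope_set <- function(x, ...) {
  cat("<od_envelope_set>\n")
  for (e in x)
    cat(sprintf("  valve %3.0f%% open: %d points, area %.4g\n",
                100 * e$valve_fraction, nrow(e$points), e$area))
  invisible(x)
}

#' Write production envelopes to TSV
#'
#' Long-form table with columns `fraction`, `biomass`, `product_min`,
#' `product_max`.
#'
#' @param envelopes An `od_envelope_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_tsv <- function(envelopes, path) {
  df <- do.call(rbind, lapply(envelopes, function(e)
    cbind(fraction = e$valve_fraction, e$points)))
  df[-1] <- lapply(df[-1], function(col) signif(col, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
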