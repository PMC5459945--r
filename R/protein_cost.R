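# Gas constant, kJ mol^-1 K^-1
.R_GAS <- 8.31446e-3

#' Per-reaction enzyme kinetics
#'
#' @param reaction_id Reaction id.
#' @param kcat Turnover number (s^-1), > 0.
#' @param km Named numeric, metabolite id -> Michaelis constant (mM), > 0.
#' @param enzyme_mass Enzyme molecular mass (g mol^-1), > 0.
#' @return List of class `od_kinetics`.
#' @export
enzyme_kinetics <- function(reaction_id, kcat, km, enzyme_mass) {
  if (kcat <= 0 || enzyme_mass <= 0 || any(km <= 0))
    od_stop(sprintf("kinetics for '%s': kcat, Km and enzyme mass must be positive",
                    reaction_id), "od_validation_error")
  structure(list(reaction_id = reaction_id, kcat = kcat, km = km,
                 enzyme_mass = enzyme_mass), class = "od_kinetics")
}

#' Thermodynamic state of a pathway
#'
#' Holds transformed standard reaction Gibbs energies and (log) metabolite
#' concentration bounds. Concentrations are in molar; the default
#' physiological window is 1 uM to 10 mM.
#'
#' @param reaction_dg0 Named numeric, reaction id -> transformed standard
#'   Gibbs energy (kJ mol^-1).
#' @param conc_lb,conc_ub Named numeric or scalar concentration bounds (M).
#' @param temperature Kelvin (default 298.15, giving RT = 2.479 kJ mol^-1).
#' @return List of class `od_thermo` with `RT` precomputed.
#' @export
thermo_state <- function(reaction_dg0, conc_lb = 1e-6, conc_ub = 1e-2,
                         temperature = 298.15) {
  structure(list(reaction_dg0 = reaction_dg0, conc_lb = conc_lb,
                 conc_ub = conc_ub, temperature = temperature,
                 RT = .R_GAS * temperature), class = "od_thermo")
}

#' Thermodynamic driving force of a reaction
#'
#' The transformed reaction Gibbs energy at given metabolite concentrations,
#' `dG' = dG'0 + RT * sum_i nu_i ln(c_i)`. Negative values drive net forward
#' flux; the more negative, the larger the usable fraction of the enzyme's
#' capacity.
#'
#' @param state An [thermo_state()].
#' @param stoichiometry Named numeric, metabolite -> signed coefficient.
#' @param log_conc Named numeric, metabolite -> ln(concentration / 1 M).
#' @param reaction_id Reaction id (for `dg0` lookup and messages).
#' @return dG' in kJ mol^-1.
#' @export
driving_force <- function(state, stoichiometry, log_conc, reaction_id) {
  stopifnot(inherits(state, "od_thermo"))
  missing <- setdiff(names(stoichiometry), names(log_conc))
  if (length(missing))
    od_stop(sprintf("reaction '%s': no concentration for metabolite(s) %s",
                    reaction_id, paste(missing, collapse = ", ")),
            "od_validation_error")
  dg0 <- state$reaction_dg0[[reaction_id]]
  if (is.null(dg0))
    od_stop(sprintf("no standard Gibbs energy for reaction '%s'", reaction_id),
            "od_validation_error")
  dg0 + state$RT * sum(stoichiometry * log_conc[names(stoichiometry)])
}

#' Thermodynamic and saturation efficiencies of a reaction
#'
#' `eta_therm = 1 - exp(dG'/RT)` is the fraction of enzyme capacity left
#' after the backward flux implied by the driving force; it requires
#' `dG' < 0`. `eta_sat` is the multiplicative Michaelis-Menten saturation
#' over the reaction's substrates, `prod_i (c_i/Km_i) / (1 + c_i/Km_i)`.
#'
#' @param state An [thermo_state()].
#' @param kinetics An [enzyme_kinetics()].
#' @param stoichiometry Named signed coefficients in the flux direction
#'   (substrates negative).
#' @param log_conc Named log-concentrations (ln M).
#' @return Named numeric `eta_therm`, `eta_sat`, each in (0, 1\].
#' @export
efficiencies <- function(state, kinetics, stoichiometry, log_conc) {
  dg <- driving_force(state, stoichiometry, log_conc, kinetics$reaction_id)
  if (dg >= 0)
    od_stop(sprintf(
      "reaction '%s': dG' = %.3g kJ/mol >= 0; no net forward flux possible",
      kinetics$reaction_id, dg), "od_infeasible_direction")
  eta_therm <- 1 - exp(dg / state$RT)
  subs <- names(stoichiometry)[stoichiometry < 0]
  eta_sat <- 1
  for (s in subs) {
    if (is.na(kinetics$km[s]))
      od_stop(sprintf("reaction '%s': no Km for substrate '%s'",
                      kinetics$reaction_id, s), "od_validation_error")
    ratio <- exp(log_conc[[s]]) / (kinetics$km[[s]] * 1e-3)  # Km mM -> M
    eta_sat <- eta_sat * ratio / (1 + ratio)
  }
  c(eta_therm = eta_therm, eta_sat = unname(eta_sat))
}

#' Minimum protein cost of one reaction
#'
#' `cost = flux * mass / (kcat * eta_sat * eta_therm)` in g s mol^-1: grams
#' of enzyme needed per mol/s of pathway input flux, with `flux` the
#' reaction's flux relative to that input. The ideal-enzyme floor is
#' `mass / kcat`.
#'
#' @param kinetics An [enzyme_kinetics()].
#' @param eta_therm,eta_sat Efficiencies in (0, 1\].
#' @param flux Reaction flux relative to the pathway input (default 1).
#' @return Cost in g s mol^-1. Efficiencies at zero raise
#'   `od_infinite_cost`.
#' @export
reaction_cost <- function(kinetics, eta_therm, eta_sat, flux = 1) {
  if (eta_therm <= 0 || eta_sat <= 0)
    od_stop(sprintf("reaction '%s': vanishing efficiency, protein cost diverges",
                    kinetics$reaction_id), "od_infinite_cost")
  flux * kinetics$enzyme_mass / (kinetics$kcat * eta_sat * eta_therm)
}

pathway_dg <- function(pathway, state, x) {
  vapply(seq_along(pathway$reactions), function(i)
    driving_force(state, pathway$reactions[[i]], x, pathway$ids[i]), 0)
}

pathway_total_cost <- function(pathway, kinetics, state, x, therm_on = TRUE) {
  total <- 0
  per <- data.frame(reaction = pathway$ids, flux = pathway$fluxes,
                    dg = NA_real_, eta_therm = NA_real_, eta_sat = NA_real_,
                    cost = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(pathway$ids)) {
    eff <- efficiencies(state, kinetics[[pathway$ids[i]]],
                        pathway$reactions[[i]], x)
    et <- if (therm_on) eff[["eta_therm"]] else 1
    per$dg[i] <- driving_force(state, pathway$reactions[[i]], x, pathway$ids[i])
    per$eta_therm[i] <- eff[["eta_therm"]]
    per$eta_sat[i] <- eff[["eta_sat"]]
    per$cost[i] <- reaction_cost(kinetics[[pathway$ids[i]]], et,
                                 eff[["eta_sat"]], pathway$fluxes[i])
    total <- total + per$cost[i]
  }
  list(total = total, per_reaction = per)
}

normalize_pathway <- function(reactions, fluxes = NULL) {
  ids <- names(reactions)
  if (is.null(ids)) od_stop("pathway reactions must be a named list", "od_validation_error")
  fluxes <- fluxes %||% rep(1, length(ids))
  list(ids = ids, reactions = reactions, fluxes = fluxes)
}

#' Max-min driving force of a pathway
#'
#' Linear program over log-concentrations: maximise the smallest
#' thermodynamic driving force `-dG'` across the pathway's reactions,
#' subject to concentration bounds. A non-positive optimum means no
#' concentration assignment can drive every reaction forward.
#'
#' @param reactions Named list: reaction id -> signed stoichiometry (named
#'   numeric over metabolites) in the flux direction.
#' @param state An [thermo_state()].
#' @return List `mdf` (kJ mol^-1), `log_conc` (named optimum),
#'   `bottlenecks` (reactions tight at the optimum).
#' @export
max_min_driving_force <- function(reactions, state) {
  pw <- normalize_pathway(reactions)
  mets <- sort(unique(unlist(lapply(pw$reactions, names))))
  nm <- length(mets)
  expand <- function(b) if (length(b) == 1L) stats::setNames(rep(b, nm), mets) else b[mets]
  lb <- log(expand(state$conc_lb)); ub <- log(expand(state$conc_ub))
  # vars: x (log conc), eps; constraint per reaction:
  #   dg0 + RT * nu.x <= -eps  <=>  RT*nu.x + eps + slack = -dg0
  nr <- length(pw$ids)
  A <- matrix(0, nr, nm + 1L, dimnames = list(pw$ids, c(mets, ".eps")))
  rhs <- numeric(nr)
  for (i in seq_len(nr)) {
    st <- pw$reactions[[i]]
    A[i, names(st)] <- state$RT * st
    A[i, ".eps"] <- 1
    rhs[i] <- -state$reaction_dg0[[pw$ids[i]]]
  }
  # slack variables turn the inequalities into equalities
  Aeq <- cbind(A, diag(1, nr))
  obj <- c(rep(0, nm), 1, rep(0, nr))
  big <- sum(abs(c(rhs, state$RT * (abs(lb) + abs(ub))))) + 100
  sol <- solve_lp(obj, Aeq, rhs, lb = c(lb, -big, rep(0, nr)),
                  ub = c(ub, big, rep(big, nr)), maximize = TRUE)
  if (sol$status != "optimal")
    od_stop("driving-force LP did not solve", "od_lp_infeasible")
  x <- stats::setNames(sol$x[seq_len(nm)], mets)
  mdf <- sol$x[nm + 1L]
  dg <- pathway_dg(pw, state, x)
  list(mdf = mdf, log_conc = x,
       bottlenecks = pw$ids[dg >= -mdf - 1e-6])
}

#' Minimise the protein cost of a pathway over metabolite concentrations
#'
#' Finds log-metabolite concentrations within physiological bounds that
#' minimise the pathway's total protein cost
#' `sum_r flux_r * mass_r / (kcat_r * eta_sat,r * eta_therm,r)`.
#' Feasibility (a concentration assignment with every `dG' < 0`) is first
#' established by the max-min driving-force LP; the nonlinear cost is then
#' minimised by deterministic multistart local descent (the MDF optimum plus
#' a coarse interior lattice, polished with `L-BFGS-B`). The thermodynamic
#' contribution reports how much of the optimal cost is attributable to
#' backward-flux losses: `(total - total with eta_therm = 1) / total * 100`.
#'
#' @param reactions Named list: reaction id -> signed stoichiometry in the
#'   flux direction (substrates negative).
#' @param kinetics List of [enzyme_kinetics()], named by reaction id (or
#'   unnamed; ids are taken from the objects).
#' @param state An [thermo_state()].
#' @param fluxes Relative fluxes (per mol pathway input), default 1 each.
#' @param n_starts Lattice points per dimension for multistart (default 5).
#' @return Object of class `od_pathway_cost`: `total_cost`, `per_reaction`
#'   (data frame with cost and efficiency decomposition),
#'   `thermo_contribution` (percent), `log_conc`, `mdf`.
#' @export
minimize_pathway_cost <- function(reactions, kinetics, state, fluxes = NULL,
                                  n_starts = 5L) {
  pw <- normalize_pathway(reactions, fluxes)
  if (is.null(names(kinetics)))
    names(kinetics) <- vapply(kinetics, `[[`, "", "reaction_id")
  missing <- setdiff(pw$ids, names(kinetics))
  if (length(missing))
    od_stop(sprintf("no kinetics for reaction(s): %s", paste(missing, collapse = ", ")),
            "od_validation_error")

  feas <- max_min_driving_force(reactions, state)
  if (feas$mdf <= 0)
    od_stop(sprintf(
      "pathway thermodynamically infeasible within concentration bounds; bottleneck reaction(s): %s",
      paste(feas$bottlenecks, collapse = ", ")), "od_thermo_infeasible")

  mets <- names(feas$log_conc)
  nm <- length(mets)
  expand <- function(b) if (length(b) == 1L) stats::setNames(rep(b, nm), mets) else b[mets]
  lb <- log(expand(state$conc_lb)); ub <- log(expand(state$conc_ub))

  fn <- function(xv) {
    x <- stats::setNames(xv, mets)
    dg <- pathway_dg(pw, state, x)
    if (any(dg >= -1e-7)) return(1e12 * (1 + sum(pmax(dg + 1e-7, 0))))
    pathway_total_cost(pw, kinetics, state, x)$total
  }

  grid1 <- lapply(seq_len(nm), function(i)
    lb[i] + (ub[i] - lb[i]) * seq(0.1, 0.9, length.out = n_starts))
  starts <- as.matrix(do.call(expand.grid, grid1))
  starts <- rbind(feas$log_conc, starts)
  vals <- apply(starts, 1, fn)
  polish <- utils::head(order(vals), 3L)
  best <- NULL
  for (i in polish) {
    opt <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    cand <- if (!is.null(opt) && opt$value < vals[i])
      list(par = opt$par, value = opt$value)
    else list(par = starts[i, ], value = vals[i])
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  x <- stats::setNames(best$par, mets)
  with_t <- pathway_total_cost(pw, kinetics, state, x, therm_on = TRUE)
  no_t <- pathway_total_cost(pw, kinetics, state, x, therm_on = FALSE)
  structure(list(total_cost = with_t$total,
                 per_reaction = with_t$per_reaction,
                 thermo_contribution = 100 * (with_t$total - no_t$total) / with_t$total,
                 log_conc = x, mdf = feas$mdf),
            class = "od_pathway_cost")
}

#' @export
print.od_pathway_cost <- function(x, ...) {
  cat(sprintf("Pathway protein cost: %.4g g s mol^-1 (thermodynamic contribution %.3g%%)\n",
              x$total_cost, x$thermo_contribution))
  print(transform(x$per_reaction, cost = signif(cost, 4), dg = signif(dg, 4),
                  eta_therm = signif(eta_therm, 4), eta_sat = signif(eta_sat, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Read kinetics and Gibbs-energy tables
#'
#' Expects a TSV with columns `reaction_id`, `kcat` (s^-1), `enzyme_mass`
#' (g mol^-1), `dg0` (kJ mol^-1), plus a long-form Km table with columns
#' `reaction_id`, `metabolite_id`, `km_mM`.
#'
#' @param kinetics_path,km_path TSV paths.
#' @return List with `kinetics` (named list of [enzyme_kinetics()]) and
#'   `dg0` (named numeric).
#' @export
read_kinetics_tsv <- function(kinetics_path, km_path) {
  kt <- utils::read.table(kinetics_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  km <- utils::read.table(km_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("reaction_id", "kcat", "enzyme_mass", "dg0")
  if (!all(need %in% names(kt)))
    od_stop(sprintf("kinetics TSV must have columns: %s", paste(need, collapse = ", ")),
            "od_format_error")
  kin <- lapply(seq_len(nrow(kt)), function(i) {
    sub <- km[km$reaction_id == kt$reaction_id[i], ]
    enzyme_kinetics(kt$reaction_id[i], kt$kcat[i],
                    stats::setNames(sub$km_mM, sub$metabolite_id),
                    kt$enzyme_mass[i])
  })
  names(kin) <- kt$reaction_id
  list(kinetics = kin, dg0 = stats::setNames(kt$dg0, kt$reaction_id))
}
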