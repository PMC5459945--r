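#' Enumerate elementary flux modes
#'
#' Computes all elementary flux modes (EFMs) of a model: the minimal-support
#' nonnegative steady-state flux distributions, unique up to positive
#' scaling. Any steady-state flux of the network is a nonnegative combination
#' of them.
#'
#' The algorithm is the classic tableau / double-description iteration on the
#' irreversible flux cone: starting from one candidate ray per reaction, each
#' mass-balance row is imposed in turn by keeping rays already in its kernel
#' and combining positive/negative pairs, followed by a support-minimality
#' (elementarity) sweep. Reversible reactions are split into forward/backward
#' pairs first ([split_reversible()]); the futile two-cycle modes this
#' creates are discarded. Rays are renormalised to a unit maximum coefficient
#' at every step and coefficients below `1e-9` are treated as zero.
#'
#' @param model An `od_model` (reversible reactions allowed; they are split
#'   internally). Reactions with `lb == ub == 0` are excluded as blocked.
#' @param max_modes Abort with a resource error if the working ray count
#'   exceeds this limit (default 500000).
#' @return An object of class `od_efm_set`: list with `modes` (matrix,
#'   columns = split reactions, one row per mode, max coefficient 1),
#'   `supports` (list of character vectors, split-reaction ids),
#'   `orig_supports` (supports mapped back to unsplit reaction ids),
#'   `model` (the split model), `mapping` (reversible split map), and after
#'   [partition_modes()] also `partition`, `m`, `n`. Modes are ordered
#'   lexicographically by support. An infeasible network yields zero modes,
#'   not an error.
#' @export
enumerate_efms <- function(model, max_modes = 500000L) {
  stopifnot(inherits(model, "od_model"))
  sp <- split_reversible(model)
  smodel <- sp$model
  blocked <- smodel$reactions$lb == 0 & smodel$reactions$ub == 0
  S <- smodel$S[, !blocked, drop = FALSE]
  rxn_ids <- colnames(S)
  n <- ncol(S)

  R <- diag(1, n)                      # candidate rays as columns
  for (i in seq_len(nrow(S))) {
    d <- as.numeric(S[i, , drop = FALSE] %*% R)
    d[abs(d) < .OD_TOL] <- 0
    zero <- which(d == 0); pos <- which(d > 0); neg <- which(d < 0)
    new <- R[, zero, drop = FALSE]
    if (length(pos) && length(neg)) {
      combos <- vector("list", length(pos) * length(neg))
      k <- 0L
      for (p in pos) for (q in neg) {
        k <- k + 1L
        v <- d[p] * R[, q] - d[q] * R[, p]
        v[abs(v) < .OD_TOL * max(abs(v))] <- 0
        combos[[k]] <- v / max(v)
      }
      new <- cbind(new, do.call(cbind, combos))
    }
    if (ncol(new) > max_modes)
      od_stop(sprintf(
        "mode enumeration exceeded max_modes = %d (working set %d at constraint %d/%d)",
        max_modes, ncol(new), i, nrow(S)), "od_resource_limit")
    R <- drop_nonelementary(new)
  }

  if (ncol(R)) {
    # remove futile two-cycles from reversible splitting
    if (nrow(sp$mapping)) {
      twocycle <- vapply(seq_len(ncol(R)), function(j) {
        supp <- rxn_ids[R[, j] > .OD_TOL]
        length(supp) == 2L &&
          length(unique(sp$mapping$orig_id[match(supp, sp$mapping$split_id)])) == 1L &&
          !anyNA(match(supp, sp$mapping$split_id))
      }, TRUE)
      R <- R[, !twocycle, drop = FALSE]
    }
    R <- R[, order(apply(R > .OD_TOL, 2, function(z) paste(as.integer(z), collapse = ""))),
           drop = FALSE]
  }

  modes <- t(R)
  colnames(modes) <- rxn_ids
  supports <- lapply(seq_len(nrow(modes)), function(j) rxn_ids[modes[j, ] > .OD_TOL])
  orig_supports <- lapply(supports, function(s) {
    m <- match(s, sp$mapping$split_id)
    unique(ifelse(is.na(m), s, sp$mapping$orig_id[m]))
  })
  structure(list(modes = modes, supports = supports, orig_supports = orig_supports,
                 model = smodel, mapping = sp$mapping,
                 partition = NULL, m = NA_integer_, n = NA_integer_),
            class = "od_efm_set")
}

# Keep only rays whose support is not a proper superset of another ray's
# support (and deduplicate equal supports, keeping the first).
drop_nonelementary <- function(R) {
  n <- ncol(R)
  if (n <= 1L) return(R)
  supp <- R > .OD_TOL
  key <- apply(supp, 2, function(z) paste(as.integer(z), collapse = ""))
  keepdup <- !duplicated(key)
  R <- R[, keepdup, drop = FALSE]; supp <- supp[, keepdup, drop = FALSE]
  n <- ncol(R)
  sizes <- colSums(supp)
  ord <- order(sizes)
  minimal <- rep(TRUE, n)
  cross <- crossprod(supp)                 # cross[i,j] = |supp_i . supp_j|
  for (a in seq_len(n)) {
    i <- ord[a]
    if (!minimal[i]) next
    contains_i <- cross[i, ] == sizes[i] & sizes > sizes[i]
    minimal[contains_i] <- FALSE
  }
  R[, minimal, drop = FALSE]
}

#' @export
print.od_efm_set <- function(x, ...) {
  cat(sprintf("<od_efm_set: %d modes over %d reactions>\n",
              nrow(x$modes), ncol(x$modes)))
  if (!is.null(x$partition))
    cat(sprintf("  partition: %d biomass-only (S_x), %d product-only (S_t), %d coupled, %d neither\n",
                x$n, x$m, sum(x$partition == "coupled"), sum(x$partition == "neither")))
  invisible(x)
}

#' Partition elementary modes into biomass-only and product-only sets
#'
#' Labels every mode: `S_x` when it carries biomass flux but no target flux,
#' `S_t` when it carries target flux but no biomass flux, `coupled` when
#' both, `neither` otherwise. The counts `n = |S_x|` and `m = |S_t|` drive
#' the orthogonality score.
#'
#' @param efms An `od_efm_set`.
#' @param biomass_id,target_id Reaction ids; default to the model's role
#'   tags.
#' @return The `od_efm_set` with `partition`, `m`, `n` filled in.
#' @export
partition_modes <- function(efms, biomass_id = NULL, target_id = NULL) {
  stopifnot(inherits(efms, "od_efm_set"))
  roles <- model_roles(efms$model)
  biomass_id <- biomass_id %||% roles$biomass
  target_id <- target_id %||% roles$target
  if (is.null(biomass_id) || is.null(target_id))
    od_stop("model has no tagged biomass/target reaction and none was given",
            "od_validation_error")
  flux_of <- function(id) {
    cols <- if (id %in% efms$mapping$orig_id)
      efms$mapping$split_id[efms$mapping$orig_id == id] else id
    cols <- intersect(cols, colnames(efms$modes))
    if (!length(cols)) rep(0, nrow(efms$modes))
    else apply(abs(efms$modes[, cols, drop = FALSE]), 1, max)
  }
  b <- flux_of(biomass_id) > .OD_TOL
  t <- flux_of(target_id) > .OD_TOL
  efms$partition <- ifelse(b & t, "coupled", ifelse(b, "S_x", ifelse(t, "S_t", "neither")))
  efms$m <- sum(efms$partition == "S_t")
  efms$n <- sum(efms$partition == "S_x")
  efms$biomass_id <- biomass_id
  efms$target_id <- target_id
  efms
}

#' Molar yield of one elementary mode
#'
#' The scale-invariant coefficient ratio of two reactions within a mode,
#' e.g. target flux per substrate uptake (mol/mol).
#'
#' @param efms An `od_efm_set`.
#' @param mode_index Row index of the mode.
#' @param numerator_id,denominator_id Reaction ids (unsplit ids allowed).
#' @return Numeric ratio.
#' @export
mode_yield <- function(efms, mode_index, numerator_id, denominator_id) {
  stopifnot(inherits(efms, "od_efm_set"))
  v <- efms$modes[mode_index, ]
  coef <- function(id) {
    cols <- if (id %in% efms$mapping$orig_id)
      efms$mapping$split_id[efms$mapping$orig_id == id] else id
    cols <- intersect(cols, names(v))
    if (!length(cols)) 0 else max(abs(v[cols]))
  }
  den <- coef(denominator_id)
  if (den <= .OD_TOL)
    od_stop(sprintf("yield undefined: mode %d carries no flux through '%s'",
                    mode_index, denominator_id), "od_undefined_yield")
  coef(numerator_id) / den
}

#' Write an elementary-mode set to sparse TSV files
#'
#' Emits a long-form coefficient table (`mode`, `reaction`, `coefficient`)
#' and, when the set is partitioned, a companion `<path>.partition.tsv`.
#'
#' @param efms An `od_efm_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_efms_tsv <- function(efms, path) {
  stopifnot(inherits(efms, "od_efm_set"))
  idx <- which(efms$modes > .OD_TOL, arr.ind = TRUE)
  df <- data.frame(mode = idx[, 1],
                   reaction = colnames(efms$modes)[idx[, 2]],
                   coefficient = signif(efms$modes[idx], 10))
  df <- df[order(df$mode, df$reaction), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(efms$partition))
    utils::write.table(
      data.frame(mode = seq_along(efms$partition), set = efms$partition),
      paste0(path, ".partition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
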