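#' Similarity between a product-only and a biomass-only mode
#'
#' The fraction of the biomass mode's reactions that the product mode also
#' uses: `|supp(t) . supp(x)| / |supp(x)|`, i.e. the shared-reaction count
#' normalised to the size of the biomass-supporting mode. Supports are
#' binary (a reaction is either in a mode or not); flux magnitudes do not
#' enter.
#'
#' @param t_support,x_support Character vectors: reaction supports of a
#'   product-only (`S_t`) and biomass-only (`S_x`) mode.
#' @return Similarity in \[0, 1\].
#' @export
pair_similarity <- function(t_support, x_support) {
  if (!length(x_support))
    od_stop("biomass mode has empty support", "od_validation_error")
  length(intersect(t_support, x_support)) / length(x_support)
}

efm_pair_values <- function(efms) {
  stopifnot(inherits(efms, "od_efm_set"))
  if (is.null(efms$partition))
    od_stop("mode set is not partitioned; call partition_modes() first",
            "od_validation_error")
  if (efms$m == 0L || efms$n == 0L)
    od_stop(sprintf(
      "orthogonality score is undefined: m = %d product-only and n = %d biomass-only modes",
      efms$m, efms$n), "od_undefined_score")
  st <- efms$supports[efms$partition == "S_t"]
  sx <- efms$supports[efms$partition == "S_x"]
  vals <- as.numeric(vapply(sx, function(x)
    vapply(st, pair_similarity, 0, x_support = x), numeric(length(st))))
  structure(list(values = vals, m = efms$m, n = efms$n),
            class = "od_similarity_distribution")
}

#' Average similarity between the product and biomass mode sets
#'
#' The mean of [pair_similarity()] over all `m x n` pairs of product-only and
#' biomass-only modes. Undefined (error of class `od_undefined_score`) when
#' either set is empty, which is the strongly growth-coupled case.
#'
#' @param efms A partitioned `od_efm_set`.
#' @return Average similarity in \[0, 1\].
#' @export
average_similarity <- function(efms) {
  mean(efm_pair_values(efms)$values)
}

#' Sample bimodality coefficient
#'
#' Sarle's sample-corrected coefficient
#' `b = (G1^2 + 1) / (G2 + 3 (N-1)^2 / ((N-2)(N-3)))`, with `G1` the
#' bias-corrected sample skewness and `G2` the bias-corrected sample excess
#' kurtosis. `b > 5/9` flags a bimodal/multimodal distribution; a uniform
#' sample sits at the 5/9 boundary in the large-N limit.
#'
#' @param values Numeric vector, length >= 4.
#' @return The coefficient `b`.
#' @export
bimodality_coefficient <- function(values) {
  N <- length(values)
  if (N < 4L)
    od_stop("bimodality coefficient requires at least 4 values", "od_validation_error")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 < .OD_TOL^2) return(0)        # degenerate point mass: unimodal
  g1 <- mean((values - m)^3) / m2^1.5
  g2 <- mean((values - m)^4) / m2^2 - 3
  G1 <- g1 * sqrt(N * (N - 1)) / (N - 2)
  G2 <- ((N + 1) * g2 + 6) * (N - 1) / ((N - 2) * (N - 3))
  (G1^2 + 1) / (G2 + 3 * (N - 1)^2 / ((N - 2) * (N - 3)))
}

# Location of the highest-density mode of a sample via a Freedman-Diaconis
# histogram; ties broken toward the higher bin.
fd_mode_estimate <- function(values) {
  n <- length(values)
  iqr <- stats::IQR(values)
  h <- if (iqr > 0) 2 * iqr / n^(1 / 3) else 0
  if (h <= 0) return(stats::median(values))
  breaks <- seq(min(values), max(values) + h, by = h)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  best <- max(which(counts == max(counts)))
  (breaks[best] + breaks[best + 1L]) / 2
}

#' Orthogonality score of a partitioned mode set
#'
#' For every pair of a product-only mode `t` and biomass-only mode `x`, the
#' per-pair orthogonality is `o(t,x) = 1 - s(t,x)` with `s` the shared
#' fraction of the biomass mode's reactions ([pair_similarity()]). When the
#' per-pair distribution is unimodal (bimodality coefficient <= 5/9, or
#' fewer than 4 pairs), the score is its mean, `OS = 1 - AS`; when the
#' distribution is flagged multimodal the score is the location of its
#' highest-density mode (Freedman-Diaconis histogram, ties toward the higher
#' value).
#'
#' A score of 1 means chemical production is fully separable from biomass
#' formation (disjoint supports); 0 means every biomass mode is contained in
#' every product mode. The score is undefined when there are no product-only
#' modes (`m = 0`) or no biomass-only modes (`n = 0`, strong growth
#' coupling); this raises an error of class `od_undefined_score`.
#'
#' @param efms A partitioned `od_efm_set`.
#' @param model Optional unsplit `od_model` supplying precursor tags; when
#'   given (or when the split model carries precursors) the result includes
#'   precursor-reaction metrics.
#' @return Object of class `od_orthogonality_result`: list with
#'   `average_similarity`, `score`, `bimodality_coefficient`, `multimodal`,
#'   `mode_estimate`, `per_pair`, `m`, `n`, `total_precursor_reactions`,
#'   `avg_precursor_reactions_per_efm`.
#' @export
orthogonality_score <- function(efms, model = NULL) {
  pp <- efm_pair_values(efms)
  o <- 1 - pp$values
  b <- if (length(o) >= 4L) bimodality_coefficient(o) else NA_real_
  multimodal <- isTRUE(!is.na(b) && b > 5 / 9)
  mode_est <- if (multimodal) fd_mode_estimate(o) else NA_real_
  score <- if (multimodal) mode_est else mean(o)
  pm <- precursor_reaction_metrics(efms, model %||% efms$model)
  structure(list(average_similarity = mean(pp$values), score = score,
                 bimodality_coefficient = b, multimodal = multimodal,
                 mode_estimate = mode_est, per_pair = pp,
                 m = pp$m, n = pp$n,
                 total_precursor_reactions = pm[["total"]],
                 avg_precursor_reactions_per_efm = pm[["average"]]),
            class = "od_orthogonality_result")
}

#' @export
print.od_orthogonality_result <- function(x, ...) {
  cat(sprintf("Orthogonality score: %.4g  (average similarity %.4g; m = %d, n = %d)\n",
              x$score, x$average_similarity, x$m, x$n))
  if (!is.na(x$bimodality_coefficient))
    cat(sprintf("  bimodality coefficient %.4g -> %s\n", x$bimodality_coefficient,
                if (x$multimodal) "multimodal (histogram mode used)" else "unimodal (mean used)"))
  if (!is.na(x$total_precursor_reactions))
    cat(sprintf("  precursor-supporting reactions: %d total, %.4g per product mode\n",
                x$total_precursor_reactions, x$avg_precursor_reactions_per_efm))
  invisible(x)
}

#' Precursor-supporting reaction metrics over the product modes
#'
#' Counts, for each product-only (`S_t`) mode, the support reactions that
#' produce at least one biomass-precursor metabolite (positive
#' stoichiometric coefficient toward a precursor in the direction the mode
#' runs them), summed over all `S_t` modes; the average divides by `m`.
#' These quantify the residual intersection chemical production has with
#' biomass formation.
#'
#' @param efms A partitioned `od_efm_set`.
#' @param model Model carrying `precursors` (defaults to the mode set's).
#' @param precursors Optional explicit precursor metabolite ids.
#' @return Named numeric: `total`, `average`.
#' @export
precursor_reaction_metrics <- function(efms, model = NULL,
                                       precursors = NULL) {
  stopifnot(inherits(efms, "od_efm_set"))
  model <- model %||% efms$model
  precursors <- precursors %||% model$precursors
  if (is.null(efms$partition) || efms$m == 0L || !length(precursors))
    return(c(total = if (!length(precursors)) 0 else NA_real_,
             average = if (!length(precursors)) 0 else NA_real_))
  S <- efms$model$S
  pre <- intersect(precursors, rownames(S))
  counts <- vapply(which(efms$partition == "S_t"), function(i) {
    supp <- efms$supports[[i]]
    sum(vapply(supp, function(r) any(S[pre, r] > 0), TRUE))
  }, 0L)
  c(total = sum(counts), average = sum(counts) / efms$m)
}

#' Compare two per-pair orthogonality distributions
#'
#' Two-sample Kolmogorov-Smirnov test on per-pair orthogonality values
#' (`1 - s`), used to compare the score distribution of a pathway against a
#' reference (e.g. the natural glycolytic route).
#'
#' @param a,b `od_similarity_distribution` objects (from an
#'   `od_orthogonality_result$per_pair`) or bare numeric vectors of per-pair
#'   similarities.
#' @return Named list `statistic`, `p_value`.
#' @export
compare_score_distributions <- function(a, b) {
  va <- if (inherits(a, "od_similarity_distribution")) a$values else as.numeric(a)
  vb <- if (inherits(b, "od_similarity_distribution")) b$values else as.numeric(b)
  if (!length(va) || !length(vb))
    od_stop("both distributions must be non-empty", "od_validation_error")
  kt <- suppressWarnings(stats::ks.test(1 - va, 1 - vb))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
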