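#' Assemble a run configuration
#'
#' Central defaults for the analysis pipeline: yield threshold 1 mol/mol,
#' substrate uptake 20 mmol gDW^-1 h^-1, valve admission at 90% of
#' wild-type growth, valve sweep fractions 1/0.5/0.2/0.1/0.05.
#'
#' @param model An `od_model`, or a path to one.
#' @param model_format `"json"` or `"sbml"` when `model` is a path.
#' @param roles Optional sidecar role designation (list or YAML path).
#' @param pathway Optional [pathway_config()] applied before analysis.
#' @param precursors Optional precursor metabolite ids (overrides model's).
#' @param yield_threshold,uptake_rate,growth_fraction Pipeline parameters
#'   (defaults as above).
#' @param valve_fractions,max_modes,max_cut_cardinality Further pipeline
#'   parameters: envelope sweep fractions, mode-count guard, largest cut-set
#'   cardinality searched.
#' @param out_dir Output directory for reports.
#' @return List of class `od_run_config`.
#' @export
run_config <- function(model, model_format = "json", roles = NULL, pathway = NULL,
                       precursors = NULL, yield_threshold = 1, uptake_rate = 20,
                       growth_fraction = 0.9,
                       valve_fractions = c(1, 0.5, 0.2, 0.1, 0.05),
                       max_modes = 500000L, max_cut_cardinality = 5L,
                       out_dir = ".") {
  if (is.character(model)) {
    if (is.character(roles)) roles <- read_roles_config(roles)
    model <- load_model(model, model_format, roles = roles)
  }
  if (!is.null(pathway)) model <- apply_pathway(model, pathway)
  roles_t <- model_roles(model)
  up <- roles_t$uptake
  if (!is.null(up)) model <- set_bounds(model, up, ub = uptake_rate)
  if (!is.null(precursors)) model$precursors <- precursors
  structure(list(model = model, yield_threshold = yield_threshold,
                 uptake_rate = uptake_rate, growth_fraction = growth_fraction,
                 valve_fractions = valve_fractions, max_modes = max_modes,
                 max_cut_cardinality = max_cut_cardinality, out_dir = out_dir),
            class = "od_run_config")
}

#' Score a network's orthogonality and write a summary table
#'
#' Enumerates elementary flux modes, partitions them, computes the
#' orthogonality score and precursor metrics, and writes a one-row summary
#' TSV (`score`, `total_precursor_supporting_reactions`,
#' `avg_precursor_reactions_per_efm`, mode counts) plus a JSON twin with the
#' full per-pair distribution.
#'
#' @param config An [run_config()].
#' @param basename Output file stem (default `"score"`).
#' @return The `od_orthogonality_result`, invisibly carrying the written
#'   paths in attribute `files`.
#' @export
run_score <- function(config, basename = "score") {
  stopifnot(inherits(config, "od_run_config"))
  efms <- partition_modes(enumerate_efms(config$model, config$max_modes))
  message(sprintf("run_score: %d modes (m = %d product-only, n = %d biomass-only); yield threshold %g, uptake %g",
                  nrow(efms$modes), efms$m, efms$n,
                  config$yield_threshold, config$uptake_rate))
  res <- orthogonality_score(efms, model = config$model)
  row <- data.frame(
    score = res$score,
    average_similarity = res$average_similarity,
    total_precursor_supporting_reactions = res$total_precursor_reactions,
    avg_precursor_reactions_per_efm = res$avg_precursor_reactions_per_efm,
    modes = nrow(efms$modes), m = res$m, n = res$n)
  files <- write_report(row, file.path(config$out_dir, basename),
                        json_extra = list(per_pair = res$per_pair$values,
                                          bimodality_coefficient = res$bimodality_coefficient,
                                          multimodal = res$multimodal))
  attr(res, "files") <- files
  invisible(res)
}

#' Run the full ValveFind pipeline and write the design table
#'
#' Modes -> low-yield target modes -> minimal cut sets -> valve search ->
#' valve-off audit -> orthogonality ranking. Output columns: `cutset`,
#' `valve`, `restored_growth_fraction`, `score`, `precursors_off`,
#' `product_yield_off`.
#'
#' @param config An [run_config()].
#' @param basename Output file stem (default `"designs"`).
#' @return The `od_design_list`, invisibly, with attribute `files`.
#' @export
run_valvefind <- function(config, basename = "designs") {
  stopifnot(inherits(config, "od_run_config"))
  efms <- partition_modes(enumerate_efms(config$model, config$max_modes))
  targets <- select_target_modes(efms, config$yield_threshold)
  cutsets <- enumerate_mcs(targets, efms,
                           max_cardinality = config$max_cut_cardinality)
  message(sprintf("run_valvefind: %d modes, %d targeted (yield < %g), %d minimal cut sets (<= %d reactions)",
                  nrow(efms$modes), length(targets$mode_indices),
                  config$yield_threshold, length(cutsets),
                  config$max_cut_cardinality))
  designs <- rank_designs(config$model, cutsets, config$growth_fraction,
                          max_modes = config$max_modes)
  files <- write_report(as.data.frame(designs), file.path(config$out_dir, basename))
  attr(designs, "files") <- files
  invisible(designs)
}

#' Write a result table as TSV plus a JSON twin
#'
#' Stable column order, floats printed with 4 significant digits in the TSV;
#' the JSON twin keeps full precision and any extra diagnostics.
#'
#' @param df Data frame (may have zero rows; the header is still written).
#' @param stem Output path without extension.
#' @param json_extra Optional named list appended to the JSON object.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_report <- function(df, stem, json_extra = NULL) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  fmt <- df
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], signif, digits = 4)
  utils::write.table(fmt, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(table = df), json_extra), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
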