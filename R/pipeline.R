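#' Run the network lesion experiment end-to-end
#'
#' Builds the MT and MST layers, sweeps the deactivation probability over
#' `p_values`, and (optionally) reports which cell-loss range matches a
#' given behavioral error. All artifacts (curve CSV, summary JSON including
#' the full configuration and seed) are written under `out_dir` when given.
#'
#' @param config Named list (or path to a JSON file) overriding defaults:
#'   `p_values`, `n_seeds`, `n_dots`, `grid_az_span`, `grid_el_span`,
#'   `mt_seed`, `mst_seed`, `behavioral_error_deg`, `readout`.
#' @param seed Master seed for stimulus and lesion draws.
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing.
#' @return List: `curve` (per-trial tibble), `summary` (per-p tibble),
#'   `matched` (cell-loss match, or NULL), `config`.
#' @export
run_network_experiment <- function(config = list(), seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    p_values = seq(0, 0.10, by = 0.01),
    n_seeds = 100,
    n_dots = 100,
    grid_az_span = 15,
    grid_el_span = 5,
    mt_seed = 1,
    mst_seed = 1,
    behavioral_error_deg = NULL,
    readout = "centroid"
  ), config)
  frustum <- build_frustum()
  mt <- build_mt_population(seed = cfg$mt_seed)
  grid <- heading_grid(az = seq(-cfg$grid_az_span, cfg$grid_az_span, by = 1),
                       el = seq(-cfg$grid_el_span, cfg$grid_el_span, by = 1))
  layer <- build_mst_layer(mt, grid, seed = cfg$mst_seed, frustum = frustum)
  curve <- lesion_error_curve(layer, mt, p_values = cfg$p_values,
                              n_seeds = cfg$n_seeds, n_dots = cfg$n_dots,
                              frustum = frustum, seed = seed,
                              readout = cfg$readout)
  summ <- lesion_error_summary(curve)
  matched <- if (!is.null(cfg$behavioral_error_deg)) {
    match_cell_loss(summ, cfg$behavioral_error_deg)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      curve[, c("p", "seed", "heading_deg", "estimate_deg", "abs_error_deg")],
      file.path(out_dir, "lesion_curve.csv")
    )
    jsonlite::write_json(
      list(seed = seed, config = cfg, summary = summ, matched = matched),
      file.path(out_dir, "network_summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
  }
  list(curve = curve, summary = summ, matched = matched,
       config = c(cfg, seed = seed))
}

#' Run the behavioral analysis pipeline
#'
#' Either reads a trial CSV (see [read_trials_csv()] for the layout) or
#' generates synthetic test/control cohorts, then computes per-condition
#' statistics, regression fits, per-heading precision, and the
#' cell-by-cell group comparison with FDR correction.
#'
#' @param trials Trial tibble, or path to a trial CSV, or `NULL` to
#'   generate the default synthetic cohorts.
#' @param alpha FDR level for the group comparison.
#' @param seed Seed for synthetic-cohort generation.
#' @param out_dir Output directory for the stats/comparison CSVs; `NULL`
#'   writes nothing.
#' @return List: `trials`, `condition_stats`, `precision` (per group),
#'   `comparisons`, `regressions`.
#' @export
run_behavioral_pipeline <- function(trials = NULL, alpha = 0.05, seed = 1,
                                    out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials_csv(trials)
  if (is.null(trials)) {
    trials <- dplyr::bind_rows(
      generate_cohort(default_cohort("control", seed = seed)),
      generate_cohort(default_cohort("test", seed = derive_seed(seed, 11L)))
    )
  }
  if (nrow(trials) == 0) {
    abort("Trial table is empty.", class = "headingflow_parse_error")
  }
  stats_tbl <- condition_summary(trials)
  precision <- trials |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ precision_by_heading(.x)) |>
    dplyr::ungroup()
  groups <- unique(trials$group)
  comparisons <- NULL
  regressions <- NULL
  if (length(groups) == 2) {
    a <- trials[trials$group == groups[1], ]
    b <- trials[trials$group == groups[2], ]
    comparisons <- compare_conditions(a, b, alpha = alpha)
    regressions <- compare_regressions(a, b)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(stats_tbl, file.path(out_dir, "condition_stats.csv"))
    readr::write_csv(precision, file.path(out_dir, "precision.csv"))
    if (!is.null(comparisons)) {
      readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    }
  }
  list(trials = trials, condition_stats = stats_tbl, precision = precision,
       comparisons = comparisons, regressions = regressions)
}
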