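#' Analysis scenario
#'
#' A declarative description of one analysis run: the primary analysis or
#' one of the seven sensitivity analyses. The same prepared data
#' ([prepare_cea_data()]) is re-aggregated under each scenario's choices.
#'
#' @param name Scenario label.
#' @param perspective `"societal"` (all costs) or `"healthcare"` (health
#'   care and intervention costs only - productivity and respondent costs
#'   excluded).
#' @param include_productivity Include absenteeism costs (must be `FALSE`
#'   under the healthcare perspective).
#' @param min_followups Minimum number of completed follow-up questionnaires
#'   (0..8), counted before imputation.
#' @param effect_variant `"lfs"` (discounted 24-month score), `"lfci"`
#'   (change from baseline), `"qaly"` or `"qaly_baseline_adjusted"`.
#' @param outlier_exclusion_percentile Optional percentile in (50, 100);
#'   participants with total costs above this single global cutoff are
#'   excluded (one pass, threshold computed before exclusion).
#' @param r_cost,r_effect Annual discount rates for second-year costs and
#'   effects (defaults 0.04 and 0.015).
#' @param qaly_adjust_method Baseline-adjustment variant for
#'   `"qaly_baseline_adjusted"` (see [adjust_qaly_baseline()]).
#' @param auc_method QALY integration rule, `"trapezoid"` or `"rectangle"`
#'   (see [qaly_auc()]).
#' @return A `cea_scenario` list.
#' @export
scenario <- function(name = "primary",
                     perspective = c("societal", "healthcare"),
                     include_productivity = TRUE,
                     min_followups = 0,
                     effect_variant = c("lfs", "lfci", "qaly",
                                        "qaly_baseline_adjusted"),
                     outlier_exclusion_percentile = NULL,
                     r_cost = 0.04, r_effect = 0.015,
                     qaly_adjust_method = c("regression", "anchored"),
                     auc_method = c("trapezoid", "rectangle")) {
  perspective <- match.arg(perspective)
  effect_variant <- match.arg(effect_variant)
  qaly_adjust_method <- match.arg(qaly_adjust_method)
  auc_method <- match.arg(auc_method)
  if (perspective == "healthcare" && include_productivity) {
    stop("healthcare perspective excludes productivity costs; ",
         "set include_productivity = FALSE")
  }
  stopifnot(min_followups %in% 0:8, r_cost >= 0, r_effect >= 0)
  if (!is.null(outlier_exclusion_percentile)) {
    stopifnot(outlier_exclusion_percentile > 50,
              outlier_exclusion_percentile < 100)
  }
  structure(list(name = name, perspective = perspective,
                 include_productivity = include_productivity,
                 min_followups = min_followups,
                 effect_variant = effect_variant,
                 outlier_exclusion_percentile = outlier_exclusion_percentile,
                 r_cost = r_cost, r_effect = r_effect,
                 qaly_adjust_method = qaly_adjust_method,
                 auc_method = auc_method),
            class = "cea_scenario")
}

#' The primary analysis plus the seven sensitivity scenarios
#'
#' For a given effect family (`"lfs"` or `"qaly"`) returns the primary
#' scenario and the seven sensitivity analyses: (1) healthcare perspective;
#' (2) productivity costs excluded; (3) at least 4 of 8 follow-up
#' questionnaires completed; (4) change-from-baseline outcome (LFCI, or
#' baseline-adjusted QALY); (5) participants above the 95th total-cost
#' percentile excluded; (6) no discounting; (7) both costs and effects
#' discounted at 4%.
#'
#' @param effect `"lfs"` or `"qaly"`.
#' @return Named list of [scenario()] objects.
#' @export
default_scenarios <- function(effect = c("lfs", "qaly")) {
  effect <- match.arg(effect)
  baseline_variant <- if (effect == "lfs") "lfci" else "qaly_baseline_adjusted"
  list(
    primary = scenario("primary", effect_variant = effect),
    healthcare_perspective = scenario(
      "healthcare_perspective", perspective = "healthcare",
      include_productivity = FALSE, effect_variant = effect),
    no_productivity = scenario(
      "no_productivity", include_productivity = FALSE,
      effect_variant = effect),
    min_4_followups = scenario(
      "min_4_followups", min_followups = 4, effect_variant = effect),
    baseline_corrected = scenario(
      "baseline_corrected", effect_variant = baseline_variant),
    outliers_excluded = scenario(
      "outliers_excluded", outlier_exclusion_percentile = 95,
      effect_variant = effect),
    no_discounting = scenario(
      "no_discounting", r_cost = 0, r_effect = 0, effect_variant = effect),
    discount_both_4pct = scenario(
      "discount_both_4pct", r_cost = 0.04, r_effect = 0.04,
      effect_variant = effect)
  )
}

#' Read scenarios from a YAML file
#'
#' The file holds a list of scenario entries whose fields are the arguments
#' of [scenario()].
#'
#' @param path YAML file path.
#' @return Named list of `cea_scenario` objects.
#' @export
read_scenarios <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read scenario files")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) do.call(scenario, x))
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Run one scenario end to end
#'
#' Builds the scenario's analysis set, aggregates arms, computes all
#' pairwise incremental comparisons, and estimates acceptability curves by
#' stratified bootstrap.
#'
#' @param cea A [prepare_cea_data()] result.
#' @param scenario A [scenario()].
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param n_boot Bootstrap replicates (default 1000, matching the
#'   uncertainty analysis convention).
#' @param seed Integer seed.
#' @return A `scenario_result` list: `scenario`, `data` (analysis set),
#'   `aggregates`, `incremental`, `ceac`.
#' @export
run_scenario <- function(cea, scenario = lifecea::scenario(),
                         wtp_grid = seq(0, 80000, by = 1000),
                         n_boot = 1000, seed = 1) {
  set_ <- analysis_set(cea, scenario)
  agg <- arm_aggregates(set_)
  structure(list(
    scenario = scenario,
    data = set_,
    aggregates = agg,
    incremental = incremental_table(agg),
    ceac = ceac(set_, wtp_grid = wtp_grid, n_boot = n_boot, seed = seed)
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario$name, "-", x$scenario$effect_variant,
      "\n")
  print(x$aggregates)
  print(x$incremental)
  invisible(x)
}

#' Probability-of-highest-NMB table across scenarios
#'
#' Runs every scenario and tabulates, per scenario, arm and reporting
#' willingness-to-pay value, the probability that the arm has the highest
#' net monetary benefit.
#'
#' @param cea A [prepare_cea_data()] result.
#' @param scenarios Named list of [scenario()] objects (default: the LFS
#'   family, [default_scenarios()]).
#' @param wtp Reporting willingness-to-pay values (default 0, 18,000 and
#'   80,000 euros; 18,000 is the accepted Dutch threshold per QALY gained
#'   for preventive interventions).
#' @param n_boot Bootstrap replicates per scenario.
#' @param seed Integer seed (each scenario derives its own substream).
#' @return Tibble: `scenario`, `arm`, `n`, one probability column per WTP
#'   value.
#' @export
scenario_suite <- function(cea, scenarios = default_scenarios("lfs"),
                           wtp = c(0, 18000, 80000), n_boot = 1000,
                           seed = 1) {
  rows <- list()
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    res <- run_scenario(cea, sc, wtp_grid = wtp, n_boot = n_boot,
                        seed = seed + k)
    pr <- res$ceac$probabilities
    long <- tidyr::pivot_longer(pr, cols = -"wtp", names_to = "arm",
                                values_to = "prob")
    wide <- tidyr::pivot_wider(long, names_from = "wtp",
                               values_from = "prob", names_prefix = "wtp_")
    wide <- dplyr::left_join(wide, res$aggregates[c("arm", "n")], by = "arm")
    wide$scenario <- sc$name
    rows[[k]] <- wide[c("scenario", "arm", "n",
                        paste0("wtp_", wtp))]
  }
  dplyr::bind_rows(rows)
}
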