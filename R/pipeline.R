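#' Prepare a trial dataset for economic evaluation
#'
#' Runs the fixed pre-analysis sequence: inclusion rule, pre-imputation
#' completeness count, plausibility truncation, the single-imputation
#' cascade on every quarterly variable (quarters 0..8), LOCF of the
#' 24-month lifestyle items from baseline where missing, EQ-5D scoring,
#' and valuation of all cost components in indexed euros.
#'
#' Discounting and effect aggregation are deliberately *not* applied here:
#' the returned object keeps undiscounted quarterly component costs and the
#' full utility trajectories, so sensitivity scenarios can vary discount
#' rates, perspectives and effect variants without re-running the
#' imputation (see [analysis_set()]).
#'
#' @param trial A `trial_data` list ([generate_trial()] or
#'   [read_trial_csv()]).
#' @param unit_costs A [unit_cost_table()].
#' @param cpi A [cpi_series()].
#' @param value_set An `eq5d_value_set`.
#' @param guidelines A [guideline_set()].
#' @param bounds Plausibility bounds (see [default_bounds()]).
#' @return A `cea_data` list: `participants` (demographics, LFS outcomes,
#'   per-quarter completeness, one-off time cost), `quarterly_costs`
#'   (indexed, undiscounted euros per participant x quarter 1..8 x
#'   component), `utilities` (participant x quarter utility, `NA` where
#'   unimputable), and reports from the inclusion and imputation steps.
#' @export
prepare_cea_data <- function(trial,
                             unit_costs = default_unit_costs(),
                             cpi = cpi_series_nl(),
                             value_set = eq5d_value_set_nl(),
                             guidelines = guideline_set(),
                             bounds = default_bounds()) {
  p <- trial$participants
  q <- trial$quarters

  # --- inclusion rule -------------------------------------------------
  adh0 <- adheres(p$pa_days_0, p$fruit_pieces_0, p$veg_grams_0,
                  p$alcohol_glasses_0, p$smoker_0, p$gender, guidelines)
  p$lfs_baseline <- lifestyle_factor_score(adh0)
  econ_cols <- intersect(c("medication", "services", "admission_days",
                           "other_care", "absent_days", "travel_trips"),
                         names(q))
  base_q <- q[q$quarter == 0, , drop = FALSE]
  base_done <- rowSums(!is.na(base_q[econ_cols])) > 0
  p$baseline_econ_completed <- base_done[match(p$id, base_q$id)]
  incl <- inclusion_filter(p)
  p <- incl$included
  q <- q[q$id %in% p$id, , drop = FALSE]

  # --- pre-imputation completeness (for the >=50% follow-ups scenario) --
  fup <- q[q$quarter > 0, , drop = FALSE]
  done <- if ("completed" %in% names(fup)) {
    fup$completed
  } else {
    rowSums(!is.na(fup[econ_cols])) > 0
  }
  n_fup <- tapply(done, factor(fup$id, levels = p$id), sum)
  p$n_followups <- as.integer(n_fup[p$id])

  # --- truncation + imputation cascade --------------------------------
  imp <- impute_trial(q[setdiff(names(q), "completed")], bounds = bounds)
  q <- imp$quarters

  # --- 24-month lifestyle items: LOCF from baseline where missing ------
  beh <- c("pa_days", "fruit_pieces", "veg_grams", "alcohol_glasses", "smoker")
  for (v in beh) {
    v24 <- paste0(v, "_24")
    v0 <- paste0(v, "_0")
    miss <- is.na(p[[v24]])
    p[[v24]][miss] <- p[[v0]][miss]
  }
  adh0_inc <- adheres(p$pa_days_0, p$fruit_pieces_0, p$veg_grams_0,
                      p$alcohol_glasses_0, p$smoker_0, p$gender, guidelines)
  adh24 <- adheres(p$pa_days_24, p$fruit_pieces_24, p$veg_grams_24,
                   p$alcohol_glasses_24, p$smoker_24, p$gender, guidelines)
  lfs <- lfs_outcomes(adh0_inc, adh24)
  p$lfs_24m_raw <- lfs$lfs_24m_raw
  p$lfci <- lfs$lfci

  # --- utilities -------------------------------------------------------
  eq_cols <- paste0("eq5d_", eq5d_dimensions)
  utilities <- tibble::tibble(
    id = q$id, quarter = q$quarter,
    utility = eq5d_utility(q[eq_cols], value_set)
  )

  # --- costs (indexed, undiscounted, quarters 1..8) --------------------
  fq <- q[q$quarter > 0, , drop = FALSE]
  long <- tidyr::pivot_longer(
    fq[c("id", "quarter", "medication", "services", "admission_days",
         "other_care")],
    cols = c("medication", "services", "admission_days", "other_care"),
    names_to = "category", values_to = "quantity")
  long$category <- ifelse(long$category == "admission_days", "admissions",
                          long$category)
  long <- value_health_care(long, unit_costs, cpi)
  hc <- tidyr::pivot_wider(long[c("id", "quarter", "category", "cost")],
                           names_from = "category", values_from = "cost")

  demo <- p[match(fq$id, p$id), c("gender", "age", "employed")]
  absenteeism <- productivity_cost(fq$absent_days, demo$gender, demo$age,
                                   demo$employed, unit_costs, cpi)
  travel <- index_cost(
    fq$travel_trips * unit_costs$km_per_visit * unit_costs$price_per_km,
    unit_costs$travel_price_year, cpi)
  quarterly_costs <- dplyr::bind_cols(
    hc[c("id", "quarter")],
    hc[c("medication", "services", "admissions", "other_care")],
    tibble::tibble(absenteeism = absenteeism, travel = travel))

  once <- respondent_costs(p$arm, p$gender, p$age,
                           travel_trips = 0, unit_costs, cpi)
  p$time_cost <- once$time_cost

  structure(list(
    participants = p,
    quarterly_costs = quarterly_costs,
    utilities = utilities,
    unit_costs = unit_costs,
    inclusion_report = incl$report,
    imputation_report = imp$report
  ), class = "cea_data")
}

#' @export
print.cea_data <- function(x, ...) {
  cat("<cea_data>", nrow(x$participants), "included participants\n")
  print(x$inclusion_report)
  invisible(x)
}

#' Participant-level analysis set for one scenario
#'
#' Applies a scenario's choices to prepared data: minimum-completeness
#' filter, cost-component selection by perspective, discounting of
#' second-year costs and effects, the chosen effect variant, and (last) the
#' single-pass exclusion of participants above the total-cost percentile.
#' The outlier threshold is computed once on the whole filtered population,
#' giving one global cutoff applied in every arm.
#'
#' Participants whose total cost is unimputable (a fully missing component
#' series) are dropped listwise from the cost side; participants without any
#' EQ-5D observation have `NA` QALYs. Rows with missing cost or effect are
#' excluded from the returned set, which is why Ns differ between effect
#' measures.
#'
#' @param cea A [prepare_cea_data()] result.
#' @param scenario A [scenario()]; defaults to the primary analysis.
#' @return Tibble: `id`, `arm`, `cost`, `effect` (plus component columns),
#'   with attributes `outlier_threshold` and `scenario`.
#' @export
analysis_set <- function(cea, scenario = lifecea::scenario()) {
  stopifnot(inherits(cea, "cea_data"), inherits(scenario, "cea_scenario"))
  p <- cea$participants
  if (scenario$min_followups > 0) {
    p <- p[p$n_followups >= scenario$min_followups, , drop = FALSE]
  }

  components <- c("medication", "services", "admissions", "other_care")
  if (scenario$perspective == "societal") {
    if (scenario$include_productivity) components <- c(components, "absenteeism")
    components <- c(components, "travel")
  }

  qc <- cea$quarterly_costs[cea$quarterly_costs$id %in% p$id, , drop = FALSE]
  disc <- dplyr::mutate(qc, dplyr::across(
    dplyr::all_of(components),
    ~ discount_quarter(.x, quarter, scenario$r_cost)))
  totals <- dplyr::summarise(
    dplyr::group_by(disc, .data$id),
    dplyr::across(dplyr::all_of(components), sum), .groups = "drop")
  totals$variable_cost <- rowSums(totals[components])

  out <- dplyr::left_join(p, totals, by = "id")
  out$cost <- out$variable_cost + cea$unit_costs$hosting_cost +
    if (scenario$perspective == "societal") out$time_cost else 0

  out$effect <- scenario_effect(out, cea, scenario)
  out <- out[!is.na(out$cost) & !is.na(out$effect), , drop = FALSE]

  threshold <- NA_real_
  if (!is.null(scenario$outlier_exclusion_percentile)) {
    threshold <- stats::quantile(out$cost,
                                 scenario$outlier_exclusion_percentile / 100,
                                 names = FALSE)
    out <- out[out$cost <= threshold, , drop = FALSE]
  }

  res <- out[c("id", "arm", "cost", "effect", components)]
  attr(res, "outlier_threshold") <- threshold
  attr(res, "scenario") <- scenario
  res
}

scenario_effect <- function(p, cea, scenario) {
  switch(scenario$effect_variant,
    lfs = p$lfs_24m_raw / (1 + scenario$r_effect),
    lfci = as.numeric(p$lfci),
    qaly = participant_qalys(cea, p$id, scenario$r_effect,
                             scenario$auc_method),
    qaly_baseline_adjusted = {
      qaly <- participant_qalys(cea, p$id, scenario$r_effect,
                                scenario$auc_method)
      u0 <- cea$utilities$utility[cea$utilities$quarter == 0]
      u0 <- u0[match(p$id, cea$utilities$id[cea$utilities$quarter == 0])]
      adjust_qaly_baseline(qaly, u0, scenario$r_effect,
                           scenario$qaly_adjust_method)
    },
    stop("unknown effect variant: ", scenario$effect_variant)
  )
}

participant_qalys <- function(cea, ids, r_effect, method = "trapezoid") {
  u <- cea$utilities[cea$utilities$id %in% ids, , drop = FALSE]
  u <- dplyr::arrange(u, .data$id, .data$quarter)
  per <- tapply(u$utility, factor(u$id, levels = ids), function(x) {
    if (anyNA(x) || length(x) != 9L) return(NA_real_)
    qaly_auc(seq(0, 24, by = 3), x, r_effect = r_effect, method = method)
  })
  as.numeric(per[ids])
}

#' Baseline adjustment of QALYs
#'
#' Two variants are provided because the adjustment formula is a genuine
#' modelling choice: `"regression"` (default) removes the pooled linear
#' association with baseline utility, `effect = QALY - b (u0 - mean(u0))`
#' with `b` from `lm(qaly ~ u0)`; `"anchored"` subtracts the QALYs a
#' participant would accrue by staying at their baseline utility for the
#' whole window, `QALY - u0 * D(r)` with `D(r) = 1 + 1/(1+r)` the discounted
#' 2-year duration.
#'
#' @param qaly,u0 Numeric vectors: discounted QALYs and baseline utilities.
#' @param r_effect Effect discount rate (used by the anchored variant).
#' @param method `"regression"` or `"anchored"`.
#' @return Adjusted effect vector.
#' @export
adjust_qaly_baseline <- function(qaly, u0, r_effect = 0.015,
                                 method = c("regression", "anchored")) {
  method <- match.arg(method)
  if (method == "anchored") {
    return(qaly - u0 * (1 + 1 / (1 + r_effect)))
  }
  ok <- !is.na(qaly) & !is.na(u0)
  if (sum(ok) < 3L || stats::var(u0[ok]) == 0) return(qaly)
  b <- stats::coef(stats::lm(qaly[ok] ~ u0[ok]))[[2]]
  qaly - b * (u0 - mean(u0[ok]))
}
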