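#' Configuration for the synthetic three-arm trial generator
#'
#' Defaults reproduce the structure of the trial the analysis targets: arm
#' sizes 552 / 517 / 664 (sequential, simultaneous, control), near-ceiling
#' baseline EQ-5D utilities (mean ~0.89 under the Dutch tariff), a baseline
#' lifestyle factor score around 3.3 of 5 guidelines, right-skewed quarterly
#' resource-use counts, absenteeism concentrated in a minority of quarters,
#' about 29% of participants returning no follow-up economic questionnaire
#' (more likely for younger participants and those with a lower baseline
#' LFS), monotone attrition thereafter, and intermittent item missingness.
#'
#' @param n_per_arm Named integer vector: participants per arm.
#' @param seed Integer seed; the same seed and configuration give a
#'   byte-identical dataset.
#' @param baseline_utility_mean Target mean baseline utility in (0, 1].
#' @param baseline_lfs_mean Target mean baseline LFS in \[0, 5\].
#' @param arm_lfs_effect Named numeric: expected shift in guidelines met at
#'   24 months, per arm.
#' @param arm_qaly_effect Named numeric: expected shift in 2-year QALYs, per
#'   arm (achieved by scaling follow-up EQ-5D severity probabilities).
#' @param arm_cost_effect Named numeric: expected shift in undiscounted
#'   biennial health care costs per arm, euros when valued with
#'   [default_unit_costs()] (spread evenly over the 8 follow-up quarters
#'   through the other-care category). Default 0 for all arms. Negative
#'   shifts are limited by the category's base mean (counts cannot go below
#'   zero), so large separations are best configured as increases on the
#'   comparator arms.
#' @param cost_distributions Named list of `list(shape =, mean =)` gamma
#'   mixing distributions for quarterly resource counts (gamma-Poisson, i.e.
#'   negative binomial - nonnegative and right-skewed).
#' @param absenteeism_rate Named numeric: expected absenteeism days per
#'   quarter, per arm.
#' @param absenteeism_shape Gamma shape of the absenteeism mixing
#'   distribution (small values give many zero quarters).
#' @param dropout_logit_coeffs Numeric `c(intercept, age, lfs)`: logistic
#'   model for returning no follow-up economic questionnaire. Age and
#'   baseline LFS enter centred at their sample means, so with zero
#'   coefficients the marginal dropout probability is
#'   `plogis(intercept)`. Negative coefficients make younger / lower-LFS
#'   participants drop out more, as observed.
#' @param quarterly_dropout_hazard Per-quarter probability that a participant
#'   who is still responding stops (monotone attrition).
#' @param missing_item_prob Probability that any single item on a returned
#'   follow-up questionnaire is missing.
#' @param employed_prob Probability of paid employment.
#' @param female_prob Probability of female gender.
#' @param age_range Uniform age window in years (trial inclusion window).
#' @param state_persistence Probability a follow-up EQ-5D state repeats the
#'   previous quarter's state instead of being redrawn.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    n_per_arm = c(sequential = 552, simultaneous = 517, control = 664),
    seed = 1L,
    baseline_utility_mean = 0.89,
    baseline_lfs_mean = 3.3,
    arm_lfs_effect = c(sequential = 0.10, simultaneous = 0.15, control = 0.05),
    arm_qaly_effect = c(sequential = -0.01, simultaneous = -0.03, control = 0),
    arm_cost_effect = c(sequential = 0, simultaneous = 0, control = 0),
    cost_distributions = list(
      medication     = list(shape = 0.5,  mean = 2.2),
      services       = list(shape = 0.8,  mean = 3.0),
      admission_days = list(shape = 0.15, mean = 0.2),
      other_care     = list(shape = 0.3,  mean = 1.1),
      travel_trips   = list(shape = 0.8,  mean = 2.7)
    ),
    absenteeism_rate = c(sequential = 2.2, simultaneous = 2.2, control = 1.6),
    absenteeism_shape = 0.2,
    dropout_logit_coeffs = c(intercept = stats::qlogis(0.292),
                             age = -0.02, lfs = -0.12),
    quarterly_dropout_hazard = 0.08,
    missing_item_prob = 0.03,
    employed_prob = 0.70,
    female_prob = 0.47,
    age_range = c(18, 65),
    state_persistence = 0.6) {

  arms <- c("sequential", "simultaneous", "control")
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid generator config: field '", field, "' ", msg,
                  call. = FALSE)
  }
  check(length(n_per_arm) == 3 && all(n_per_arm >= 1) &&
          all(n_per_arm == round(n_per_arm)), "n_per_arm",
        "must be 3 positive integers")
  if (is.null(names(n_per_arm))) names(n_per_arm) <- arms
  check(all(arms %in% names(n_per_arm)), "n_per_arm", "must name the 3 arms")
  check(baseline_utility_mean > 0 && baseline_utility_mean <= 1,
        "baseline_utility_mean", "must lie in (0, 1]")
  check(baseline_lfs_mean >= 0 && baseline_lfs_mean <= 5,
        "baseline_lfs_mean", "must lie in [0, 5]")
  check(all(arms %in% names(arm_lfs_effect)), "arm_lfs_effect",
        "must name the 3 arms")
  check(all(arms %in% names(arm_qaly_effect)), "arm_qaly_effect",
        "must name the 3 arms")
  check(all(arms %in% names(arm_cost_effect)), "arm_cost_effect",
        "must name the 3 arms")
  for (nm in names(cost_distributions)) {
    d <- cost_distributions[[nm]]
    check(d$shape > 0 && d$mean >= 0, paste0("cost_distributions$", nm),
          "needs shape > 0 and mean >= 0")
  }
  check(all(arms %in% names(absenteeism_rate)) && all(absenteeism_rate >= 0),
        "absenteeism_rate", "must be nonnegative and name the 3 arms")
  check(length(dropout_logit_coeffs) == 3, "dropout_logit_coeffs",
        "must be c(intercept, age, lfs)")
  check(quarterly_dropout_hazard >= 0 && quarterly_dropout_hazard <= 1,
        "quarterly_dropout_hazard", "must lie in [0, 1]")
  check(missing_item_prob >= 0 && missing_item_prob <= 1,
        "missing_item_prob", "must lie in [0, 1]")
  check(employed_prob >= 0 && employed_prob <= 1, "employed_prob",
        "must lie in [0, 1]")
  check(female_prob >= 0 && female_prob <= 1, "female_prob",
        "must lie in [0, 1]")
  check(length(age_range) == 2 && age_range[1] < age_range[2], "age_range",
        "must be an increasing pair")
  check(state_persistence >= 0 && state_persistence <= 1,
        "state_persistence", "must lie in [0, 1]")

  structure(list(
    n_per_arm = n_per_arm[arms], seed = as.integer(seed),
    baseline_utility_mean = baseline_utility_mean,
    baseline_lfs_mean = baseline_lfs_mean,
    arm_lfs_effect = arm_lfs_effect[arms],
    arm_qaly_effect = arm_qaly_effect[arms],
    arm_cost_effect = arm_cost_effect[arms],
    cost_distributions = cost_distributions,
    absenteeism_rate = absenteeism_rate[arms],
    absenteeism_shape = absenteeism_shape,
    dropout_logit_coeffs = dropout_logit_coeffs,
    quarterly_dropout_hazard = quarterly_dropout_hazard,
    missing_item_prob = missing_item_prob,
    employed_prob = employed_prob, female_prob = female_prob,
    age_range = age_range, state_persistence = state_persistence
  ), class = "generator_config")
}

# Per-dimension EQ-5D-3L level probabilities tuned so the Dutch-tariff mean
# utility is ~0.890 (SD ~0.13), reproducing the reported ceiling effect.
base_eq5d_probs <- function() {
  rbind(
    mobility = c(0.92, 0.075, 0.005),
    selfcare = c(0.97, 0.028, 0.002),
    activity = c(0.89, 0.105, 0.005),
    pain     = c(0.66, 0.322, 0.018),
    anxiety  = c(0.85, 0.145, 0.005)
  )
}

# Scale the severity (level 2/3) probabilities by `mult`, level 1 absorbing
# the remainder.
scale_severity <- function(probs, mult) {
  p <- probs
  p[, 2:3] <- pmax(p[, 2:3] * mult, 0)
  p[, 1] <- 1 - rowSums(p[, 2:3, drop = FALSE])
  p
}

# Expected Dutch-tariff decrement (1 - mean utility) under independent
# per-dimension draws from `probs`.
expected_decrement <- function(probs, value_set = eq5d_value_set_nl()) {
  states <- as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3, 1:3))
  u <- eq5d_utility(states, value_set)
  pr <- apply(states, 1, function(s) prod(probs[cbind(1:5, s)]))
  1 - sum(pr * u)
}

draw_states <- function(n, probs) {
  vapply(seq_len(5), function(d) {
    sample.int(3, n, replace = TRUE, prob = probs[d, ])
  }, integer(n))
}

# Natural-scale behaviour values consistent with a drawn adherence vector.
behaviour_values <- function(adh, gender, guidelines = guideline_set()) {
  n <- nrow(adh)
  limit <- ifelse(gender == "female", guidelines$alcohol_max_female,
                  guidelines$alcohol_max_male)
  tibble::tibble(
    pa_days = ifelse(adh$pa,
                     sample(5:7, n, TRUE, prob = c(0.6, 0.25, 0.15)),
                     sample(0:4, n, TRUE)),
    fruit_pieces = round(ifelse(adh$fruit,
                                guidelines$fruit_min_pieces + stats::rexp(n, 2),
                                stats::runif(n, 0, guidelines$fruit_min_pieces * 0.95)), 1),
    veg_grams = round(ifelse(adh$veg,
                             guidelines$veg_min_grams + stats::rexp(n, 1 / 60),
                             stats::runif(n, 40, guidelines$veg_min_grams * 0.98))),
    alcohol_glasses = round(ifelse(adh$alcohol,
                                   stats::runif(n, 0, limit),
                                   limit + 0.1 + stats::rexp(n, 1)), 1),
    smoker = !adh$nonsmoking
  )
}

# Gamma-Poisson (negative binomial) counts: nonnegative, right-skewed.
# `mean` may be a vector (e.g. per-arm rates aligned with rows).
rcount <- function(n, shape, mean) {
  if (all(mean == 0)) return(integer(n))
  stats::rpois(n, stats::rgamma(n, shape = shape, scale = mean / shape))
}

#' Generate a seeded synthetic three-arm trial dataset
#'
#' Produces a participant table (demographics, baseline and 24-month
#' lifestyle behaviours on their natural scales) and a long quarterly table
#' (quarters 0..8: resource-use counts, absenteeism days, travel trips, and
#' the five EQ-5D-3L item levels), then applies the configured missingness
#' via [apply_dropout()]. Baseline (quarter 0) is complete by construction:
#' the configured arm sizes are the sizes of the *included* analysis set.
#'
#' @param config A [generator_config()].
#' @return A `trial_data` list with tibbles `participants` and `quarters`.
#' @export
generate_trial <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  guidelines <- guideline_set()
  arms <- names(config$n_per_arm)
  n <- sum(config$n_per_arm)

  participants <- tibble::tibble(
    id = sprintf("p%04d", seq_len(n)),
    arm = rep(arms, times = config$n_per_arm),
    age = round(stats::runif(n, config$age_range[1], config$age_range[2]), 1),
    gender = ifelse(stats::rbinom(n, 1, config$female_prob) == 1,
                    "female", "male"),
    employed = stats::rbinom(n, 1, config$employed_prob) == 1
  )

  # Baseline adherence probabilities scaled to the configured mean LFS.
  p0 <- c(pa = 0.55, fruit = 0.55, veg = 0.55, alcohol = 0.85, nonsmoking = 0.80)
  p0 <- pmin(p0 * config$baseline_lfs_mean / sum(p0), 0.98)
  adh0 <- tibble::as_tibble(lapply(p0, function(p) stats::rbinom(n, 1, p) == 1))
  base_beh <- behaviour_values(adh0, participants$gender, guidelines)
  names(base_beh) <- paste0(names(base_beh), "_0")

  # 24-month adherence: baseline probability plus the configured arm shift
  # spread over the 5 guidelines, drawn independently so the expected LFS
  # shift equals the configured effect exactly.
  shift <- config$arm_lfs_effect[participants$arm] / 5
  adh24 <- tibble::as_tibble(lapply(p0, function(p) {
    stats::rbinom(n, 1, pmin(pmax(p + shift, 0), 1)) == 1
  }))
  beh24 <- behaviour_values(adh24, participants$gender, guidelines)
  names(beh24) <- paste0(names(beh24), "_24")

  participants <- dplyr::bind_cols(participants, base_beh, beh24)

  # EQ-5D probabilities: baseline tuned to the configured ceiling, follow-up
  # severities scaled per arm so the expected 2-year QALY shifts by the
  # configured arm effect (QALY ~ 2 x mean utility).
  probs0 <- base_eq5d_probs()
  dec0 <- expected_decrement(probs0)
  probs0 <- scale_severity(probs0, (1 - config$baseline_utility_mean) / dec0)
  dec_base <- expected_decrement(probs0)
  arm_probs <- lapply(config$arm_qaly_effect, function(delta) {
    scale_severity(probs0, max(1 - delta / (2 * dec_base), 0))
  })

  q <- tidyr::expand_grid(id = participants$id, quarter = 0:8)
  q <- dplyr::left_join(q, participants[c("id", "arm")], by = "id")

  # resource use, in participant-major order matching q
  nq <- nrow(q)
  # per-arm cost shift, euros over 8 quarters at the default other-care price
  other_price <- default_unit_costs()$prices$price[
    default_unit_costs()$prices$category == "other_care"]
  extra_other <- unname(config$arm_cost_effect[q$arm]) / (8 * other_price) *
    (q$quarter > 0)  # baseline quarter precedes randomization
  for (cat in names(config$cost_distributions)) {
    d <- config$cost_distributions[[cat]]
    mu <- if (cat == "other_care") pmax(d$mean + extra_other, 0) else d$mean
    q[[cat]] <- rcount(nq, d$shape, mu)
  }
  q$absent_days <- rcount(nq, config$absenteeism_shape,
                          unname(config$absenteeism_rate[q$arm]))
  q$absent_days <- pmin(q$absent_days, 90)

  # EQ-5D trajectories with quarter-to-quarter persistence
  states <- matrix(NA_integer_, nrow = nq, ncol = 5)
  base_rows <- which(q$quarter == 0)
  states[base_rows, ] <- draw_states(n, probs0)
  for (qq in 1:8) {
    rows <- which(q$quarter == qq)
    prev <- rows - 1L
    keep <- stats::runif(n) < config$state_persistence
    new_states <- states[prev, , drop = FALSE]
    for (a in arms) {
      redraw <- !keep & participants$arm == a
      if (any(redraw)) {
        new_states[redraw, ] <- draw_states(sum(redraw), arm_probs[[a]])
      }
    }
    states[rows, ] <- new_states
  }
  colnames(states) <- paste0("eq5d_", eq5d_dimensions)
  q <- dplyr::bind_cols(q, tibble::as_tibble(states))
  q$arm <- NULL

  trial <- structure(list(participants = participants,
                          quarters = q,
                          config = config),
                     class = "trial_data")
  apply_dropout(trial, config)
}

#' Apply the configured missingness mechanism to a complete trial dataset
#'
#' Two-component missing-at-random mechanism:
#'
#' 1. *Full dropout* - a logistic model on centred age and baseline LFS
#'    decides whether a participant returns no follow-up economic
#'    questionnaire at all (marginal rate `plogis(intercept)` when the
#'    covariate coefficients are zero).
#' 2. *Monotone attrition* - among the rest, each quarter is completed with
#'    probability `1 - quarterly_dropout_hazard` given the previous one was;
#'    once a questionnaire is missed, all later ones are too.
#'
#' On returned questionnaires, each item is additionally missing
#' independently with probability `missing_item_prob`. The 24-month
#' lifestyle measurement is observed only for participants still responding
#' at quarter 8. Baseline (quarter 0) is never made missing.
#'
#' @param trial A `trial_data` list (complete records).
#' @param config A [generator_config()].
#' @return The `trial_data` with missingness applied and a logical
#'   `completed` column added to `quarters`.
#' @export
apply_dropout <- function(trial, config = trial$config) {
  p <- trial$participants
  n <- nrow(p)
  adh0 <- adheres(p$pa_days_0, p$fruit_pieces_0, p$veg_grams_0,
                  p$alcohol_glasses_0, p$smoker_0, p$gender)
  lfs0 <- lifestyle_factor_score(adh0)

  co <- config$dropout_logit_coeffs
  eta <- co[[1]] +
    co[[2]] * (p$age - mean(p$age)) +
    co[[3]] * (lfs0 - mean(lfs0, na.rm = TRUE))
  full_dropout <- stats::runif(n) < stats::plogis(eta)

  # Last completed follow-up quarter: 0 for full dropouts. Everyone else
  # completes quarter 1 (so the zero-follow-up rate is exactly the logistic
  # rate) and then faces the quarterly attrition hazard up to quarter 8.
  surv <- matrix(stats::runif(n * 7) >= config$quarterly_dropout_hazard,
                 nrow = n)
  last_q <- ifelse(full_dropout, 0L,
                   apply(surv, 1, function(s) {
                     miss <- which(!s)
                     if (length(miss)) miss[1] else 8L
                   }))

  q <- trial$quarters
  ord <- match(q$id, p$id)
  q$completed <- q$quarter == 0 | q$quarter <= last_q[ord]

  item_cols <- setdiff(names(q), c("id", "quarter", "completed"))
  followup <- q$quarter > 0
  for (v in item_cols) {
    drop_item <- followup &
      (!q$completed | stats::runif(nrow(q)) < config$missing_item_prob)
    q[[v]][drop_item] <- NA
  }

  beh24 <- grep("_24$", names(p), value = TRUE)
  gone <- last_q < 8L
  for (v in beh24) p[[v]][gone] <- NA

  structure(list(participants = p, quarters = q, config = config),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data>", nrow(x$participants), "participants,",
      nrow(x$quarters), "participant-quarters\n")
  print(dplyr::count(x$participants, .data$arm))
  invisible(x)
}

#' Write / read a trial dataset as CSV files
#'
#' `write_trial_csv()` writes `participants.csv` (one row per participant)
#' and `quarters.csv` (one row per participant-quarter) to `dir`;
#' `read_trial_csv()` reads them back.
#'
#' @param trial A `trial_data` list.
#' @param dir Directory path.
#' @return `write_trial_csv()` returns `dir` invisibly; `read_trial_csv()`
#'   returns a `trial_data` list.
#' @export
write_trial_csv <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(trial$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$quarters, file.path(dir, "quarters.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(dir) {
  p <- tibble::as_tibble(utils::read.csv(file.path(dir, "participants.csv"),
                                         stringsAsFactors = FALSE))
  q <- tibble::as_tibble(utils::read.csv(file.path(dir, "quarters.csv"),
                                         stringsAsFactors = FALSE))
  structure(list(participants = p, quarters = q, config = NULL),
            class = "trial_data")
}
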