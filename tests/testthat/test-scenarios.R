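local_cea <- local({
  cea <- NULL
  function() {
    if (is.null(cea)) {
      cea <<- prepare_cea_data(generate_trial(quick_config(n = 70, seed = 29)))
    }
    cea
  }
})

test_that("scenario validation rejects contradictory flags", {
  expect_error(scenario(perspective = "healthcare",
                        include_productivity = TRUE), "healthcare")
  expect_error(scenario(outlier_exclusion_percentile = 40))
  expect_error(scenario(min_followups = 9))
  expect_silent(scenario(perspective = "healthcare",
                         include_productivity = FALSE))
})

test_that("healthcare-perspective totals drop productivity and respondent
           costs participant-wise", {
  cea <- local_cea()
  soc <- analysis_set(cea, scenario())
  hc <- analysis_set(cea, scenario(perspective = "healthcare",
                                   include_productivity = FALSE))
  m <- match(soc$id, hc$id)
  time_cost <- cea$participants$time_cost[match(soc$id, cea$participants$id)]
  expect_equal(hc$cost[m],
               soc$cost - soc$absenteeism - soc$travel - time_cost)
})

test_that("excluding productivity only removes the absenteeism component", {
  cea <- local_cea()
  soc <- analysis_set(cea, scenario())
  nop <- analysis_set(cea, scenario(include_productivity = FALSE))
  expect_equal(nop$cost, soc$cost - soc$absenteeism)
})

test_that("discount scenarios differ from the primary only in year-2 terms", {
  cea <- local_cea()
  primary <- analysis_set(cea, scenario())
  undisc <- analysis_set(cea, scenario(r_cost = 0, r_effect = 0))
  qc <- cea$quarterly_costs
  comp <- c("medication", "services", "admissions", "other_care",
            "absenteeism", "travel")
  y2 <- qc[qc$quarter >= 5, ]
  y2_total <- tapply(rowSums(y2[comp]), factor(y2$id, levels = primary$id), sum)
  gap <- as.numeric(y2_total[primary$id]) * (1 - 1 / 1.04)
  expect_equal(undisc$cost - primary$cost, gap)
  # 4% on both sides brackets the primary's effect discounting
  both4 <- analysis_set(cea, scenario(r_cost = 0.04, r_effect = 0.04))
  expect_equal(both4$cost, primary$cost)
  expect_true(all(both4$effect <= primary$effect))
  expect_true(all(undisc$effect >= primary$effect))
})

test_that("outlier exclusion keeps exactly the sub-percentile participants in
           a single pass", {
  cea <- prepare_cea_data(generate_trial(quick_config(n = 40, seed = 43)))
  # 120 participants with distinct continuous costs
  full <- analysis_set(cea, scenario())
  cut95 <- analysis_set(cea, scenario(outlier_exclusion_percentile = 95))
  expect_equal(nrow(cut95), ceiling(0.95 * nrow(full)))
  thr <- attr(cut95, "outlier_threshold")
  expect_equal(thr, unname(stats::quantile(full$cost, 0.95)))
  expect_true(all(cut95$cost <= thr))
})

test_that("the minimum-followups filter counts pre-imputation questionnaires", {
  cfg <- generator_config(
    n_per_arm = c(sequential = 120, simultaneous = 120, control = 120),
    seed = 37, quarterly_dropout_hazard = 0.25, missing_item_prob = 0)
  trial <- generate_trial(cfg)
  cea <- prepare_cea_data(trial)
  s4 <- analysis_set(cea, scenario(min_followups = 4))
  direct <- cea$participants$id[cea$participants$n_followups >= 4]
  expect_setequal(s4$id, direct)
  s0 <- analysis_set(cea, scenario())
  expect_gt(nrow(s0), nrow(s4))
})

test_that("the scenario suite mirrors the reporting table and is deterministic", {
  cea <- local_cea()
  scs <- default_scenarios("lfs")[c("primary", "no_discounting")]
  t1 <- scenario_suite(cea, scs, n_boot = 100, seed = 3)
  t2 <- scenario_suite(cea, scs, n_boot = 100, seed = 3)
  expect_identical(t1, t2)
  expect_equal(names(t1), c("scenario", "arm", "n",
                            "wtp_0", "wtp_18000", "wtp_80000"))
  expect_equal(nrow(t1), 2 * 3)
  for (w in c("wtp_0", "wtp_18000", "wtp_80000")) {
    sums <- tapply(t1[[w]], t1$scenario, sum)
    expect_equal(as.numeric(sums), rep(1, 2))
  }
})

test_that("identical-arm data put every suite cell near one third", {
  set.seed(61)
  base <- tibble::tibble(id = paste0("x", 1:90),
                         cost = rnorm(90, 4000, 500),
                         effect = rnorm(90, 3.3, 1))
  d <- dplyr::bind_rows(
    dplyr::mutate(base, arm = "sequential", id = paste0(id, "s")),
    dplyr::mutate(base, arm = "simultaneous", id = paste0(id, "m")),
    dplyr::mutate(base, arm = "control", id = paste0(id, "c")))
  r <- ceac(d, wtp_grid = c(0, 18000, 80000), n_boot = 1000, seed = 9)
  pr <- as.matrix(r$probabilities[c("control", "sequential", "simultaneous")])
  expect_true(all(abs(pr - 1 / 3) < 0.06))
})

test_that("scenario files read back into scenario objects", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste(
    "- name: healthcare",
    "  perspective: healthcare",
    "  include_productivity: no",
    "- name: undiscounted",
    "  r_cost: 0",
    "  r_effect: 0", sep = "\n"), path)
  scs <- read_scenarios(path)
  expect_equal(names(scs), c("healthcare", "undiscounted"))
  expect_equal(scs$healthcare$perspective, "healthcare")
  expect_equal(scs$undiscounted$r_cost, 0)
})
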