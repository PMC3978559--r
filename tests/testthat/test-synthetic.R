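test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_per_arm = c(sequential = 60, simultaneous = 60,
                                        control = 60), seed = 99)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1$participants, t2$participants)
  expect_identical(t1$quarters, t2$quarters)
  t3 <- generate_trial(generator_config(
    n_per_arm = c(sequential = 60, simultaneous = 60, control = 60),
    seed = 100))
  expect_false(identical(t1$quarters, t3$quarters))
})

test_that("arm sizes and basic record invariants match the configuration", {
  trial <- generate_trial(quick_config(n = 80, seed = 2))
  counts <- table(trial$participants$arm)
  expect_equal(unname(counts[c("sequential", "simultaneous", "control")]),
               rep(80L, 3), ignore_attr = TRUE)
  q <- trial$quarters
  expect_true(all(q$quarter %in% 0:8))
  expect_true(all(q$absent_days[!is.na(q$absent_days)] <= 90))
  expect_true(all(q$absent_days[!is.na(q$absent_days)] >= 0))
  eq <- as.matrix(q[grep("^eq5d_", names(q))])
  expect_true(all(eq[!is.na(eq)] %in% 1:3))
  ages <- trial$participants$age
  expect_true(all(ages >= 18 & ages <= 65))
})

test_that("invalid configurations name the offending field", {
  expect_error(generator_config(n_per_arm = c(0, 10, 10)), "n_per_arm")
  expect_error(generator_config(baseline_utility_mean = 1.2),
               "baseline_utility_mean")
  expect_error(generator_config(missing_item_prob = 1.5), "missing_item_prob")
  expect_error(generator_config(baseline_lfs_mean = 7), "baseline_lfs_mean")
})

test_that("null arm effects leave 24-month LFS equal up to sampling noise", {
  cfg <- quick_config(
    n = 2000, seed = 31,
    arm_lfs_effect = c(sequential = 0, simultaneous = 0, control = 0))
  trial <- generate_trial(cfg)
  p <- trial$participants
  adh <- adheres(p$pa_days_24, p$fruit_pieces_24, p$veg_grams_24,
                 p$alcohol_glasses_24, p$smoker_24, p$gender)
  lfs24 <- lifestyle_factor_score(adh)
  means <- tapply(lfs24, p$arm, mean)
  se <- sqrt(2) * stats::sd(lfs24) / sqrt(2000)
  expect_lt(max(means) - min(means), 4 * se)
})

test_that("dropout is off with a large negative intercept, and matches the
           configured logistic rate otherwise", {
  complete <- generate_trial(quick_config(n = 120, seed = 8))
  expect_false(anyNA(complete$quarters))
  expect_false(anyNA(complete$participants))

  cfg <- generator_config(
    n_per_arm = c(sequential = 1200, simultaneous = 1200, control = 1200),
    seed = 13,
    dropout_logit_coeffs = c(intercept = stats::qlogis(0.292),
                             age = 0, lfs = 0),
    quarterly_dropout_hazard = 0, missing_item_prob = 0)
  trial <- generate_trial(cfg)
  fup <- trial$quarters[trial$quarters$quarter > 0, ]
  none <- tapply(fup$completed, fup$id, function(x) !any(x))
  rate <- mean(none)
  se <- sqrt(0.292 * 0.708 / 3600)
  expect_lt(abs(rate - 0.292), 4 * se)
})

test_that("negative age and LFS coefficients make dropouts younger and less
           healthy on average", {
  cfg <- generator_config(
    n_per_arm = c(sequential = 1000, simultaneous = 1000, control = 1000),
    seed = 17,
    dropout_logit_coeffs = c(intercept = stats::qlogis(0.3),
                             age = -0.08, lfs = -0.5),
    quarterly_dropout_hazard = 0, missing_item_prob = 0)
  trial <- generate_trial(cfg)
  p <- trial$participants
  fup <- trial$quarters[trial$quarters$quarter > 0, ]
  none <- tapply(fup$completed, factor(fup$id, levels = p$id), function(x) !any(x))
  dropped <- as.logical(none[p$id])
  expect_lt(mean(p$age[dropped]), mean(p$age[!dropped]))
  adh <- adheres(p$pa_days_0, p$fruit_pieces_0, p$veg_grams_0,
                 p$alcohol_glasses_0, p$smoker_0, p$gender)
  lfs0 <- lifestyle_factor_score(adh)
  expect_lt(mean(lfs0[dropped]), mean(lfs0[!dropped]))
})

test_that("attrition is monotone and item missingness only hits follow-ups", {
  cfg <- generator_config(
    n_per_arm = c(sequential = 150, simultaneous = 150, control = 150),
    seed = 23)
  trial <- generate_trial(cfg)
  q <- trial$quarters
  base <- q[q$quarter == 0, ]
  expect_false(anyNA(base[setdiff(names(base), "completed")]))
  by_id <- split(q[q$quarter > 0, ], q$id[q$quarter > 0])
  for (d in by_id[1:50]) {
    comp <- d$completed[order(d$quarter)]
    # once a questionnaire is missed, all later ones are missed too
    expect_true(all(diff(comp) <= 0))
  }
})

test_that("generated quarterly cost components are right-skewed", {
  trial <- generate_trial(quick_config(n = 300, seed = 41))
  fup <- trial$quarters[trial$quarters$quarter > 0, ]
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  for (v in c("medication", "services", "admission_days", "other_care",
              "absent_days")) {
    expect_gt(skew(fup[[v]]), 0)
    expect_true(all(fup[[v]] >= 0))
  }
})

test_that("baseline utilities reproduce the configured ceiling effect", {
  trial <- generate_trial(quick_config(n = 700, seed = 51))
  q0 <- trial$quarters[trial$quarters$quarter == 0, ]
  u <- eq5d_utility(q0[paste0("eq5d_", c("mobility", "selfcare", "activity",
                                         "pain", "anxiety"))])
  expect_equal(mean(u), 0.89, tolerance = 0.01)
})

test_that("trial data round-trips through the CSV writer", {
  trial <- generate_trial(quick_config(n = 25, seed = 3))
  dir <- withr::local_tempdir()
  write_trial_csv(trial, dir)
  back <- read_trial_csv(dir)
  expect_equal(as.data.frame(back$participants),
               as.data.frame(trial$participants))
  expect_equal(as.data.frame(back$quarters), as.data.frame(trial$quarters))
})
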