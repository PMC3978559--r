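seq_agg <- list(arm = "sequential", mean_cost = 4324.76, mean_effect = 3.38)
sim_agg <- list(arm = "simultaneous", mean_cost = 5009.00, mean_effect = 3.42)
con_agg <- list(arm = "control", mean_cost = 4141.00, mean_effect = 3.34)

test_that("incremental ratios follow delta-cost over delta-effect", {
  r <- incremental(seq_agg, con_agg)
  expect_equal(r$delta_cost, 183.76)
  expect_equal(r$delta_effect, 0.04)
  expect_equal(r$icer_rounded, 4594.00)
  r2 <- incremental(sim_agg, con_agg)
  expect_equal(r2$icer_rounded, 10850.00)
  # both deltas negative is still a tradeoff (price per unit forgone)
  r3 <- incremental(seq_agg, sim_agg)
  expect_equal(r3$delta_cost, -684.24)
  expect_equal(r3$icer_rounded, 17106.00)
  expect_equal(c(r$label, r2$label, r3$label), rep("tradeoff", 3))
})

test_that("dominance labels cover higher-cost-lower-effect and its mirror", {
  a <- list(arm = "a", mean_cost = 1100, mean_effect = 1.5)
  b <- list(arm = "b", mean_cost = 1000, mean_effect = 1.6)
  expect_equal(incremental(a, b)$label, "dominated")
  expect_equal(incremental(b, a)$label, "dominant")
  expect_true(is.na(incremental(a, b)$icer))
})

test_that("equal effects with unequal costs yield an undefined ICER, not Inf", {
  a <- list(arm = "a", mean_cost = 1100, mean_effect = 2)
  b <- list(arm = "b", mean_cost = 1000, mean_effect = 2)
  r <- incremental(a, b)
  expect_equal(r$label, "icer undefined")
  expect_true(is.na(r$icer))
  expect_equal(incremental(a, a)$label, "equivalent")
})

test_that("incremental is antisymmetric", {
  set.seed(5)
  for (i in 1:20) {
    a <- list(arm = "a", mean_cost = runif(1, 0, 5000),
              mean_effect = runif(1, -1, 4))
    b <- list(arm = "b", mean_cost = runif(1, 0, 5000),
              mean_effect = runif(1, -1, 4))
    ab <- incremental(a, b)
    ba <- incremental(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_effect, -ba$delta_effect)
    if (ab$label == "tradeoff") expect_equal(ab$icer, ba$icer)
    if (ab$label == "dominated") expect_equal(ba$label, "dominant")
  }
})

test_that("net monetary benefit is wtp x effect - cost", {
  expect_equal(nmb(4000, 2, 18000), 32000)
  expect_equal(nmb(c(100, 200), c(1, 1), 0), c(-100, -200))
  # equal effects: NMB ordering is the reverse of cost ordering at any wtp
  for (w in c(0, 500, 80000)) {
    v <- nmb(c(100, 200, 300), rep(1.3, 3), w)
    expect_equal(order(v), rev(order(c(100, 200, 300))))
  }
  expect_error(nmb(1, 1, -5), "wtp")
})

test_that("stratified bootstrap is reproducible and respects arm sizes", {
  d <- toy_arms(40, c(1000, 1200, 900), c(1, 1.2, 0.9), seed = 2)
  stat <- function(x) {
    m <- tapply(x$cost, x$arm, mean)
    c(diff_ab = m[["a"]] - m[["b"]])
  }
  b1 <- bootstrap_arms(d, stat, n_boot = 50, seed = 7)
  b2 <- bootstrap_arms(d, stat, n_boot = 50, seed = 7)
  expect_identical(b1$draws, b2$draws)
  expect_equal(dim(b1$draws), c(50L, 1L))
  expect_true(b1$ci[1, 1] <= b1$ci[1, 2])
})

test_that("degenerate data give a zero-width bootstrap interval", {
  d <- tibble::tibble(id = 1:20, arm = rep(c("a", "b"), each = 10),
                      cost = rep(c(100, 200), each = 10),
                      effect = rep(c(1, 2), each = 10))
  b <- bootstrap_arms(d, function(x) mean(x$cost[x$arm == "a"]),
                      n_boot = 30, seed = 1)
  expect_equal(unname(b$ci[1, 1]), unname(b$ci[1, 2]))
  expect_error(bootstrap_arms(d[d$arm == "a", ][0, ], mean, 10, 1), "arm")
})

test_that("the percentile CI of an arm mean covers the sample mean", {
  d <- toy_arms(200, c(1000, 1000, 1000), c(1, 1, 1), sd_cost = 300, seed = 9)
  b <- bootstrap_arms(d, function(x) mean(x$cost[x$arm == "a"]),
                      n_boot = 500, seed = 3)
  m <- mean(d$cost[d$arm == "a"])
  expect_true(b$ci[1, 1] <= m && m <= b$ci[1, 2])
})

test_that("CEAC probabilities sum to one and split ties equally", {
  d <- toy_arms(50, c(1000, 1050, 980), c(1.1, 1.3, 1.0), seed = 4)
  r <- ceac(d, wtp_grid = seq(0, 80000, by = 5000), n_boot = 300, seed = 11)
  pr <- r$probabilities
  sums <- rowSums(pr[setdiff(names(pr), "wtp")])
  expect_equal(sums, rep(1, nrow(pr)))
  expect_true(all(pr$a >= 0 & pr$a <= 1))
  # exact ties: identical duplicated participants in each arm
  base <- tibble::tibble(id = 1:30, cost = rep(c(900, 1000, 1100), 10),
                         effect = rep(c(0.9, 1.0, 1.1), 10))
  tied <- dplyr::bind_rows(
    dplyr::mutate(base, arm = "a"),
    dplyr::mutate(base, arm = "b"))
  rt <- ceac(tied, wtp_grid = c(0, 18000), n_boot = 100, seed = 1)
  expect_equal(rowSums(rt$probabilities[c("a", "b")]), c(1, 1))
})

test_that("a strictly dominant arm wins almost surely at every wtp", {
  d <- toy_arms(60, c(500, 2000, 2000), c(2.0, 1.0, 1.0),
                sd_cost = 50, sd_effect = 0.05, seed = 6)
  r <- ceac(d, wtp_grid = seq(0, 80000, by = 10000), n_boot = 500, seed = 2)
  expect_true(all(r$probabilities$a > 0.95))
})

test_that("as wtp grows the winner is the arm with the highest mean effect", {
  d <- toy_arms(80, c(1000, 1000, 1000), c(1.0, 1.5, 2.0),
                sd_effect = 0.2, seed = 8)
  r <- ceac(d, wtp_grid = c(0, 80000), n_boot = 400, seed = 5)
  top <- r$probabilities[r$probabilities$wtp == 80000, ]
  expect_gt(top$c, 0.95)
})
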