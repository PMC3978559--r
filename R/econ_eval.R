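#' Per-arm cost and effect aggregates
#'
#' @param data Participant-level tibble with columns `arm`, `cost`, `effect`
#'   (an [analysis_set()] output), plus optional component columns.
#' @return Tibble: `arm`, `n`, `mean_cost`, `mean_effect` and per-component
#'   means where components are present.
#' @export
arm_aggregates <- function(data) {
  stopifnot(all(c("arm", "cost", "effect") %in% names(data)))
  extra <- setdiff(names(data), c("id", "arm", "cost", "effect"))
  dplyr::summarise(
    dplyr::group_by(data, .data$arm),
    n = dplyr::n(),
    mean_cost = mean(.data$cost),
    mean_effect = mean(.data$effect),
    dplyr::across(dplyr::all_of(extra), mean),
    .groups = "drop")
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Incremental cost-effectiveness with dominance classification
#'
#' Computes the incremental cost and effect of arm `a` over arm `b` and
#' classifies the comparison:
#'
#' * `dominated` - `a` costs more and is less effective (ICER meaningless);
#' * `dominant` - `a` costs less and is more effective;
#' * `tradeoff` - costs and effects move in the same direction, so the
#'   ICER, delta-cost / delta-effect, is the price per unit of effect;
#' * `icer undefined` - equal effects with unequal costs (no finite ratio);
#' * `equivalent` - equal costs and effects.
#'
#' ICERs are computed at full precision; `icer_rounded` reports the
#' conventional 2-decimal half-up rounding.
#'
#' @param a,b One-row aggregates (from [arm_aggregates()]), or lists with
#'   `arm`, `mean_cost`, `mean_effect`.
#' @return One-row tibble: `comparison`, `delta_cost`, `delta_effect`,
#'   `icer`, `icer_rounded`, `label`.
#' @examples
#' s <- list(arm = "sequential", mean_cost = 4324.76, mean_effect = 3.38)
#' c0 <- list(arm = "control", mean_cost = 4141.00, mean_effect = 3.34)
#' incremental(s, c0) # delta 183.76 / 0.04, ICER 4594
#' @export
incremental <- function(a, b) {
  dc <- a$mean_cost - b$mean_cost
  de <- a$mean_effect - b$mean_effect
  if (dc > 0 && de < 0) {
    label <- "dominated"; icer <- NA_real_
  } else if (dc < 0 && de > 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (de == 0) {
    label <- if (dc == 0) "equivalent" else "icer undefined"
    icer <- NA_real_
  } else {
    label <- "tradeoff"; icer <- dc / de
  }
  tibble::tibble(
    comparison = paste(a$arm, "vs", b$arm),
    delta_cost = dc, delta_effect = de,
    icer = icer, icer_rounded = round_half_up(icer, 2),
    label = label
  )
}

#' All pairwise incremental comparisons between arms
#'
#' @param aggregates An [arm_aggregates()] tibble.
#' @param order Arm ordering; each arm is compared to every later one.
#' @return Tibble of [incremental()] rows.
#' @export
incremental_table <- function(aggregates,
                              order = c("sequential", "simultaneous",
                                        "control")) {
  arms <- intersect(order, aggregates$arm)
  rows <- list()
  for (i in seq_along(arms)) {
    for (j in seq_along(arms)) {
      if (i < j) {
        a <- aggregates[aggregates$arm == arms[i], ]
        b <- aggregates[aggregates$arm == arms[j], ]
        rows[[length(rows) + 1L]] <- incremental(a, b)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Net monetary benefit
#'
#' `NMB = wtp x effect - cost`: the monetary value of the effect at the
#' willingness-to-pay threshold, net of cost.
#'
#' @param cost,effect Numeric (vectorised).
#' @param wtp Willingness to pay per unit of effect, euros (nonnegative).
#' @return Euro NMB.
#' @export
nmb <- function(cost, effect, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * effect - cost
}

#' Stratified nonparametric bootstrap over trial arms
#'
#' Resamples participants with replacement *within each arm* (preserving the
#' randomized arm sizes) and recomputes a statistic per replicate.
#'
#' @param data Participant-level tibble with an `arm` column.
#' @param statistic Function of a resampled data tibble returning a numeric
#'   vector (possibly named).
#' @param n_boot Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return List: `draws` (n_boot x length(statistic) matrix), `ci`
#'   (percentile bounds per statistic), `n_boot`, `seed`.
#' @export
bootstrap_arms <- function(data, statistic, n_boot = 1000, seed = 1,
                           conf = 0.95) {
  stopifnot(n_boot >= 1, "arm" %in% names(data))
  if (nrow(data) == 0) stop("every arm must be nonempty")
  arms <- split(seq_len(nrow(data)), data$arm)
  if (any(lengths(arms) == 0)) stop("every arm must be nonempty")
  set.seed(seed)
  draws <- NULL
  for (r in seq_len(n_boot)) {
    idx <- unlist(lapply(arms, function(i) i[sample.int(length(i),
                                                        replace = TRUE)]),
                  use.names = FALSE)
    s <- statistic(data[idx, , drop = FALSE])
    if (is.null(draws)) {
      draws <- matrix(NA_real_, nrow = n_boot, ncol = length(s),
                      dimnames = list(NULL, names(s)))
    }
    draws[r, ] <- s
  }
  alpha <- (1 - conf) / 2
  ci <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  list(draws = draws, ci = t(ci), n_boot = n_boot, seed = seed)
}

# Bootstrap replicate means of cost and effect per arm, vectorised:
# returns list of n_boot x n_arms matrices `cost` and `effect`.
boot_arm_means <- function(data, n_boot, seed) {
  arms <- sort(unique(data$arm))
  set.seed(seed)
  cost <- effect <- matrix(NA_real_, nrow = n_boot, ncol = length(arms),
                           dimnames = list(NULL, arms))
  for (a in arms) {
    rows <- which(data$arm == a)
    n <- length(rows)
    if (n == 0) stop("every arm must be nonempty")
    idx <- matrix(rows[sample.int(n, n * n_boot, replace = TRUE)],
                  nrow = n_boot)
    cm <- matrix(data$cost[idx], nrow = n_boot)
    em <- matrix(data$effect[idx], nrow = n_boot)
    cost[, a] <- rowMeans(cm)
    effect[, a] <- rowMeans(em)
  }
  list(cost = cost, effect = effect, arms = arms)
}

#' Cost-effectiveness acceptability curves for a multi-arm trial
#'
#' For each bootstrap replicate (stratified within-arm resampling) and each
#' willingness-to-pay value, the arm with the highest replicate-mean net
#' monetary benefit wins; ties split the win equally so probabilities sum to
#' exactly 1 at every grid point.
#'
#' @param data Participant-level tibble with `arm`, `cost`, `effect`.
#' @param wtp_grid Willingness-to-pay grid, euros (default 0 to 80,000 in
#'   steps of 1,000).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param keep_draws Keep the replicate mean-cost/effect matrices.
#' @return A `ceac_result`: tibble `probabilities` (`wtp`, one probability
#'   column per arm), plus `n_boot`, `seed` and optionally `draws`.
#' @export
ceac <- function(data, wtp_grid = seq(0, 80000, by = 1000), n_boot = 1000,
                 seed = 1, keep_draws = FALSE) {
  stopifnot(all(c("arm", "cost", "effect") %in% names(data)),
            length(unique(data$arm)) >= 2)
  bm <- boot_arm_means(data, n_boot, seed)
  probs <- matrix(NA_real_, nrow = length(wtp_grid), ncol = length(bm$arms),
                  dimnames = list(NULL, bm$arms))
  for (k in seq_along(wtp_grid)) {
    benefit <- wtp_grid[k] * bm$effect - bm$cost
    best <- apply(benefit, 1, max)
    wins <- benefit == best
    wins <- wins / rowSums(wins)          # split ties equally
    probs[k, ] <- colMeans(wins)
  }
  out <- tibble::as_tibble(probs)
  out <- dplyr::bind_cols(tibble::tibble(wtp = wtp_grid), out)
  structure(list(probabilities = out, n_boot = n_boot, seed = seed,
                 draws = if (keep_draws) bm else NULL),
            class = "ceac_result")
}

#' @export
print.ceac_result <- function(x, ...) {
  cat("<ceac_result>", x$n_boot, "bootstrap replicates, seed", x$seed, "\n")
  print(x$probabilities, n = 6)
  invisible(x)
}
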