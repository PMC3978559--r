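#' Single-imputation cascade for a longitudinal series
#'
#' Fills missing entries in an ordered measurement series (e.g. one variable
#' across quarters 0..8 for one participant) using, in order of preference:
#'
#' * neighbour mean - an interior gap of exactly one point is filled with the
#'   mean of the flanking observed values;
#' * last observation carried forward (LOCF) - runs not bracketed by an
#'   observation on both sides, and interior gaps longer than one point, are
#'   filled from the last observed value to the left;
#' * next observation carried backward (NOCB) - leading gaps (no observation
#'   to the left, e.g. a missing baseline) are filled from the first observed
#'   value to the right.
#'
#' @param values Numeric vector in time order, with `NA` for missing.
#' @return The completed vector. Errors if every entry is missing (such a
#'   series is handled at the participant level by the inclusion rule).
#' @examples
#' impute_series(c(5, NA, 7))   # 5 6 7
#' impute_series(c(NA, 4, 4))   # 4 4 4
#' impute_series(c(3, NA, NA))  # 3 3 3
#' @export
impute_series <- function(values) {
  obs <- which(!is.na(values))
  if (length(obs) == 0L) stop("fully missing series cannot be imputed")
  out <- values
  miss <- which(is.na(values))
  for (i in miss) {
    left <- obs[obs < i]
    right <- obs[obs > i]
    left_i <- if (length(left)) max(left) else NA_integer_
    right_i <- if (length(right)) min(right) else NA_integer_
    if (!is.na(left_i) && !is.na(right_i) && right_i - left_i == 2L) {
      out[i] <- (values[left_i] + values[right_i]) / 2   # single interior gap
    } else if (!is.na(left_i)) {
      out[i] <- values[left_i]                           # LOCF
    } else {
      out[i] <- values[right_i]                          # NOCB
    }
  }
  out
}

#' Truncate implausible values to their upper bound
#'
#' Values above a variable's plausibility bound are recoded to the highest
#' possible value (e.g. more than 90 absenteeism days reported for a 90-day
#' quarter become 90). Negative quantities are rejected as data errors rather
#' than truncated.
#'
#' @param value Numeric vector.
#' @param upper Upper plausibility bound.
#' @return `pmin(value, upper)`, with `NA`s passed through.
#' @examples
#' truncate_implausible(120, 90) # 90
#' @export
truncate_implausible <- function(value, upper) {
  if (any(!is.na(value) & value < 0)) {
    stop("negative quantities are data errors, not truncatable values")
  }
  pmin(value, upper)
}

#' Default plausibility bounds per quarterly variable
#'
#' Absenteeism is capped at 90 days per 90-day quarter; other resource counts
#' get loose sanity caps.
#'
#' @return Named numeric vector of upper bounds.
#' @export
default_bounds <- function() {
  c(absent_days = 90, medication = 1000, services = 90, admission_days = 90,
    other_care = 1000, travel_trips = 90)
}

#' Impute unclear monetary answers with the study-group mean
#'
#' Free-text answers that cannot be valued (flagged `NA` with
#' `unclear = TRUE`) are replaced by the mean of the valid values for the
#' same question within the participant's study group. If a group has no
#' valid entry the overall mean is used (and flagged in the report).
#'
#' @param value Numeric vector with `NA` at unclear entries.
#' @param group Factor/character of study-group membership, same length.
#' @return List with `value` (completed vector) and `fallback` (logical: was
#'   the overall mean needed).
#' @examples
#' impute_category_mean(c(10, 20, NA), c("a", "a", "a"))$value # 10 20 15
#' @export
impute_category_mean <- function(value, group) {
  stopifnot(length(value) == length(group))
  out <- value
  fallback <- FALSE
  overall <- mean(value, na.rm = TRUE)
  if (is.nan(overall)) stop("no valid entries at all for this question")
  for (g in unique(group[is.na(value)])) {
    sel <- group == g
    m <- mean(value[sel], na.rm = TRUE)
    if (is.nan(m)) {
      m <- overall
      fallback <- TRUE
    }
    out[sel & is.na(value)] <- m
  }
  list(value = out, fallback = fallback)
}

#' Inclusion rule for the economic analysis
#'
#' Participants enter the analysis only when their baseline LFS is available
#' and the baseline economic questionnaire was completed.
#'
#' @param participants Tibble with a logical `baseline_lfs_available` column
#'   (or a `lfs_baseline` column, where `NA` means unavailable) and a logical
#'   `baseline_econ_completed` column.
#' @return List with `included` (the retained rows), `excluded` (the rest)
#'   and `report` (a one-row tibble of counts).
#' @export
inclusion_filter <- function(participants) {
  has_lfs <- if ("baseline_lfs_available" %in% names(participants)) {
    participants$baseline_lfs_available
  } else if ("lfs_baseline" %in% names(participants)) {
    !is.na(participants$lfs_baseline)
  } else {
    stop("no baseline LFS availability column found")
  }
  has_econ <- if ("baseline_econ_completed" %in% names(participants)) {
    participants$baseline_econ_completed
  } else {
    rep(TRUE, nrow(participants))
  }
  keep <- has_lfs & has_econ
  list(
    included = participants[keep, , drop = FALSE],
    excluded = participants[!keep, , drop = FALSE],
    report = tibble::tibble(
      n_total = nrow(participants),
      n_included = sum(keep),
      n_missing_baseline_lfs = sum(!has_lfs),
      n_missing_baseline_econ = sum(!has_econ)
    )
  )
}

#' Apply the full missing-data cascade to a trial dataset
#'
#' Order of operations is fixed: plausibility truncation first (observed
#' implausible values must be truncated before they can be carried into
#' gaps), then the per-series imputation cascade for every quarterly variable
#' of every participant (quarters 0..8). EQ-5D items are imputed per
#' dimension on the 1-3 level scale and re-scored afterwards; imputed levels
#' are rounded to the nearest integer level (half away from zero).
#'
#' Participants whose series for a variable is entirely missing keep it
#' missing; downstream statistics drop them listwise for that outcome, which
#' is why cost and effect Ns can differ.
#'
#' @param quarters Tibble, one row per participant-quarter (`id`, `quarter`
#'   0..8, resource-use columns, `eq5d_*` level columns).
#' @param bounds Named upper bounds per variable (see [default_bounds()]).
#' @return List with `quarters` (completed tibble) and `report` (counts of
#'   truncated and imputed cells per variable).
#' @export
impute_trial <- function(quarters, bounds = default_bounds()) {
  q <- dplyr::arrange(quarters, .data$id, .data$quarter)
  eq_cols <- grep("^eq5d_", names(q), value = TRUE)
  num_cols <- setdiff(names(q)[vapply(q, is.numeric, logical(1))],
                      c("id", "quarter", eq_cols))

  truncated <- stats::setNames(integer(length(num_cols) + length(eq_cols)),
                               c(num_cols, eq_cols))
  for (v in intersect(num_cols, names(bounds))) {
    n_over <- sum(!is.na(q[[v]]) & q[[v]] > bounds[[v]])
    truncated[v] <- n_over
    q[[v]] <- truncate_implausible(q[[v]], bounds[[v]])
  }

  impute_col <- function(x, id, integer_levels = FALSE) {
    before <- is.na(x)
    grouped <- unlist(lapply(split(x, id), function(s) {
      if (all(is.na(s))) s else impute_series(s)
    }), use.names = FALSE)
    # split() orders rows by id level; scatter back to the original order
    out <- x
    out[order(id)] <- grouped
    if (integer_levels) {
      filled <- before & !is.na(out)
      out[filled] <- pmin(pmax(floor(out[filled] + 0.5), 1), 3)
    }
    out
  }

  id_f <- factor(q$id, levels = unique(q$id))
  imputed <- integer(0)
  still <- integer(0)
  for (v in c(num_cols, eq_cols)) {
    n_before <- sum(is.na(q[[v]]))
    q[[v]] <- impute_col(q[[v]], id_f, integer_levels = v %in% eq_cols)
    imputed[v] <- n_before - sum(is.na(q[[v]]))
    still[v] <- sum(is.na(q[[v]]))
  }

  list(
    quarters = q,
    report = tibble::tibble(
      variable = c(num_cols, eq_cols),
      truncated = unname(truncated[c(num_cols, eq_cols)]),
      imputed = unname(imputed[c(num_cols, eq_cols)]),
      still_missing = unname(still[c(num_cols, eq_cols)])
    )
  )
}
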