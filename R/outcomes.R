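#' Public-health lifestyle guidelines
#'
#' The five Dutch public-health guidelines behind the lifestyle factor score:
#' moderate physical activity of at least 30 minutes on at least `pa_min_days`
#' days per week, at least `fruit_min_pieces` pieces of fruit per day, at
#' least `veg_min_grams` grams of vegetables per day, at most
#' `alcohol_max_female` / `alcohol_max_male` glasses of alcohol per day, and
#' not smoking.
#'
#' Boundary values count as adherent: the guidelines read "at least" for the
#' minima and "not more than" for the alcohol maximum.
#'
#' @param pa_min_days Days per week of >=30-minute moderate activity (default 5).
#' @param fruit_min_pieces Pieces of fruit per day (default 2).
#' @param veg_min_grams Grams of vegetables per day (default 200).
#' @param alcohol_max_female,alcohol_max_male Maximum glasses of alcohol per
#'   day by gender (defaults 1 and 2).
#' @return A `guideline_set` list.
#' @export
guideline_set <- function(pa_min_days = 5, fruit_min_pieces = 2,
                          veg_min_grams = 200, alcohol_max_female = 1,
                          alcohol_max_male = 2) {
  stopifnot(pa_min_days > 0, fruit_min_pieces > 0, veg_min_grams > 0,
            alcohol_max_female >= 0, alcohol_max_male >= 0,
            alcohol_max_female <= alcohol_max_male)
  structure(list(pa_min_days = pa_min_days,
                 fruit_min_pieces = fruit_min_pieces,
                 veg_min_grams = veg_min_grams,
                 alcohol_max_female = alcohol_max_female,
                 alcohol_max_male = alcohol_max_male),
            class = "guideline_set")
}

#' Guideline adherence from behaviour measurements
#'
#' Vectorised over participants. Behaviours are on their natural scales:
#' activity days/week, fruit pieces/day, vegetable grams/day, alcohol
#' glasses/day, and a smoker flag. A missing behaviour yields a missing
#' adherence for that guideline (which propagates to a missing LFS).
#'
#' @param pa_days,fruit_pieces,veg_grams,alcohol_glasses Numeric vectors,
#'   nonnegative where observed.
#' @param smoker Logical vector.
#' @param gender Character vector, `"male"` or `"female"` (alcohol limit is
#'   gender-specific).
#' @param guidelines A [guideline_set()].
#' @return A tibble with logical columns `pa`, `fruit`, `veg`, `alcohol`,
#'   `nonsmoking`.
#' @examples
#' adheres(5, 2, 200, 1, FALSE, "female") # all TRUE (boundaries adhere)
#' @export
adheres <- function(pa_days, fruit_pieces, veg_grams, alcohol_glasses,
                    smoker, gender, guidelines = guideline_set()) {
  stopifnot(inherits(guidelines, "guideline_set"))
  gender <- match_gender(gender)
  neg <- function(x) any(!is.na(x) & x < 0)
  if (neg(pa_days) || neg(fruit_pieces) || neg(veg_grams) || neg(alcohol_glasses)) {
    stop("behaviour values must be nonnegative")
  }
  limit <- ifelse(gender == "female", guidelines$alcohol_max_female,
                  guidelines$alcohol_max_male)
  tibble::tibble(
    pa         = pa_days >= guidelines$pa_min_days,
    fruit      = fruit_pieces >= guidelines$fruit_min_pieces,
    veg        = veg_grams >= guidelines$veg_min_grams,
    alcohol    = alcohol_glasses <= limit,
    nonsmoking = !smoker
  )
}

match_gender <- function(gender) {
  g <- match.arg(tolower(as.character(gender)), c("male", "female"),
                 several.ok = TRUE)
  if (length(g) != length(gender)) g <- rep_len(g, length(gender))
  g
}

#' Lifestyle factor score (LFS)
#'
#' The LFS counts the public-health guidelines a participant adheres to
#' (0-5). Any missing adherence makes the score missing.
#'
#' @param adherence A tibble/data frame of 5 logical adherence columns (as
#'   returned by [adheres()]), or a logical vector of length 5.
#' @return Integer vector of scores in 0..5 (NA where any input is NA).
#' @export
lifestyle_factor_score <- function(adherence) {
  m <- if (is.data.frame(adherence)) as.matrix(adherence) else matrix(adherence, nrow = 1)
  if (ncol(m) != 5L) stop("the LFS is built from exactly 5 guideline adherences")
  out <- rowSums(m)
  as.integer(ifelse(is.na(out), NA, out))
}

#' Lifestyle outcomes for a set of participants
#'
#' Combines baseline and 24-month adherence into the LFS at both time points,
#' the discounted 24-month LFS (divided by `1 + r_effect`, since the score is
#' observed in the second study year), and the lifestyle factor change index
#' LFCI = LFS(24m) - LFS(baseline).
#'
#' @param baseline,followup Tibbles of adherence columns per participant.
#' @param r_effect Annual discount rate for effects (default 0.015).
#' @return A tibble with columns `lfs_baseline`, `lfs_24m_raw`,
#'   `lfs_24m_discounted`, `lfci`.
#' @export
lfs_outcomes <- function(baseline, followup, r_effect = 0.015) {
  b <- lifestyle_factor_score(baseline)
  f <- lifestyle_factor_score(followup)
  tibble::tibble(
    lfs_baseline = b,
    lfs_24m_raw = f,
    lfs_24m_discounted = f / (1 + r_effect),
    lfci = f - b
  )
}

#' Discounted QALYs by the area-under-the-curve method
#'
#' Integrates a utility trajectory over the 24-month study window. Time is in
#' months; the area is returned in years (quality-adjusted life years).
#' Segments lying in the second study year (both endpoints at months > 12)
#' are discounted by `1/(1 + r_effect)`; the month-12 point itself anchors
#' year 1, so the segment spanning months 12-15 is discounted.
#'
#' `method = "trapezoid"` (default) joins consecutive utility points
#' linearly; `"rectangle"` carries each utility forward to the next point.
#' Both reduce to duration x quality weight when utility is constant.
#'
#' @param times Numeric vector of measurement times in months, strictly
#'   increasing, starting at 0.
#' @param utilities Utility at each time; no missing values (impute first).
#' @param r_effect Annual discount rate for effects (default 0.015).
#' @param method `"trapezoid"` or `"rectangle"`.
#' @return Discounted QALYs (scalar).
#' @examples
#' qaly_auc(seq(0, 24, by = 3), rep(1, 9), r_effect = 0)     # 2
#' qaly_auc(seq(0, 24, by = 3), rep(1, 9), r_effect = 0.015) # 1 + 1/1.015
#' @export
qaly_auc <- function(times, utilities, r_effect = 0.015,
                     method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  if (length(times) != length(utilities) || length(times) < 2L) {
    stop("times and utilities must align, with at least two points")
  }
  if (anyNA(utilities) || anyNA(times)) {
    stop("utility trajectory contains missing values; impute before scoring")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  dt <- diff(times) / 12   # years
  seg <- if (method == "trapezoid") {
    (utilities[-length(utilities)] + utilities[-1]) / 2 * dt
  } else {
    utilities[-length(utilities)] * dt
  }
  year2 <- times[-length(times)] >= 12 & times[-1] > 12
  sum(seg * ifelse(year2, 1 / (1 + r_effect), 1))
}
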