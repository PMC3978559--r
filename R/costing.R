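#' Consumer price index series
#'
#' Used to index historical unit prices to the study's reference price year.
#' `cpi_series_nl()` ships the Dutch CPI values for 2009-2013 with reference
#' year 2013 (105.38, 106.72, 109.22, 111.90, 115.00).
#'
#' @param index Named numeric vector of CPI values, names are years.
#' @param reference_year Year all prices are indexed to.
#' @return A `cpi_series` object.
#' @export
cpi_series <- function(index, reference_year) {
  stopifnot(all(index > 0), !is.null(names(index)))
  years <- as.integer(names(index))
  if (!reference_year %in% years) stop("reference year missing from CPI series")
  structure(list(index = stats::setNames(as.numeric(index), years),
                 reference_year = as.integer(reference_year)),
            class = "cpi_series")
}

#' @rdname cpi_series
#' @export
cpi_series_nl <- function() {
  cpi_series(c("2009" = 105.38, "2010" = 106.72, "2011" = 109.22,
               "2012" = 111.90, "2013" = 115.00),
             reference_year = 2013)
}

#' Index an amount to the reference price year
#'
#' `amount * index(reference_year) / index(from_year)`.
#'
#' @param amount Euro amount(s).
#' @param from_year Price year(s) of `amount`.
#' @param cpi A [cpi_series()].
#' @return Indexed euro amount(s).
#' @examples
#' index_cost(100, 2009, cpi_series_nl()) # 100 * 115.00 / 105.38
#' @export
index_cost <- function(amount, from_year, cpi = cpi_series_nl()) {
  stopifnot(inherits(cpi, "cpi_series"))
  key <- as.character(from_year)
  if (any(!key %in% names(cpi$index))) {
    stop("year(s) missing from CPI series: ",
         paste(unique(from_year[!key %in% names(cpi$index)]), collapse = ", "))
  }
  amount * cpi$index[[as.character(cpi$reference_year)]] / unname(cpi$index[key])
}

#' Unit-cost table
#'
#' Collects everything needed to value resource use in euros: unit prices per
#' resource category (each with its own price year), an hourly wage table by
#' gender and age band (for the human capital method and for respondent time),
#' travel constants, per-arm intervention time, and the fixed per-participant
#' hosting cost of the web intervention.
#'
#' `default_unit_costs()` returns a round-number fixture table (price year
#' 2013) suitable for tests and synthetic-data analyses; real analyses supply
#' prices from the applicable costing manual via [read_unit_costs()].
#'
#' @param prices Tibble with columns `category`, `unit`, `price`,
#'   `price_year`.
#' @param wages Tibble with columns `gender`, `age_min`, `age_max`,
#'   `cost_per_hour`, `price_year`; age bands are half-open,
#'   `age_min <= age < age_max`.
#' @param km_per_visit Average one-way travel distance to a health care
#'   service, km.
#' @param price_per_km Euro per km travelled.
#' @param travel_price_year Price year of the travel constants.
#' @param intervention_time_minutes Named numeric: minutes each arm spends on
#'   the web intervention (defaults 70 sequential / 100 simultaneous /
#'   20 control).
#' @param hosting_cost Fixed hosting cost per participant, euros (default
#'   0.54).
#' @param hours_per_workday Hours valued per absenteeism day (default 8).
#' @return A `unit_cost_table`.
#' @export
unit_cost_table <- function(prices, wages,
                            km_per_visit = 3, price_per_km = 0.4,
                            travel_price_year = 2013,
                            intervention_time_minutes = c(sequential = 70,
                                                          simultaneous = 100,
                                                          control = 20),
                            hosting_cost = 0.54,
                            hours_per_workday = 8) {
  stopifnot(all(c("category", "unit", "price", "price_year") %in% names(prices)),
            all(prices$price >= 0),
            all(c("gender", "age_min", "age_max", "cost_per_hour", "price_year")
                %in% names(wages)),
            all(wages$cost_per_hour >= 0),
            km_per_visit >= 0, price_per_km >= 0, hosting_cost >= 0)
  structure(list(prices = tibble::as_tibble(prices),
                 wages = tibble::as_tibble(wages),
                 km_per_visit = km_per_visit,
                 price_per_km = price_per_km,
                 travel_price_year = travel_price_year,
                 intervention_time_minutes = intervention_time_minutes,
                 hosting_cost = hosting_cost,
                 hours_per_workday = hours_per_workday),
            class = "unit_cost_table")
}

#' @rdname unit_cost_table
#' @export
default_unit_costs <- function() {
  prices <- tibble::tibble(
    category   = c("medication", "services", "admissions", "other_care"),
    unit       = c("item", "visit", "day", "hour"),
    price      = c(10, 30, 250, 25),
    price_year = 2013L
  )
  wages <- tidyr::expand_grid(
    gender = c("male", "female"),
    tibble::tibble(age_min = c(18, 40), age_max = c(40, 66))
  )
  wages$cost_per_hour <- 36
  wages$price_year <- 2013L
  unit_cost_table(prices, wages)
}

#' Read a unit-cost table from CSV files
#'
#' @param prices_path CSV with columns `category`, `unit`, `price`,
#'   `price_year`.
#' @param wages_path CSV with columns `gender`, `age_min`, `age_max`,
#'   `cost_per_hour`, `price_year`.
#' @param ... Passed to [unit_cost_table()] (travel constants, intervention
#'   times, hosting cost).
#' @return A `unit_cost_table`.
#' @export
read_unit_costs <- function(prices_path, wages_path, ...) {
  unit_cost_table(
    tibble::as_tibble(utils::read.csv(prices_path, stringsAsFactors = FALSE)),
    tibble::as_tibble(utils::read.csv(wages_path, stringsAsFactors = FALSE)),
    ...
  )
}

lookup_price <- function(unit_costs, category) {
  i <- match(category, unit_costs$prices$category)
  if (anyNA(i)) {
    stop("no unit price for category: ",
         paste(unique(category[is.na(i)]), collapse = ", "))
  }
  unit_costs$prices[i, c("price", "price_year")]
}

lookup_wage <- function(unit_costs, gender, age) {
  w <- unit_costs$wages
  gender <- match_gender(gender)
  out <- numeric(length(gender))
  yr <- integer(length(gender))
  for (k in seq_along(gender)) {
    hit <- which(w$gender == gender[k] & w$age_min <= age[k] & age[k] < w$age_max)
    if (length(hit) == 0L) {
      stop("no wage band for ", gender[k], " aged ", age[k])
    }
    out[k] <- w$cost_per_hour[hit[1]]
    yr[k] <- w$price_year[hit[1]]
  }
  list(cost_per_hour = out, price_year = yr)
}

#' Value health care resource use
#'
#' Multiplies quarterly resource quantities by their unit prices and indexes
#' the result to the reference price year. Medication is valued per described
#' dose unit (tablet, gram or millilitre), health care services per visit,
#' admissions per day, other care per hour.
#'
#' @param quantities Tibble in long form with columns `category` and
#'   `quantity` (nonnegative), plus any id columns, e.g. one row per
#'   participant-quarter-category.
#' @param unit_costs A [unit_cost_table()].
#' @param cpi A [cpi_series()].
#' @return `quantities` with an added `cost` column (indexed euros).
#' @export
value_health_care <- function(quantities, unit_costs, cpi = cpi_series_nl()) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  if (any(!is.na(quantities$quantity) & quantities$quantity < 0)) {
    stop("resource quantities must be nonnegative")
  }
  p <- lookup_price(unit_costs, quantities$category)
  quantities$cost <- index_cost(quantities$quantity * p$price, p$price_year, cpi)
  quantities
}

#' Productivity costs by the human capital method
#'
#' Values absenteeism days at the population mean wage cost for the
#' participant's gender and age band (hourly wage times
#' `hours_per_workday`). Unemployed participants contribute zero. Days must
#' already be truncated to the plausible 0-90 per quarter (see
#' [truncate_implausible()]).
#'
#' @param absent_days Absenteeism days (per quarter), in `[0, 90]`.
#' @param gender,age Participant demographics (vectorised).
#' @param employed Logical; unemployed participants are valued at zero.
#' @param unit_costs A [unit_cost_table()] providing the wage table.
#' @param cpi A [cpi_series()].
#' @return Indexed euro cost(s).
#' @export
productivity_cost <- function(absent_days, gender, age, employed,
                              unit_costs = default_unit_costs(),
                              cpi = cpi_series_nl()) {
  if (any(!is.na(absent_days) & (absent_days < 0 | absent_days > 90))) {
    stop("absenteeism days per quarter must lie in [0, 90] (truncate first)")
  }
  w <- lookup_wage(unit_costs, gender, age)
  raw <- absent_days * w$cost_per_hour * unit_costs$hours_per_workday
  ifelse(employed, index_cost(raw, w$price_year, cpi), 0)
}

#' Respondent costs: intervention time and travel
#'
#' Time cost values the minutes the participant's arm spends on the web
#' intervention at the participant's wage; travel cost values trips to health
#' care services at the configured average distance and price per km.
#'
#' @param arm Arm label(s): `"sequential"`, `"simultaneous"` or `"control"`.
#' @param gender,age Participant demographics.
#' @param travel_trips Number of trips to health care services (biennial or
#'   per quarter, as the caller accumulates).
#' @param unit_costs A [unit_cost_table()].
#' @param cpi A [cpi_series()].
#' @return Tibble with columns `time_cost` and `travel_cost` (indexed euros).
#' @export
respondent_costs <- function(arm, gender, age, travel_trips,
                             unit_costs = default_unit_costs(),
                             cpi = cpi_series_nl()) {
  minutes <- unit_costs$intervention_time_minutes[as.character(arm)]
  if (anyNA(minutes)) {
    stop("no intervention time configured for arm(s): ",
         paste(unique(arm[is.na(minutes)]), collapse = ", "))
  }
  w <- lookup_wage(unit_costs, gender, age)
  tibble::tibble(
    time_cost = index_cost(unname(minutes) / 60 * w$cost_per_hour,
                           w$price_year, cpi),
    travel_cost = index_cost(
      travel_trips * unit_costs$km_per_visit * unit_costs$price_per_km,
      unit_costs$travel_price_year, cpi)
  )
}

#' Discount quarterly amounts over the two-year window
#'
#' Quarters 1-4 (first study year) enter at face value; quarters 5-8 (second
#' year) are divided by `1 + r_cost`.
#'
#' @param amount Amounts aligned with `quarter`.
#' @param quarter Follow-up quarter index 1..8.
#' @param r_cost Annual discount rate for costs (default 0.04).
#' @return Discounted amounts.
#' @export
discount_quarter <- function(amount, quarter, r_cost = 0.04) {
  stopifnot(all(quarter %in% 1:8))
  amount / ifelse(quarter >= 5, 1 + r_cost, 1)
}

#' Total discounted biennial cost per participant
#'
#' Sums a participant's valued quarterly cost components over the 8 follow-up
#' quarters with second-year discounting, then adds the one-off respondent
#' time cost and the fixed hosting cost. All 8 quarters must be present for
#' every component (run the imputation cascade first).
#'
#' @param quarterly Tibble with columns `id`, `quarter` (1..8) and one numeric
#'   column per cost component (already indexed euros), e.g. `medication`,
#'   `services`, `admissions`, `other_care`, `absenteeism`, `travel`.
#' @param once Tibble with columns `id`, `time_cost` (one row per
#'   participant); hosting is added from `unit_costs`.
#' @param unit_costs A [unit_cost_table()] (for the hosting cost).
#' @param r_cost Annual discount rate for costs (default 0.04).
#' @return Tibble, one row per participant: discounted biennial totals per
#'   component plus `hosting`, `time` and `total_discounted`.
#' @export
total_biennial_cost <- function(quarterly, once, unit_costs = default_unit_costs(),
                                r_cost = 0.04) {
  comp_cols <- setdiff(names(quarterly), c("id", "quarter"))
  if (length(comp_cols) == 0L) stop("no cost component columns found")
  counts <- dplyr::count(quarterly, .data$id)
  if (any(counts$n != 8L)) {
    stop("each participant needs exactly 8 follow-up quarters; impute first")
  }
  if (anyNA(quarterly[comp_cols])) {
    stop("missing quarterly cost values; impute first")
  }
  disc <- dplyr::mutate(quarterly, dplyr::across(
    dplyr::all_of(comp_cols), ~ discount_quarter(.x, quarter, r_cost)))
  totals <- dplyr::summarise(dplyr::group_by(disc, .data$id),
                             dplyr::across(dplyr::all_of(comp_cols), sum),
                             .groups = "drop")
  out <- dplyr::left_join(totals, once, by = "id")
  out$hosting <- unit_costs$hosting_cost
  out$total_discounted <- rowSums(out[c(comp_cols, "time_cost", "hosting")])
  out
}
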