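#' ADL/IADL disability category
#'
#' Maps the screener disability measurements to the three-level index:
#' `"nondisabled"` (no ADLs, no IADL), `"IADL only or/and 1-2 ADLs"`, and
#' `"3-6 ADLs"` (which takes precedence regardless of IADL status).
#'
#' @param n_adl Number of ADL limitations (0-6).
#' @param has_iadl Logical; any IADL limitation.
#' @return Character vector of category labels.
#' @export
#' @examples
#' disability_category(0, FALSE)  # nondisabled
#' disability_category(2, FALSE)  # IADL only or/and 1-2 ADLs
#' disability_category(4, TRUE)   # 3-6 ADLs
disability_category <- function(n_adl, has_iadl) {
  if (any(!is.finite(n_adl) | n_adl < 0 | n_adl > 6)) {
    stop("n_adl must lie in 0..6", call. = FALSE)
  }
  ifelse(n_adl >= 3, "3-6 ADLs",
         ifelse(has_iadl | n_adl >= 1, "IADL only or/and 1-2 ADLs",
                "nondisabled"))
}

#' Onset-aligned person-month costs
#'
#' Aggregates one person's CPI-adjusted claim payments into calendar-month
#' bins offset from the onset month (the claim's service month minus the
#' onset month; a claim in the onset's calendar month has `m = 0`),
#' covering `m = -window..window`. Months with no claims while the person
#' is enrolled and alive are real zero-cost months. `at_risk` is `FALSE`
#' for months outside the enrollment span and for months strictly after
#' the death month (the death month itself stays at risk: partial-month
#' outlays are real costs); costs are `NA` when not at risk.
#'
#' @param claims Claims tibble (columns `person_id`, `service_date`,
#'   `paid_amount`, `claim_year`).
#' @param person One-row tibble with `person_id`, `death_date`,
#'   `enrollment_start`, `enrollment_end`.
#' @param onset_date The person's onset date.
#' @param window Half-width in months (default 20, giving 41 bins).
#' @param cpi [cpi_series()] used to express costs in base-year dollars.
#' @return A tibble with columns `person_id`, `m`, `cost`, `at_risk`.
#' @export
person_month_costs <- function(claims, person, onset_date, window = 20,
                               cpi = default_medical_cpi()) {
  onset_mi <- month_index(as.Date(onset_date))
  pc <- claims[claims$person_id == person$person_id, , drop = FALSE]
  pc$m <- month_index(pc$service_date) - onset_mi
  pc <- pc[pc$m >= -window & pc$m <= window, , drop = FALSE]
  sums <- pc |>
    mutate(cost = adjust_to_2000_dollars(paid_amount, claim_year, cpi)) |>
    group_by(m) |>
    summarise(cost = sum(cost), .groups = "drop")
  grid <- tibble(person_id = person$person_id, m = seq(-window, window))
  start_mi <- month_index(person$enrollment_start)
  end_mi <- month_index(person$enrollment_end)
  if (!is.na(person$death_date)) {
    end_mi <- min(end_mi, month_index(person$death_date))
  }
  grid$at_risk <- (grid$m + onset_mi) >= start_mi & (grid$m + onset_mi) <= end_mi
  out <- grid |> left_join(sums, by = "m")
  out$cost <- ifelse(out$at_risk, ifelse(is.na(out$cost), 0, out$cost),
                     NA_real_)
  out
}

#' Person-month costs for a whole cohort
#'
#' Vectorized equivalent of [person_month_costs()] over all cohort
#' members.
#'
#' @param claims Claims tibble.
#' @param persons Person tibble with enrollment and death dates.
#' @param cohort Tibble with `person_id` and `onset_date`.
#' @inheritParams person_month_costs
#' @return Person-month tibble (`person_id`, `m`, `cost`, `at_risk`).
#' @export
cohort_month_costs <- function(claims, persons, cohort, window = 20,
                               cpi = default_medical_cpi()) {
  info <- cohort |>
    select(person_id, onset_date) |>
    left_join(persons |>
                select(person_id, death_date, enrollment_start,
                       enrollment_end),
              by = "person_id") |>
    mutate(onset_mi = month_index(onset_date),
           start_mi = month_index(enrollment_start),
           end_mi = pmin(month_index(enrollment_end),
                         ifelse(is.na(death_date), Inf,
                                month_index(death_date))))
  cc <- claims |>
    filter(person_id %in% info$person_id) |>
    left_join(info |> select(person_id, onset_mi), by = "person_id") |>
    mutate(m = month_index(service_date) - onset_mi) |>
    filter(m >= -window, m <= window) |>
    mutate(cost = adjust_to_2000_dollars(paid_amount, claim_year, cpi)) |>
    group_by(person_id, m) |>
    summarise(cost = sum(cost), .groups = "drop")
  grid <- tidyr::crossing(info |> select(person_id, onset_mi, start_mi,
                                         end_mi),
                          m = seq(-window, window)) |>
    mutate(at_risk = (m + onset_mi) >= start_mi & (m + onset_mi) <= end_mi)
  grid |>
    left_join(cc, by = c("person_id", "m")) |>
    mutate(cost = ifelse(at_risk, ifelse(is.na(cost), 0, cost), NA_real_)) |>
    select(person_id, m, cost, at_risk)
}

#' Build a 41-point trajectory profile
#'
#' Per-month means and standard errors of cost per month per capita over
#' the at-risk persons of a cohort (optionally weighted). The standard
#' error is the sample standard deviation over persons divided by the
#' square root of the at-risk count; months with fewer than two at-risk
#' persons are flagged by `se = NA` and are excluded from weighted fits.
#'
#' @param month_costs Person-month tibble (`person_id`, `m`, `cost`,
#'   `at_risk`) as from [person_month_costs()] for all cohort members.
#' @param disease,stratum Labels attached to the profile.
#' @param weights Optional tibble (`person_id`, `weight`); defaults to
#'   equal weights.
#' @return A profile tibble with columns `disease`, `stratum`, `m`,
#'   `mean`, `se`, `n` (41 rows).
#' @export
build_profile <- function(month_costs, disease = NA_character_,
                          stratum = "total", weights = NULL) {
  if (nrow(month_costs) == 0 || !any(month_costs$at_risk)) {
    stop("empty stratum: no at-risk person-months", call. = FALSE)
  }
  d <- month_costs |> filter(at_risk)
  if (!is.null(weights)) {
    d <- d |> left_join(weights, by = "person_id")
    if (anyNA(d$weight)) stop("missing weights for some persons", call. = FALSE)
  } else {
    d$weight <- 1
  }
  prof <- d |>
    group_by(m) |>
    summarise(
      n = dplyr::n(),
      mean = weighted.mean(cost, weight),
      se = {
        if (dplyr::n() > 1) {
          n_eff <- sum(weight)^2 / sum(weight^2)
          v <- sum(weight * (cost - weighted.mean(cost, weight))^2) /
            sum(weight) * dplyr::n() / (dplyr::n() - 1)
          sqrt(v / n_eff)
        } else NA_real_
      },
      .groups = "drop")
  full <- tibble(m = seq(min(month_costs$m), max(month_costs$m))) |>
    left_join(prof, by = "m") |>
    mutate(n = ifelse(is.na(n), 0L, n))
  full$disease <- disease
  full$stratum <- stratum
  full[, c("disease", "stratum", "m", "mean", "se", "n")]
}

#' Stratify an incident cohort
#'
#' Computes the four stratification variables for each cohort member:
#' Charlson comorbidity category (index over the 12 months before the
#' interview: 0 / 1 / 2 / >2), ADL/IADL disability category, age at
#' diagnosis (at most 80 vs over 80), and survival status 2.5 years
#' (913 days) after onset. Within each variable the levels partition the
#' cohort.
#'
#' @param cohort Onset tibble (`person_id`, `onset_date`).
#' @param persons Person tibble (`person_id`, `birth_date`, `death_date`,
#'   `n_adl`, `has_iadl`).
#' @param claims Claims tibble (for the Charlson index).
#' @param interview_date Interview date anchoring the Charlson lookback.
#' @return A tibble with columns `person_id`, `total`, `disability`,
#'   `charlson`, `age`, `survival`.
#' @export
stratify <- function(cohort, persons, claims, interview_date) {
  p <- cohort |>
    select(person_id, onset_date) |>
    left_join(persons |>
                select(person_id, birth_date, death_date, n_adl, has_iadl),
              by = "person_id")
  ch <- charlson_scores(claims, p$person_id, as.Date(interview_date))
  p |>
    left_join(ch, by = "person_id") |>
    mutate(
      total = "total",
      disability = disability_category(n_adl, has_iadl),
      charlson = charlson_category(charlson),
      age = ifelse(as.numeric(onset_date - birth_date) / 365.25 <= 80,
                   "<=80", ">80"),
      survival = ifelse(!is.na(death_date) &
                          as.numeric(death_date - onset_date) <= 913,
                        "died", "survived")) |>
    select(person_id, total, disability, charlson, age, survival)
}
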