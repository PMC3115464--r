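#' Generating truth for the twelve tracked diseases
#'
#' One row per disease with the four-parameter cost-trajectory quadruple
#' used as generating truth by the synthetic claims generator (the
#' total-population estimates for each disease: pre-onset plateau `c`,
#' onset cost `P`, recovery rate `r`, acquired comorbidity `delta`), the
#' per-month onset hazard, and any sex restriction (breast cancer: women;
#' prostate cancer: men).
#'
#' The default onset hazard is uniform across diseases (0.0012/month,
#' about a 7% five-year cumulative incidence) so that every disease cohort
#' is large enough to support the four-parameter fit at the default
#' population size; it is a simulation design choice, not an empirical
#' incidence rate.
#'
#' @param onset_hazard Per-month onset hazard applied to every disease
#'   (scalar or length-12 vector).
#' @return A tibble with columns `disease`, `name`, `c`, `P`, `r`, `delta`,
#'   `onset_hazard`, `sex_restriction`.
#' @export
#' @examples
#' disease_presets()[, c("disease", "c", "P", "r", "delta")]
disease_presets <- function(onset_hazard = 0.0012) {
  defs <- disease_definition_list()
  truth <- tibble(
    disease = c("achd", "stroke", "ulcer", "breast_cancer", "prostate_cancer",
                "melanoma", "lung_cancer", "colon_cancer", "diabetes",
                "asthma", "parkinsons", "alzheimers"),
    c     = c(815, 1176, 1071, 795, 618, 744, 876, 1132, 800, 1198, 1130, 926),
    P     = c(29842, 22542, 17849, 10477, 6466, 3482, 20524, 27959, 3045,
              5530, 3667, 5323),
    r     = c(1.15, 0.80, 1.15, 0.42, 0.20, 0.22, 0.42, 1.03, 0.68, 1.63,
              0.52, 1.14),
    delta = c(1005, 949, 630, 613, 399, 201, 2818, 1288, 637, 985, 864, 1244),
    onset_hazard = rep_len(onset_hazard, 12))
  truth |>
    left_join(defs, by = "disease") |>
    select(disease, name, c, P, r, delta, onset_hazard, sex_restriction,
           patterns)
}

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic claims generator.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer RNG seed.
#' @param diseases Disease truth table as from [disease_presets()].
#' @param interview_date Survey interview date anchoring the cohort.
#' @param followup_years Incident-selection horizon after the interview
#'   (default 5).
#' @param cpi_base_year Base year of the CPI series (default 2000).
#' @param prevalent_fraction Fraction of per-disease onset cases that also
#'   carry a qualifying record pair before the interview (and should hence
#'   be excluded as prevalent).
#' @param single_record_fraction Fraction of onset cases emitting only a
#'   single qualifying record (never confirmed, hence never detected).
#' @param confirm_delay_days Length-2 integer range (min, max days >= 1)
#'   from which the gap between the onset record and its confirming record
#'   is drawn uniformly.
#' @param noise_sd Gaussian standard deviation (USD/month, year-2000
#'   dollars) of per-person monthly cost noise; negative draws are
#'   truncated at zero.
#' @param death_hazard_post_onset Per-month death probability after onset.
#' @param background_condition_rates Named numeric vector: annual
#'   probability of planting a claim for each Charlson condition group in
#'   the 12 months before interview. Defaults cover the groups whose
#'   planting codes do not collide with the twelve disease definitions.
#' @param baseline_cost Monthly cost plateau (USD, year-2000) for persons
#'   who never develop a tracked disease.
#' @param data_start First date with claims coverage (default 1991-01-01).
#' @param cpi [cpi_series()] used to emit nominal dollars.
#' @param disability_probs Length-3 probabilities of the three disability
#'   categories (nondisabled; IADL/1-2 ADLs; 3-6 ADLs).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 2000,
                       seed = 1L,
                       diseases = disease_presets(),
                       interview_date = as.Date("1994-10-01"),
                       followup_years = 5,
                       cpi_base_year = 2000,
                       prevalent_fraction = 0.05,
                       single_record_fraction = 0.05,
                       confirm_delay_days = c(7L, 60L),
                       noise_sd = 300,
                       death_hazard_post_onset = 0.01,
                       background_condition_rates = c(
                         mi = 0.05, chf = 0.05, pvd = 0.04, cvd = 0.04,
                         dementia = 0.03, copd = 0.08, rheum = 0.03,
                         mild_liver = 0.02, paralysis = 0.02, renal = 0.03,
                         malignancy = 0.03, sev_liver = 0.01, mets = 0.015,
                         aids = 0.002),
                       baseline_cost = 800,
                       data_start = as.Date("1991-01-01"),
                       cpi = default_medical_cpi(),
                       disability_probs = c(0.75, 0.13, 0.12)) {
  if (!is.numeric(n_persons) || n_persons < 1) {
    stop_config("n_persons", "must be a positive count")
  }
  for (f in c("prevalent_fraction", "single_record_fraction")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) stop_config(f, "must lie in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_config("noise_sd", "must be >= 0")
  }
  if (any(diseases$onset_hazard < 0 | diseases$onset_hazard > 1)) {
    stop_config("diseases", "onset hazards must lie in [0, 1]")
  }
  if (death_hazard_post_onset < 0 || death_hazard_post_onset > 1) {
    stop_config("death_hazard_post_onset", "must lie in [0, 1]")
  }
  if (length(confirm_delay_days) != 2 || any(confirm_delay_days < 1) ||
      confirm_delay_days[1] > confirm_delay_days[2]) {
    stop_config("confirm_delay_days", "must be an increasing range of days >= 1")
  }
  if (!is.null(names(background_condition_rates)) &&
      length(background_condition_rates) > 0) {
    unknown <- setdiff(names(background_condition_rates),
                       names(charlson_plant_codes))
    if (length(unknown) > 0) {
      stop_config("background_condition_rates",
                  paste("unknown condition group(s):",
                        paste(unknown, collapse = ", ")))
    }
  }
  if (abs(sum(disability_probs) - 1) > 1e-8 || any(disability_probs < 0)) {
    stop_config("disability_probs", "must be nonnegative and sum to 1")
  }
  if (cpi$base_year != cpi_base_year) {
    stop_config("cpi_base_year", "must match the CPI series base year")
  }
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    diseases = diseases, interview_date = as.Date(interview_date),
    followup_years = followup_years, cpi_base_year = as.integer(cpi_base_year),
    prevalent_fraction = prevalent_fraction,
    single_record_fraction = single_record_fraction,
    confirm_delay_days = as.integer(confirm_delay_days),
    noise_sd = noise_sd,
    death_hazard_post_onset = death_hazard_post_onset,
    background_condition_rates = background_condition_rates,
    baseline_cost = baseline_cost, data_start = as.Date(data_start),
    cpi = cpi, disability_probs = disability_probs),
    class = "sim_config")
}

#' Simulate one person's monthly cost sequence
#'
#' Evaluates the cost-trajectory model month by month: months before onset
#' have mean `c`, the onset month has mean `c + P`, and later months decay
#' toward `c + delta`. Months after the death month are absent (not
#' zero-filled).
#'
#' @param truth A [cost_model_params()] (or list with `c`, `P`, `r`,
#'   `delta`).
#' @param onset_month Zero-based month index of onset within the series,
#'   or `NA` for no onset.
#' @param death_month Optional zero-based month of death; months after it
#'   are dropped (a negative value yields an empty sequence).
#' @param noise_sd Gaussian noise SD (USD/month), truncated at zero.
#' @param n_months Length of the series.
#' @param seed Optional seed for reproducibility.
#' @return A tibble with columns `month` (0-based) and `cost`.
#' @export
simulate_cost_series <- function(truth, onset_month = NA, death_month = NULL,
                                 noise_sd = 0, n_months = 41, seed = NULL) {
  stopifnot(n_months >= 1)
  if (!is.null(seed)) set.seed(seed)
  months <- seq_len(n_months) - 1L
  if (!is.null(death_month)) months <- months[months <= death_month]
  if (length(months) == 0) return(tibble(month = integer(), cost = numeric()))
  mean_cost <- if (is.na(onset_month)) {
    rep(truth$c, length(months))
  } else {
    evaluate_cost(months - onset_month, truth)
  }
  cost <- if (noise_sd > 0) {
    pmax(mean_cost + rnorm(length(months), 0, noise_sd), 0)
  } else mean_cost
  tibble(month = months, cost = cost)
}

#' Emit the qualifying disease claims for one person
#'
#' Produces the primary-diagnosis claim records that drive onset detection:
#' an `"incident"` case gets two records on distinct dates separated by
#' `confirm_delay_days` (both from the four qualifying sources); a
#' `"single_record"` case gets exactly one; a `"prevalent"` case gets a
#' qualifying pair dated before the person's interview date.
#'
#' @param person One-row tibble (or list) with at least `person_id` and,
#'   for `role = "prevalent"`, `interview_date`.
#' @param disease Disease id (string) or a one-row disease table carrying
#'   a `patterns` list column.
#' @param onset_date Date of the first record (for `"prevalent"`, the date
#'   of the historical record; the pair must fall before the interview).
#' @param confirm_delay_days Days between the two records (>= 1).
#' @param role `"incident"`, `"prevalent"` or `"single_record"`.
#' @param cpi CPI series for nominal conversion of `paid_amount`.
#' @param paid_2000 Year-2000-dollar amounts attached to the records
#'   (default 0; costs ride on the monthly background claims).
#' @return A claims tibble.
#' @export
emit_claims <- function(person, disease, onset_date,
                        confirm_delay_days = 30L,
                        role = c("incident", "prevalent", "single_record"),
                        cpi = default_medical_cpi(), paid_2000 = 0) {
  role <- match.arg(role)
  if (is.character(disease)) {
    dd <- disease_definition_list()
    disease <- dd[dd$disease == disease, ]
    if (nrow(disease) != 1) stop("unknown disease id", call. = FALSE)
  }
  code <- pattern_example_code(disease$patterns[[1]][1])
  onset_date <- as.Date(onset_date)
  if (role != "single_record" && confirm_delay_days < 1) {
    stop("confirm_delay_days must be >= 1: the confirming record needs a ",
         "different date", call. = FALSE)
  }
  dates <- switch(role,
                  incident = c(onset_date, onset_date + confirm_delay_days),
                  prevalent = c(onset_date, onset_date + confirm_delay_days),
                  single_record = onset_date)
  sources <- c("inpatient", "physician")[seq_along(dates)]
  if (role == "prevalent") {
    iv <- as.Date(person$interview_date)
    if (any(dates >= iv)) {
      stop("prevalent record pair must be dated before the interview date",
           call. = FALSE)
    }
  }
  yrs <- claim_year(dates)
  tibble(person_id = person$person_id,
         service_date = dates,
         source = sources,
         icd9_primary = code,
         icd9_secondary = "",
         paid_amount = to_nominal_dollars(rep_len(paid_2000, length(dates)),
                                          yrs, cpi),
         claim_year = yrs)
}

#' Simulate a person/claims population with known ground truth
#'
#' Generates person- and claim-level tables with the statistical structure
#' the downstream analysis assumes: a pre-onset cost plateau, an
#' onset-month cost spike followed by exponential decline to a new plateau,
#' competing per-month disease onset hazards (at most one tracked onset per
#' person), post-onset mortality, background Charlson-condition claims in
#' the year before interview, prevalent-case contamination, and nominal
#' dollars inflated by the configured CPI series. Each monthly total rides
#' on one background (carrier) claim dated the first of the month;
#' detection, confirmation, prevalence and comorbidity claims are separate
#' zero-paid records.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A list of class `sim_population` with elements `persons`
#'   (tibble), `claims` (tibble) and `ground_truth` (list with per-person
#'   truth and the disease truth table).
#' @export
simulate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_persons
  dis <- config$diseases
  D <- nrow(dis)
  mi0 <- month_index(config$interview_date)
  fu_months <- as.integer(round(config$followup_years * 12))
  data_end_mi <- mi0 + fu_months + 21L

  person_id <- sprintf("P%05d", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age_iv <- runif(n, 65, 95)
  birth_date <- config$interview_date - round(age_iv * 365.25)
  b65_mi <- month_index(birth_date + round(65 * 365.25))
  enroll_start_mi <- pmax(month_index(config$data_start), b65_mi)
  enroll_start <- month_index_to_date(enroll_start_mi)

  dis_cat <- sample.int(3, n, replace = TRUE, prob = config$disability_probs)
  n_adl <- integer(n)
  has_iadl <- logical(n)
  lvl2 <- dis_cat == 2
  n_adl[lvl2] <- sample(0:2, sum(lvl2), replace = TRUE)
  has_iadl[lvl2] <- n_adl[lvl2] == 0 | runif(sum(lvl2)) < 0.5
  lvl3 <- dis_cat == 3
  n_adl[lvl3] <- sample(3:6, sum(lvl3), replace = TRUE)
  has_iadl[lvl3] <- runif(sum(lvl3)) < 0.7

  # competing onset hazards (sex restrictions zero out a column)
  H <- matrix(rep(dis$onset_hazard, each = n), nrow = n)
  for (j in seq_len(D)) {
    sr <- dis$sex_restriction[j]
    if (!is.na(sr)) H[sex != sr, j] <- 0
  }
  Htot <- rowSums(H)
  onset_rel <- rep(NA_integer_, n)
  pos <- Htot > 0
  if (any(pos)) onset_rel[pos] <- rgeom(sum(pos), pmin(Htot[pos], 1)) + 1L
  has_onset <- !is.na(onset_rel) & onset_rel <= fu_months
  disease_idx <- rep(NA_integer_, n)
  if (any(has_onset)) {
    u <- runif(n)
    cum <- H / ifelse(Htot > 0, Htot, 1)
    cum <- t(apply(cum, 1, cumsum))
    disease_idx[has_onset] <- (rowSums(u > cum) + 1L)[has_onset]
  }
  onset_mi <- ifelse(has_onset, mi0 + onset_rel, NA_integer_)
  onset_date <- rep(as.Date(NA), n)
  onset_date[has_onset] <- month_index_to_date(
    onset_mi[has_onset], sample(1:28, sum(has_onset), replace = TRUE))

  # roles for onset cases
  role <- rep(NA_character_, n)
  if (any(has_onset)) {
    u <- runif(n)
    role[has_onset] <- "incident"
    role[has_onset & u < config$prevalent_fraction +
           config$single_record_fraction] <- "single_record"
    role[has_onset & u < config$prevalent_fraction] <- "prevalent"
  }
  # prevalent history needs room between enrollment and interview
  delay_lo <- config$confirm_delay_days[1]
  delay_hi <- config$confirm_delay_days[2]
  infeasible <- role == "prevalent" &
    (config$interview_date - enroll_start) < (delay_hi + 150)
  role[which(infeasible)] <- "incident"

  # post-onset mortality (monthly Bernoulli hazard, death strictly after
  # the onset month so every death postdates its onset)
  death_mi <- rep(NA_integer_, n)
  if (config$death_hazard_post_onset > 0 && any(has_onset)) {
    k <- rgeom(sum(has_onset), config$death_hazard_post_onset) + 1L
    dm <- onset_mi[has_onset] + k
    dm[dm > data_end_mi] <- NA_integer_
    death_mi[has_onset] <- dm
  }
  death_date <- rep(as.Date(NA), n)
  dd <- !is.na(death_mi)
  death_date[dd] <- month_index_to_date(death_mi[dd],
                                        sample(1:28, sum(dd), replace = TRUE))

  confirm_delay <- if (delay_lo == delay_hi) rep(delay_lo, n) else
    sample(seq(delay_lo, delay_hi), n, replace = TRUE)

  end_mi <- pmin(ifelse(is.na(death_mi), data_end_mi, death_mi), data_end_mi)
  enrollment_end <- ifelse(is.na(death_date),
                           month_index_to_date(data_end_mi, 28),
                           death_date)
  enrollment_end <- as.Date(enrollment_end, origin = "1970-01-01")

  persons <- tibble(
    person_id = person_id, sex = sex, birth_date = birth_date,
    interview_date = config$interview_date, death_date = death_date,
    enrollment_start = enroll_start, enrollment_end = enrollment_end,
    n_adl = n_adl, has_iadl = has_iadl, weight = 1)

  # ---- monthly background costs -------------------------------------
  n_mo <- end_mi - enroll_start_mi + 1L
  prow <- rep(seq_len(n), n_mo)
  mi <- sequence(n_mo, from = enroll_start_mi, by = 1L)
  m_rel <- mi - onset_mi[prow]            # NA when the person has no onset
  c_p <- ifelse(has_onset, dis$c[disease_idx], config$baseline_cost)
  mean_cost <- c_p[prow]
  post <- !is.na(m_rel) & m_rel >= 0
  if (any(post)) {
    j <- disease_idx[prow[post]]
    mean_cost[post] <- dis$c[j] + dis$delta[j] +
      (dis$P[j] - dis$delta[j]) * exp(-dis$r[j] * m_rel[post])
  }
  cost2000 <- if (config$noise_sd > 0) {
    pmax(mean_cost + rnorm(length(mean_cost), 0, config$noise_sd), 0)
  } else mean_cost
  bg_date <- month_index_to_date(mi)
  bg_year <- mi %/% 12L
  background <- tibble(
    person_id = person_id[prow],
    service_date = bg_date,
    source = "carrier",
    icd9_primary = "4019",
    icd9_secondary = "",
    paid_amount = to_nominal_dollars(cost2000, bg_year, config$cpi),
    claim_year = bg_year)

  # ---- structural claims --------------------------------------------
  structural <- list()
  oi <- which(has_onset)
  if (length(oi) > 0) {
    first_date <- onset_date[oi]
    conf_date <- first_date + confirm_delay[oi]
    # a confirming claim cannot postdate death or the data window
    cap <- pmin(death_date[oi], month_index_to_date(data_end_mi, 28),
                na.rm = TRUE)
    conf_date <- pmin(conf_date, cap)
    keep_confirm <- role[oi] != "single_record" & conf_date > first_date
    code <- vapply(dis$patterns[disease_idx[oi]],
                   function(p) pattern_example_code(p[1]), character(1))
    onset_claims <- tibble(
      person_id = person_id[oi], service_date = first_date,
      source = "inpatient", icd9_primary = code, icd9_secondary = "",
      paid_amount = 0, claim_year = claim_year(first_date))
    confirm_claims <- tibble(
      person_id = person_id[oi][keep_confirm],
      service_date = conf_date[keep_confirm],
      source = "physician", icd9_primary = code[keep_confirm],
      icd9_secondary = "", paid_amount = 0,
      claim_year = claim_year(conf_date[keep_confirm]))
    structural$onset <- bind_rows(onset_claims, confirm_claims)

    pi <- oi[role[oi] == "prevalent"]
    if (length(pi) > 0) {
      span <- as.integer(config$interview_date - enroll_start[pi]) -
        confirm_delay[pi] - 1L
      hist_offset <- vapply(span, function(s) sample.int(s, 1), integer(1))
      hist_date <- config$interview_date - confirm_delay[pi] - hist_offset
      pcode <- vapply(dis$patterns[disease_idx[pi]],
                      function(p) pattern_example_code(p[1]), character(1))
      structural$prevalent <- tibble(
        person_id = rep(person_id[pi], 2),
        service_date = c(hist_date, hist_date + confirm_delay[pi]),
        source = rep(c("outpatient", "physician"), each = length(pi)),
        icd9_primary = rep(pcode, 2), icd9_secondary = "",
        paid_amount = 0,
        claim_year = claim_year(c(hist_date, hist_date + confirm_delay[pi])))
    }
  }

  rates <- config$background_condition_rates
  planted <- vector("list", length(rates))
  truth_conditions <- rep(list(character()), n)
  if (length(rates) > 0) {
    for (k in seq_along(rates)) {
      hit <- which(rbinom(n, 1, rates[[k]]) == 1)
      # keep planted claims inside the enrollment span
      span_ok <- as.integer(config$interview_date - enroll_start[hit]) > 32
      hit <- hit[span_ok]
      if (length(hit) == 0) next
      max_back <- pmin(360L,
                       as.integer(config$interview_date - enroll_start[hit]) - 1L)
      back <- vapply(max_back, function(mb) sample(30:mb, 1), integer(1))
      dt <- config$interview_date - back
      planted[[k]] <- tibble(
        person_id = person_id[hit], service_date = dt, source = "physician",
        icd9_primary = charlson_plant_codes[[names(rates)[k]]],
        icd9_secondary = "", paid_amount = 0, claim_year = claim_year(dt))
      for (i in hit) {
        truth_conditions[[i]] <- c(truth_conditions[[i]], names(rates)[k])
      }
    }
  }
  structural$charlson <- bind_rows(planted)

  claims <- bind_rows(background, bind_rows(structural)) |>
    arrange(person_id, service_date, source)
  claims$claim_id <- sprintf("C%07d", seq_len(nrow(claims)))
  claims <- claims |>
    select(claim_id, person_id, service_date, source, icd9_primary,
           icd9_secondary, paid_amount, claim_year)

  ground_truth <- list(
    persons = tibble(
      person_id = person_id,
      disease = ifelse(has_onset, dis$disease[disease_idx], NA_character_),
      onset_date = onset_date,
      role = role,
      death_date = death_date,
      plateau = c_p,
      disability_category = c("nondisabled", "IADL only or/and 1-2 ADLs",
                              "3-6 ADLs")[dis_cat],
      conditions = truth_conditions),
    disease_truth = dis |> select(-patterns),
    seed = seed,
    interview_date = config$interview_date)

  structure(list(persons = persons, claims = claims,
                 ground_truth = ground_truth, config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population: %d persons, %d claims, %d true onsets>\n",
              nrow(x$persons), nrow(x$claims),
              sum(!is.na(x$ground_truth$persons$onset_date))))
  invisible(x)
}

#' Write a simulated population to disk
#'
#' Writes `persons.csv`, `claims.csv` and `ground_truth.json` (ISO-8601
#' dates throughout).
#'
#' @param pop A `sim_population` from [simulate_population()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(pop$persons, file.path(dir, "persons.csv"), row.names = FALSE)
  write.csv(pop$claims, file.path(dir, "claims.csv"), row.names = FALSE)
  gt <- pop$ground_truth
  gt$persons <- as.data.frame(gt$persons)
  gt$persons$conditions <- vapply(gt$persons$conditions, paste,
                                  character(1), collapse = "|")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       Date = "ISO8601")
  invisible(dir)
}
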