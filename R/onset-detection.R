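#' Find a disease onset in one person's claims
#'
#' Implements the two-record onset rule: the onset date is the date of the
#' earliest claim carrying a matching ICD-9 code as primary diagnosis in
#' one of the four qualifying sources (inpatient, outpatient, physician,
#' skilled nursing facility), provided a second such claim exists on a
#' strictly later date no more than 0.3 years (109.575 days; integer gaps
#' up to 109 days qualify) after it. Absence of a confirming record means
#' no onset. Ties on the earliest date are resolved by claim id; same-date
#' records never confirm each other.
#'
#' @param records Claims tibble for a single person with columns
#'   `service_date`, `source`, `icd9_primary` and optionally `claim_id`.
#' @param disease One row of [disease_definition_list()] (or a disease id
#'   string).
#' @return A one-row tibble (`person_id` if present, `disease`,
#'   `onset_date`, `first_record_id`, `confirming_record_id`,
#'   `confirm_gap_days`), or `NULL` when no onset qualifies.
#' @export
find_onset <- function(records, disease) {
  if (is.character(disease)) {
    dd <- disease_definition_list()
    disease <- dd[dd$disease == disease, ]
    if (nrow(disease) != 1) stop("unknown disease id", call. = FALSE)
  }
  if (nrow(records) == 0) return(NULL)
  if (!"claim_id" %in% names(records)) {
    records$claim_id <- sprintf("R%04d", seq_len(nrow(records)))
  }
  qual <- records[records$source %in% QUALIFYING_SOURCES &
                    match_any_pattern(records$icd9_primary,
                                      disease$patterns[[1]]), , drop = FALSE]
  if (nrow(qual) == 0) return(NULL)
  qual <- qual[order(qual$service_date, qual$claim_id), , drop = FALSE]
  first <- qual[1, ]
  gap <- as.numeric(qual$service_date - first$service_date)
  confirm <- qual[gap > 0 & gap <= CONFIRM_WINDOW_DAYS, , drop = FALSE]
  if (nrow(confirm) == 0) return(NULL)
  conf <- confirm[1, ]
  tibble(person_id = col_or(first, "person_id", NA_character_),
         disease = disease$disease,
         onset_date = first$service_date,
         first_record_id = first$claim_id,
         confirming_record_id = conf$claim_id,
         confirm_gap_days = as.numeric(conf$service_date - first$service_date))
}

#' Detect onsets for every person in a claims table
#'
#' Vectorized equivalent of applying [find_onset()] to each person's
#' records; returns one row per detected onset.
#'
#' @param claims Claims tibble (`person_id`, `service_date`, `source`,
#'   `icd9_primary`, optionally `claim_id`).
#' @param disease One row of [disease_definition_list()] or a disease id.
#' @return An onset tibble (possibly empty).
#' @export
detect_onsets <- function(claims, disease) {
  if (is.character(disease)) {
    dd <- disease_definition_list()
    disease <- dd[dd$disease == disease, ]
  }
  if (!"claim_id" %in% names(claims)) {
    claims$claim_id <- sprintf("R%07d", seq_len(nrow(claims)))
  }
  qual <- claims |>
    filter(source %in% QUALIFYING_SOURCES,
           match_any_pattern(icd9_primary, disease$patterns[[1]])) |>
    arrange(person_id, service_date, claim_id)
  if (nrow(qual) == 0) {
    return(tibble(person_id = character(), disease = character(),
                  onset_date = as.Date(character()),
                  first_record_id = character(),
                  confirming_record_id = character(),
                  confirm_gap_days = numeric()))
  }
  qual |>
    group_by(person_id) |>
    summarise(
      onset_date = first(service_date),
      first_record_id = first(claim_id),
      conf_pos = {
        gap <- as.numeric(service_date - first(service_date))
        ok <- which(gap > 0 & gap <= CONFIRM_WINDOW_DAYS)
        if (length(ok)) ok[1] else NA_integer_
      },
      confirming_record_id = ifelse(is.na(conf_pos), NA_character_,
                                    claim_id[pmax(conf_pos, 1L)]),
      confirm_gap_days = ifelse(is.na(conf_pos), NA_real_,
                                as.numeric(service_date[pmax(conf_pos, 1L)] -
                                             first(service_date))),
      .groups = "drop") |>
    filter(!is.na(conf_pos)) |>
    mutate(disease = disease$disease) |>
    select(person_id, disease, onset_date, first_record_id,
           confirming_record_id, confirm_gap_days)
}

#' Exclude prevalent cases
#'
#' Removes every person with at least one claim matching the disease's
#' ICD-9 patterns dated before the interview. Histories are reconstructed
#' combining all records: by default any diagnosis position (primary or
#' secondary) and any claim source counts.
#'
#' @param persons Person tibble with `person_id`.
#' @param claims Claims tibble covering the period from data start to the
#'   interview.
#' @param disease One row of [disease_definition_list()] or a disease id.
#' @param interview_date The reference interview date (required).
#' @param any_position If `TRUE` (default), secondary diagnoses also mark
#'   a history; if `FALSE`, only primary diagnoses do.
#' @return The subset of `persons` without a pre-interview disease history.
#' @export
exclude_prevalent <- function(persons, claims, disease, interview_date,
                              any_position = TRUE) {
  if (missing(interview_date) || is.null(interview_date) ||
      is.na(interview_date)) {
    stop("interview_date is required for prevalence exclusion", call. = FALSE)
  }
  if (is.character(disease)) {
    dd <- disease_definition_list()
    disease <- dd[dd$disease == disease, ]
  }
  pre <- claims[claims$service_date < as.Date(interview_date), , drop = FALSE]
  hit <- match_any_pattern(pre$icd9_primary, disease$patterns[[1]])
  if (any_position) {
    sec <- col_or(pre, "icd9_secondary", rep("", nrow(pre)))
    sec[is.na(sec)] <- ""
    has_sec <- nzchar(sec) & !hit
    if (any(has_sec)) {
      parts <- strsplit(sec[has_sec], "|", fixed = TRUE)
      sec_hit <- vapply(parts,
                        function(p) any(match_any_pattern(p,
                                                          disease$patterns[[1]])),
                        logical(1))
      hit[has_sec] <- sec_hit
    }
  }
  prevalent_ids <- unique(pre$person_id[hit])
  persons[!persons$person_id %in% prevalent_ids, , drop = FALSE]
}

#' Select the incident cohort
#'
#' Keeps onsets occurring strictly after the interview and within the
#' follow-up horizon (default 5 years), and applies the disease's sex
#' restriction.
#'
#' @param persons Person tibble (after prevalence exclusion) with
#'   `person_id` and `sex`.
#' @param onsets Onset tibble as from [find_onset()]/[detect_onsets()].
#' @param disease One row of [disease_definition_list()] or a disease id.
#' @param interview_date Reference interview date.
#' @param horizon_years Selection horizon after the interview (default 5).
#' @return The subset of `onsets` defining the incident cohort.
#' @export
select_incident_cohort <- function(persons, onsets, disease, interview_date,
                                   horizon_years = 5) {
  if (is.character(disease)) {
    dd <- disease_definition_list()
    disease <- dd[dd$disease == disease, ]
  }
  interview_date <- as.Date(interview_date)
  horizon_end <- interview_date + horizon_years * 365.25
  keep <- onsets |>
    filter(onset_date > interview_date, onset_date <= horizon_end,
           person_id %in% persons$person_id)
  sr <- disease$sex_restriction
  if (length(sr) == 1 && !is.na(sr)) {
    ok_ids <- persons$person_id[persons$sex == sr]
    keep <- keep |> filter(person_id %in% ok_ids)
  }
  keep
}
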