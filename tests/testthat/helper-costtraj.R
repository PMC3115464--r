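# Shared fixtures and independent oracles.

achd_truth <- function() {
  cost_model_params(c = 815, P = 29842, r = 1.15, delta = 1005)
}

qualifying_sources <- c("inpatient", "outpatient", "physician", "snf")
all_sources <- c(qualifying_sources, "hospice", "hha", "carrier", "dme")

make_claims <- function(dates, sources, codes, person_id = "p1",
                        secondary = "") {
  tibble::tibble(
    claim_id = sprintf("R%03d", seq_along(dates)),
    person_id = person_id,
    service_date = as.Date(dates),
    source = sources,
    icd9_primary = codes,
    icd9_secondary = secondary,
    paid_amount = 0,
    claim_year = as.integer(format(as.Date(dates), "%Y")))
}

# Brute-force onset oracle: exhaustive search over all ordered record
# pairs, built directly from the rule's text (earliest qualifying
# primary-diagnosis record, confirmed by a later record within 0.3 years).
# Deliberately naive; shares only match_icd9 with the implementation.
brute_force_onset <- function(records, patterns) {
  is_qual <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    is_qual[i] <- records$source[i] %in% qualifying_sources &&
      any(vapply(patterns,
                 function(p) match_icd9(records$icd9_primary[i], p),
                 logical(1)))
  }
  q <- records[is_qual, , drop = FALSE]
  if (nrow(q) == 0) return(NULL)
  first_date <- min(q$service_date)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(q))) {
      if (i == j) next
      gap <- as.numeric(q$service_date[j] - q$service_date[i])
      if (q$service_date[i] == first_date && gap > 0 &&
          gap <= 0.3 * 365.25) {
        return(first_date)
      }
    }
  }
  NULL
}

# Random claim set for the oracle-equivalence property: up to 12 records,
# dates concentrated so that confirm-window edge cases occur often.
random_record_set <- function() {
  n <- sample(1:12, 1)
  codes <- sample(c("41011", "41100", "4139", "431", "25000", "V4501"),
                  n, replace = TRUE)
  make_claims(
    dates = as.Date("1995-01-01") + sample(0:160, n, replace = TRUE),
    sources = sample(all_sources, n, replace = TRUE),
    codes = codes)
}

# Minimal single-disease simulation: everyone with an onset gets it in
# month 1 when hazard = 1, handy for exact-profile tests.
achd_only_config <- function(n_persons, noise_sd = 0, hazard = 0.02,
                             seed = 1, ...) {
  dis <- disease_presets()
  dis$onset_hazard <- ifelse(dis$disease == "achd", hazard, 0)
  sim_config(n_persons = n_persons, seed = seed, diseases = dis,
             noise_sd = noise_sd, ...)
}
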