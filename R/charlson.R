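#' Charlson condition groups and weights (ICD-9 claims coding)
#'
#' The seventeen chronic-condition groups contributing to the Charlson
#' comorbidity index, with their mortality-risk weights and the ICD-9-CM
#' code prefixes (Quan et al. enhanced coding) used to recognise each group
#' in claims. A claim code belongs to a group when one of the group's
#' prefixes is a prefix of the dotless code.
#'
#' @return A tibble with columns `condition`, `weight`, `icd9_prefix`.
#' @export
charlson_conditions <- function() {
  as_tibble(read.csv(costtraj_extdata("charlson_icd9.csv"),
                     colClasses = c("character", "integer", "character")))
}

# condition -> weight (one row per condition)
charlson_weights <- function(cond = charlson_conditions()) {
  w <- cond |> distinct(condition, weight)
  setNames(w$weight, w$condition)
}

# condition -> single regex over canonical codes
charlson_regexes <- function(cond = charlson_conditions()) {
  sp <- split(cond$icd9_prefix, cond$condition)
  vapply(sp, function(p) paste0("^(", paste(p, collapse = "|"), ")"),
         character(1))
}

# Hierarchy: the severe member of each pair supersedes the mild one.
CHARLSON_HIERARCHY <- list(
  c(severe = "diab_comp", mild = "diab_unc"),
  c(severe = "mets",      mild = "malignancy"),
  c(severe = "sev_liver", mild = "mild_liver"))

apply_charlson_hierarchy <- function(conditions) {
  for (h in CHARLSON_HIERARCHY) {
    if (h[["severe"]] %in% conditions) {
      conditions <- setdiff(conditions, h[["mild"]])
    }
  }
  conditions
}

# All ICD-9 codes (primary + pipe-delimited secondary) per claim, long form.
claim_codes_long <- function(claims) {
  sec <- col_or(claims, "icd9_secondary", rep("", nrow(claims)))
  sec[is.na(sec)] <- ""
  has_sec <- nzchar(sec)
  out <- tibble(row = seq_len(nrow(claims)), code = as.character(claims$icd9_primary))
  if (any(has_sec)) {
    parts <- strsplit(sec[has_sec], "|", fixed = TRUE)
    out <- bind_rows(out,
                     tibble(row = rep(which(has_sec), lengths(parts)),
                            code = unlist(parts)))
  }
  out[nzchar(out$code) & !is.na(out$code), ]
}

#' Charlson comorbidity index from claims
#'
#' Maps all ICD-9 codes (primary and secondary, any claim source) appearing
#' in the lookback window before `index_date` to the seventeen Charlson
#' condition groups and returns the weight sum. Each group is counted at
#' most once, and the hierarchy rules apply: complicated diabetes
#' supersedes uncomplicated diabetes, metastatic solid tumour supersedes
#' other malignancy, and moderate/severe liver disease supersedes mild
#' liver disease.
#'
#' @param claims Claims tibble with `person_id`, `service_date`,
#'   `icd9_primary` and optionally `icd9_secondary` (pipe-delimited).
#' @param person_id The person whose index is computed.
#' @param index_date Date anchoring the lookback window; claims dated in
#'   `[index_date - lookback_days, index_date)` are used.
#' @param lookback_days Length of the lookback window (default 365).
#' @return A non-negative integer weight sum (0 for an empty window).
#' @export
#' @examples
#' claims <- tibble::tibble(person_id = "p1",
#'                          service_date = as.Date("1994-05-01"),
#'                          icd9_primary = "41001", icd9_secondary = "2500")
#' charlson_index(claims, "p1", as.Date("1994-10-01"))  # MI + diabetes = 2
charlson_index <- function(claims, person_id, index_date, lookback_days = 365) {
  window <- claims[claims$person_id == person_id &
                     claims$service_date >= index_date - lookback_days &
                     claims$service_date < index_date, , drop = FALSE]
  if (nrow(window) == 0) return(0L)
  codes <- icd9_canonical(claim_codes_long(window)$code)
  rx <- charlson_regexes()
  present <- names(rx)[vapply(rx, function(r) any(grepl(r, codes)), logical(1))]
  present <- apply_charlson_hierarchy(present)
  sum(charlson_weights()[present])
}

# Vectorized Charlson over many persons at a common index date.
# Returns tibble(person_id, charlson).
charlson_scores <- function(claims, person_ids, index_date, lookback_days = 365) {
  window <- claims |>
    filter(person_id %in% person_ids,
           service_date >= index_date - lookback_days,
           service_date < index_date)
  if (nrow(window) > 0) {
    long <- claim_codes_long(window)
    long$person_id <- window$person_id[long$row]
    long$code <- icd9_canonical(long$code)
    rx <- charlson_regexes()
    hits <- lapply(names(rx), function(cn) {
      ok <- grepl(rx[[cn]], long$code)
      if (!any(ok)) return(NULL)
      tibble(person_id = unique(long$person_id[ok]), condition = cn)
    })
    hits <- bind_rows(hits)
  } else {
    hits <- tibble(person_id = character(), condition = character())
  }
  w <- charlson_weights()
  scores <- hits |>
    group_by(person_id) |>
    summarise(charlson = sum(w[apply_charlson_hierarchy(condition)]),
              .groups = "drop")
  tibble(person_id = person_ids) |>
    left_join(scores, by = "person_id") |>
    mutate(charlson = ifelse(is.na(charlson), 0L, charlson))
}

#' Charlson stratum label (0 / 1 / 2 / >2)
#'
#' @param index Integer Charlson weight sum.
#' @return Character vector of stratum labels.
#' @export
charlson_category <- function(index) {
  ifelse(index > 2, ">2", as.character(index))
}

# Representative planting codes per condition group used by the synthetic
# generator. Codes are chosen so that none matches the twelve disease
# definitions (e.g. old MI 412 rather than 410/411/413), keeping background
# comorbidity from creating prevalent cases.
charlson_plant_codes <- c(
  mi = "412", chf = "4280", pvd = "4409", cvd = "4380",
  dementia = "2900", copd = "496", rheum = "7140",
  mild_liver = "5715", paralysis = "3429", renal = "585",
  malignancy = "20000", sev_liver = "5722", mets = "1970", aids = "042")
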