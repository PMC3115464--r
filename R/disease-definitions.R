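#' Shipped ICD-9 disease definitions
#'
#' Returns the ICD-9 pattern table defining the twelve aging-related
#' diseases tracked by the package: acute coronary heart disease, stroke,
#' ulcer, breast/prostate/lung/colon cancer, melanoma, diabetes, asthma,
#' Parkinson's and Alzheimer's disease. Patterns come in three forms:
#' `"NNN.xx"` (any code with three-digit root NNN), `"NNN.x1"` (five-digit
#' code with root NNN and fifth digit 1, used for the stroke subcodes), and
#' `"NNN.D"` (fourth digit exactly D, any or no fifth digit). Breast cancer
#' is restricted to women and prostate cancer to men.
#'
#' @param file Optional path to an alternative definition CSV with columns
#'   `disease,name,pattern,sex_restriction`.
#' @return A tibble with one row per (disease, pattern).
#' @export
#' @examples
#' disease_definitions()
disease_definitions <- function(file = NULL) {
  path <- file %||% costtraj_extdata("disease_definitions.csv")
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df$sex_restriction[is.na(df$sex_restriction) | df$sex_restriction == ""] <- NA_character_
  as_tibble(df)
}

#' Canonicalize an ICD-9 code
#'
#' Uppercases and strips the embedded dot, so `"433.01"` and `"43301"`
#' compare equal.
#'
#' @param code Character vector of ICD-9 codes.
#' @return Character vector of dotless codes.
#' @export
icd9_canonical <- function(code) {
  toupper(gsub(".", "", as.character(code), fixed = TRUE))
}

icd9_pattern_regex <- function(pattern) {
  m <- regmatches(pattern,
                  regexec("^([0-9]{3})\\.(xx|x1|[0-9])$", pattern))[[1]]
  if (length(m) == 0) {
    stop("malformed ICD-9 pattern: '", pattern,
         "' (expected NNN.xx, NNN.x1 or NNN.D)", call. = FALSE)
  }
  root <- m[2]
  suffix <- m[3]
  if (suffix == "xx") {
    paste0("^", root, "[0-9]{0,2}$")
  } else if (suffix == "x1") {
    paste0("^", root, "[0-9]1$")
  } else {
    paste0("^", root, suffix, "[0-9]?$")
  }
}

#' Match ICD-9 codes against a disease definition pattern
#'
#' @param code Character vector of ICD-9 codes, with or without the dot.
#' @param pattern A single pattern string (`"NNN.xx"`, `"NNN.x1"` or
#'   `"NNN.D"`).
#' @return Logical vector.
#' @export
#' @examples
#' match_icd9("41071", "410.xx")  # TRUE
#' match_icd9(c("43301", "43300"), "433.x1")  # TRUE FALSE
#' match_icd9(c("3310", "3311"), "331.0")  # TRUE FALSE
match_icd9 <- function(code, pattern) {
  stopifnot(length(pattern) == 1)
  grepl(icd9_pattern_regex(pattern), icd9_canonical(code))
}

# TRUE where `codes` matches any of the patterns.
match_any_pattern <- function(codes, patterns) {
  canon <- icd9_canonical(codes)
  hit <- rep(FALSE, length(canon))
  for (p in patterns) {
    hit <- hit | grepl(icd9_pattern_regex(p), canon)
  }
  hit
}

# A concrete claimable code satisfying `pattern` (used by the generator).
pattern_example_code <- function(pattern) {
  m <- regmatches(pattern,
                  regexec("^([0-9]{3})\\.(xx|x1|[0-9])$", pattern))[[1]]
  if (length(m) == 0) stop("malformed ICD-9 pattern: ", pattern)
  root <- m[2]
  suffix <- m[3]
  switch(suffix,
         xx = paste0(root, "0"),
         x1 = paste0(root, "01"),
         paste0(root, suffix))
}

# One-row-per-disease view with patterns collapsed into a list column.
disease_definition_list <- function(defs = disease_definitions()) {
  defs |>
    group_by(disease, name) |>
    summarise(patterns = list(pattern),
              sex_restriction = first(sex_restriction),
              .groups = "drop")
}
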