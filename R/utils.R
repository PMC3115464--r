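# Calendar helpers. Months are indexed as year*12 + (month - 1) so that
# differences of indices are calendar-month offsets, the binning convention
# used throughout the profile builder.

month_index <- function(date) {
  lt <- as.POSIXlt(date)
  (lt$year + 1900L) * 12L + lt$mon
}

month_index_to_date <- function(mi, day = 1L) {
  as.Date(sprintf("%04d-%02d-%02d", mi %/% 12L, mi %% 12L + 1L, day))
}

claim_year <- function(date) as.integer(format(date, "%Y"))

`%||%` <- function(x, y) if (is.null(x)) y else x

# column if present, else a default (tibbles warn on `$` for missing cols)
col_or <- function(df, nm, default) {
  if (nm %in% names(df)) df[[nm]] else default
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

# Gap (in days) within which a confirming record must follow the earliest
# qualifying record: 0.3 years on a 365.25-day year.
CONFIRM_WINDOW_DAYS <- 0.3 * 365.25

# Claim sources that may carry the qualifying primary diagnosis.
QUALIFYING_SOURCES <- c("inpatient", "outpatient", "physician", "snf")

costtraj_extdata <- function(file) {
  path <- system.file("extdata", file, package = "costtraj")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("cannot locate shipped data file: ", file)
  path
}
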