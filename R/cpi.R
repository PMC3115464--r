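#' Construct a medical-care CPI series
#'
#' A CPI series maps calendar years to index values and carries a base year;
#' monetary amounts are expressed in base-year dollars by multiplying with
#' `index[base_year] / index[year]`.
#'
#' @param data A data frame with columns `year` and `index` (all `index`
#'   values positive).
#' @param base_year Base year for adjusted amounts (default 2000). Must be
#'   present in `data`.
#' @return An object of class `cpi_series`.
#' @export
cpi_series <- function(data, base_year = 2000) {
  stopifnot(all(c("year", "index") %in% names(data)))
  if (any(!is.finite(data$index) | data$index <= 0)) {
    stop("CPI index values must be positive", call. = FALSE)
  }
  if (anyDuplicated(data$year)) stop("duplicate CPI years", call. = FALSE)
  if (!base_year %in% data$year) {
    stop("CPI base year ", base_year, " not present in series", call. = FALSE)
  }
  structure(
    list(index = setNames(as.numeric(data$index), as.character(data$year)),
         base_year = as.integer(base_year)),
    class = "cpi_series")
}

#' @export
print.cpi_series <- function(x, ...) {
  cat("<cpi_series> base year", x$base_year, "covering",
      min(as.integer(names(x$index))), "-",
      max(as.integer(names(x$index))), "\n")
  invisible(x)
}

#' Default medical-care CPI series
#'
#' Annual medical-care consumer price index (1982-84 = 100 basis) for
#' 1991-2005, base year 2000, used by the synthetic claims generator to
#' emit nominal dollars and by the cohort builder to deflate them back.
#'
#' @return A `cpi_series`.
#' @export
default_medical_cpi <- function() {
  cpi_series(read.csv(costtraj_extdata("cpi_medical.csv")), base_year = 2000)
}

cpi_lookup <- function(cpi, year) {
  idx <- cpi$index[as.character(year)]
  if (anyNA(idx)) {
    stop("CPI year(s) missing from series: ",
         paste(unique(year[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  unname(idx)
}

#' Adjust nominal dollars to base-year (year-2000) dollars
#'
#' @param amount Numeric vector of nominal dollar amounts.
#' @param year Integer vector (recycled) of the years the amounts were paid.
#' @param cpi A [cpi_series()]; defaults to the shipped medical-care series.
#' @return Amounts in base-year dollars: `amount * index[base] / index[year]`.
#' @export
#' @examples
#' adjust_to_2000_dollars(100, 2000)  # identity at the base year
adjust_to_2000_dollars <- function(amount, year, cpi = default_medical_cpi()) {
  amount * cpi_lookup(cpi, cpi$base_year) / cpi_lookup(cpi, year)
}

# Inverse of adjust_to_2000_dollars; the generator emits nominal claims.
to_nominal_dollars <- function(amount, year, cpi = default_medical_cpi()) {
  amount * cpi_lookup(cpi, year) / cpi_lookup(cpi, cpi$base_year)
}
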