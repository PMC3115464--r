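#' Survival specifications for the population cost forecast
#'
#' The forecast needs the cohort's disease-free survival function `S(x)`
#' (equivalently its hazard, density or distribution function). Two kinds
#' are supported: a constant per-month hazard (`S(x) = exp(-h x)`), and a
#' tabulated right-continuous step function such as a Kaplan-Meier
#' estimate, with probability mass `dF` at each drop time.
#'
#' @param h Constant hazard rate (1/month), `h >= 0`.
#' @return An object of class `survival_input`.
#' @export
#' @examples
#' constant_hazard_survival(0.02)
constant_hazard_survival <- function(h) {
  if (!is.finite(h) || h < 0) stop("hazard h must be >= 0", call. = FALSE)
  structure(list(kind = "constant_hazard", h = h), class = "survival_input")
}

#' @rdname constant_hazard_survival
#' @param steps Data frame with columns `time` (strictly increasing, > 0)
#'   and `S` (survival just after `time`; non-increasing, in `[0, 1]`,
#'   with the implicit `S(0) = 1`).
#' @export
tabulated_survival <- function(steps) {
  stopifnot(all(c("time", "S") %in% names(steps)))
  steps <- steps[order(steps$time), , drop = FALSE]
  if (any(diff(steps$time) <= 0)) stop("step times must be strictly increasing", call. = FALSE)
  if (any(steps$S < 0 | steps$S > 1)) stop("S must lie in [0, 1]", call. = FALSE)
  if (any(diff(c(1, steps$S)) > 1e-12)) stop("S must be non-increasing from S(0) = 1", call. = FALSE)
  structure(list(kind = "tabulated",
                 steps = tibble(time = as.numeric(steps$time),
                                S = as.numeric(steps$S))),
            class = "survival_input")
}

#' @export
print.survival_input <- function(x, ...) {
  if (x$kind == "constant_hazard") {
    cat(sprintf("<survival_input: constant hazard h = %g /month>\n", x$h))
  } else {
    cat(sprintf("<survival_input: tabulated step S with %d drop times>\n",
                nrow(x$steps)))
  }
  invisible(x)
}

#' Kaplan-Meier survival from an event table
#'
#' Product-limit estimator \eqn{S(t_k) = \prod_{j \le k} (1 - d_j / n_j)}
#' from an ordered event table.
#'
#' @param event_table Data frame with columns `time` (strictly increasing),
#'   `n_at_risk` and `n_events` (`n_events <= n_at_risk`).
#' @return A tabulated [survival_input].
#' @export
#' @examples
#' survival_from_km(data.frame(time = c(3, 7), n_at_risk = c(10, 6),
#'                             n_events = c(1, 2)))
survival_from_km <- function(event_table) {
  et <- as.data.frame(event_table)
  stopifnot(all(c("time", "n_at_risk", "n_events") %in% names(et)))
  if (any(diff(et$time) <= 0)) stop("event times must be strictly increasing", call. = FALSE)
  if (any(et$n_events > et$n_at_risk) || any(et$n_events < 0) ||
      any(et$n_at_risk <= 0)) {
    stop("inconsistent event table: need 0 <= n_events <= n_at_risk",
         call. = FALSE)
  }
  tabulated_survival(tibble(time = et$time,
                            S = cumprod(1 - et$n_events / et$n_at_risk)))
}

surv_S <- function(survival, x) {
  if (survival$kind == "constant_hazard") return(exp(-survival$h * x))
  st <- survival$steps
  vapply(x, function(xx) {
    k <- sum(st$time <= xx)
    if (k == 0) 1 else st$S[k]
  }, numeric(1))
}

forecast_point <- function(x, healthy, acquired, treatment) {
  structure(list(x = x, total_cost = healthy + acquired + treatment,
                 components = c(healthy = healthy, acquired = acquired,
                                treatment = treatment)),
            class = "forecast_point")
}

#' @export
print.forecast_point <- function(x, ...) {
  cat(sprintf("<forecast_point x = %g months: total %.2f (healthy %.2f + acquired %.2f + treatment %.2f)>\n",
              x$x, x$total_cost, x$components[["healthy"]],
              x$components[["acquired"]], x$components[["treatment"]]))
  invisible(x)
}

#' Expected per-capita cost for a cohort exposed to one disease
#'
#' Averages the individual cost-trajectory model over onset times drawn
#' from the survival specification:
#' \deqn{C_{tot}(x) = c S(x) + (c + \delta) F(x) +
#'       (P - \delta) \int_0^x e^{-r (x - u)} f(u) \, du}
#' The three terms are the contribution of still-healthy individuals, the
#' acquired-comorbidity plateau of those with onset, and the decaying
#' treatment cost after onset. Individuals are assumed not to experience
#' any other health event (including death) during follow-up. For a
#' constant hazard the integral is computed by adaptive quadrature
#' (absolute tolerance `1e-10 * (c + P)`); for a tabulated survival the
#' density is a sum of point masses at the drop times, making the integral
#' an exact finite sum.
#'
#' @param x Forecast time in months since cohort start (`x >= 0`, scalar).
#' @param params A full-variant [cost_model_params()].
#' @param survival A [constant_hazard_survival()], [tabulated_survival()]
#'   or [survival_from_km()] object.
#' @return A `forecast_point` with the total and its three components.
#' @export
#' @examples
#' achd <- cost_model_params(c = 815, P = 29842, r = 1.15, delta = 1005)
#' total_cost(12, achd, constant_hazard_survival(0.02))
total_cost <- function(x, params, survival) {
  if (!is.finite(x) || x < 0) stop("forecast time x must be >= 0", call. = FALSE)
  if ((params$variant %||% "full") != "full") {
    stop("total_cost requires the full model variant", call. = FALSE)
  }
  S <- surv_S(survival, x)
  F <- 1 - S
  if (x == 0) {
    return(forecast_point(x, params$c, 0, 0))
  }
  if (survival$kind == "constant_hazard") {
    h <- survival$h
    treat_int <- if (h == 0) 0 else {
      stats::integrate(function(u) exp(-params$r * (x - u)) * h * exp(-h * u),
                       lower = 0, upper = x,
                       abs.tol = 1e-10 * (params$c + params$P),
                       rel.tol = 1e-12)$value
    }
  } else {
    st <- survival$steps
    dF <- diff(c(0, 1 - st$S))
    in_win <- st$time <= x
    treat_int <- sum(dF[in_win] * exp(-params$r * (x - st$time[in_win])))
  }
  forecast_point(x,
                 healthy = params$c * S,
                 acquired = (params$c + params$delta) * F,
                 treatment = (params$P - params$delta) * treat_int)
}

#' Closed-form forecast under a constant onset hazard
#'
#' With `S(x) = exp(-h x)` the treatment integral has the closed form
#' `h (e^{-h x} - e^{-r x}) / (r - h)` (and `h x e^{-h x}` at `r = h`).
#'
#' @param x Forecast time in months (`x >= 0`, scalar).
#' @param params A full-variant [cost_model_params()].
#' @param h Constant onset hazard (1/month, `h >= 0`).
#' @return A `forecast_point`.
#' @export
total_cost_constant_hazard <- function(x, params, h) {
  if (!is.finite(x) || x < 0) stop("forecast time x must be >= 0", call. = FALSE)
  if (!is.finite(h) || h < 0) stop("hazard h must be >= 0", call. = FALSE)
  S <- exp(-h * x)
  F <- 1 - S
  r <- params$r
  treat_int <- if (h == 0) {
    0
  } else if (abs(r - h) < 1e-9 * max(1, abs(h))) {
    h * x * exp(-h * x)
  } else {
    h * (exp(-h * x) - exp(-r * x)) / (r - h)
  }
  forecast_point(x,
                 healthy = params$c * S,
                 acquired = (params$c + params$delta) * F,
                 treatment = (params$P - params$delta) * treat_int)
}

#' Forecast curve over a grid of times
#'
#' @param xs Numeric vector of forecast times (months).
#' @inheritParams total_cost
#' @return A tibble with columns `x`, `total`, `healthy`, `acquired`,
#'   `treatment`.
#' @export
forecast_curve <- function(xs, params, survival) {
  rows <- lapply(xs, function(x) {
    fp <- total_cost(x, params, survival)
    tibble(x = x, total = fp$total_cost,
           healthy = fp$components[["healthy"]],
           acquired = fp$components[["acquired"]],
           treatment = fp$components[["treatment"]])
  })
  bind_rows(rows)
}
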