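#' Construct a cost-trajectory parameter set
#'
#' The four-parameter model for mean medical cost per month per capita
#' around disease onset is
#' \deqn{C(m) = c + (\delta + (P - \delta) e^{-r m}) I(m \ge 0)}
#' where `m` is the month relative to onset, `c` the pre-diagnosis plateau
#' (initial comorbidity, USD/month), `P` the cost of onset (USD), `r` the
#' population recovery rate (1/month) and `delta` the acquired comorbidity
#' (post- minus pre-onset plateau, USD/month). The degenerate `"step"`
#' variant \eqn{C(m) = c + P I(m \ge 0)} drops `r` and `delta` and is used
#' when the recovery slope is unidentifiable.
#'
#' @param c,P,r,delta Model parameters (see description). `r` and `delta`
#'   must be omitted (NA) for `variant = "step"`.
#' @param se Optional named numeric vector of standard errors
#'   (`c`, `P`, `r`, `delta`).
#' @param covariance Optional parameter covariance matrix.
#' @param variant `"full"` or `"step"`.
#' @return An object of class `cost_model_params`.
#' @export
#' @examples
#' achd <- cost_model_params(c = 815, P = 29842, r = 1.15, delta = 1005)
#' evaluate_cost(c(-3, 0, 20), achd)
cost_model_params <- function(c, P, r = NA_real_, delta = NA_real_,
                              se = NULL, covariance = NULL,
                              variant = c("full", "step")) {
  variant <- match.arg(variant)
  if (variant == "full" && (is.na(r) || is.na(delta))) {
    stop("variant 'full' requires r and delta", call. = FALSE)
  }
  if (variant == "step") {
    r <- NA_real_
    delta <- NA_real_
  }
  structure(list(c = as.numeric(c), P = as.numeric(P), r = as.numeric(r),
                 delta = as.numeric(delta), se = se,
                 covariance = covariance, variant = variant),
            class = "cost_model_params")
}

#' @export
print.cost_model_params <- function(x, ...) {
  cat(sprintf("<cost_model_params: %s>\n", x$variant))
  fmt <- function(nm) {
    v <- x[[nm]]
    s <- if (!is.null(x$se) && nm %in% names(x$se)) {
      sprintf(" (se %.4g)", x$se[[nm]])
    } else ""
    cat(sprintf("  %-5s %12.4f%s\n", nm, v, s))
  }
  fmt("c"); fmt("P")
  if (x$variant == "full") { fmt("r"); fmt("delta") }
  invisible(x)
}

#' Evaluate the cost-trajectory model
#'
#' @param m Integer (or numeric) vector of months relative to onset;
#'   negative months are pre-diagnosis.
#' @param params A [cost_model_params()] object (or a list with fields
#'   `c`, `P`, `r`, `delta`, `variant`).
#' @return Mean cost per month per capita (USD) at each `m`.
#' @export
evaluate_cost <- function(m, params) {
  if ((params$variant %||% "full") == "step") {
    return(params$c + params$P * (m >= 0))
  }
  params$c + (m >= 0) *
    (params$delta + (params$P - params$delta) * exp(-params$r * pmax(m, 0)))
}

#' Build a noiseless profile from model parameters
#'
#' Evaluates the model at months `-window..window` and attaches a nominal
#' per-month standard error, yielding a profile in the same shape that
#' [build_profile()] produces. Used for fixed-point fitting checks and for
#' simulating profile-level noise.
#'
#' @param params A [cost_model_params()].
#' @param se Per-month standard error attached to every point (default 1;
#'   a scalar or a length-41 vector).
#' @param window Half-width of the month window (default 20).
#' @param noise_sd If positive, adds independent Gaussian noise with this
#'   standard deviation (a scalar, or `"se"` to use the `se` values) to the
#'   profile means.
#' @return A profile tibble with columns `m`, `mean`, `se`, `n`.
#' @export
profile_from_params <- function(params, se = 1, window = 20, noise_sd = 0) {
  m <- seq(-window, window)
  se <- rep_len(se, length(m))
  mean <- evaluate_cost(m, params)
  if (identical(noise_sd, "se")) {
    mean <- mean + rnorm(length(m), 0, se)
  } else if (noise_sd > 0) {
    mean <- mean + rnorm(length(m), 0, noise_sd)
  }
  tibble(m = m, mean = mean, se = se, n = NA_integer_)
}

# Usable points for fitting/diagnostics: finite mean and (for weighted
# work) a positive finite se; months flagged by the profile builder
# (n_at_risk < 2 -> se NA) drop out here.
usable_points <- function(profile, need_se) {
  ok <- is.finite(profile$m) & is.finite(profile$mean)
  if (need_se) ok <- ok & is.finite(profile$se) & profile$se > 0
  profile[ok, , drop = FALSE]
}

fit_start_values <- function(d) {
  pre <- d$mean[d$m < 0]
  post <- d$mean[d$m >= 0]
  c0 <- if (length(pre)) mean(pre) else min(d$mean)
  at0 <- d$mean[d$m == 0]
  P0 <- if (length(at0)) at0[1] - c0 else max(post) - c0
  tail_mean <- mean(tail(post, max(3L, length(post) %/% 4L)))
  d0 <- tail_mean - c0
  list(c0 = c0, P0 = P0, d0 = d0)
}

#' Fit the four-parameter cost-trajectory model
#'
#' Minimises \eqn{\sum_i w_i (C_i - C(m_i))^2} over `(c, P, r, delta)` by
#' Levenberg-Marquardt nonlinear least squares with a fixed multi-start
#' grid of recovery-rate starting values (`r` is unconstrained in sign).
#' With inverse-variance weighting (`w_i = 1/se_i^2`, the default, matching
#' the chi-square diagnostic) parameter covariances are the unscaled
#' inverse normal-equations matrix; unweighted fits use the standard
#' residual-variance-scaled covariance.
#'
#' @param profile Profile tibble (`m`, `mean`, `se`, `n`), e.g. from
#'   [build_profile()] or [profile_from_params()].
#' @param weighting `"inverse_variance"` or `"unweighted"`.
#' @param r_starts Numeric grid of starting values for `r`.
#' @return A list with elements `params` ([cost_model_params()], fitted),
#'   `diagnostics` (list: `chi2_per_df`, `df`, `converged`,
#'   `n_restarts_used`, `rss`), and `fit` (the underlying `nls` object or
#'   NULL). If no start converges, `params` is NULL, `converged` is FALSE
#'   and `rss` carries the best residual sum reached.
#' @export
fit_full_model <- function(profile,
                           weighting = c("inverse_variance", "unweighted"),
                           r_starts = c(0.05, 0.2, 0.5, 1, 2)) {
  weighting <- match.arg(weighting)
  d <- usable_points(profile, need_se = weighting == "inverse_variance")
  if (nrow(d) < 5 || sum(d$m < 0) < 1 || sum(d$m >= 0) < 2) {
    stop("profile has too few usable points for the full model",
         call. = FALSE)
  }
  w <- if (weighting == "inverse_variance") 1 / d$se^2 else rep(1, nrow(d))
  post <- as.numeric(d$m >= 0)
  mp <- pmax(d$m, 0)
  y <- d$mean
  s <- fit_start_values(d)

  best <- NULL
  best_rss <- Inf
  n_tried <- 0L
  for (r0 in r_starts) {
    n_tried <- n_tried + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ cc + post * (dd + (PP - dd) * exp(-rr * mp)),
        start = list(cc = s$c0, PP = s$P0, rr = r0, dd = s$d0),
        weights = w,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = .Machine$double.eps,
          ptol = .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- deviance(fit)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }

  df <- nrow(d) - 4L
  if (is.null(best)) {
    return(list(params = NULL,
                diagnostics = list(chi2_per_df = NA_real_, df = df,
                                   converged = FALSE,
                                   n_restarts_used = n_tried,
                                   rss = best_rss),
                fit = NULL))
  }

  cf <- coef(best)
  if (weighting == "inverse_variance") {
    # the weights already carry the variances, so the covariance is the
    # unscaled inverse normal-equations matrix (J' W J)^-1; computing it
    # from the Jacobian avoids the 0/0 of rescaling vcov() on an exact
    # fit. nls stores the sqrt(w)-scaled Jacobian, so crossprod(J) is
    # already J' W J.
    J <- best$m$gradient()
    vc <- tryCatch(solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 4, 4))
  } else {
    vc <- suppressWarnings(vcov(best))
  }
  se <- sqrt(diag(vc))
  names(se) <- names(cf) <- c("c", "P", "r", "delta")
  dimnames(vc) <- list(names(cf), names(cf))
  params <- cost_model_params(c = cf[["c"]], P = cf[["P"]], r = cf[["r"]],
                              delta = cf[["delta"]], se = se,
                              covariance = vc, variant = "full")
  chi2 <- if (all(is.finite(d$se) & d$se > 0)) {
    sum((y - evaluate_cost(d$m, params))^2 / d$se^2) / df
  } else NA_real_
  list(params = params,
       diagnostics = list(chi2_per_df = chi2, df = df, converged = TRUE,
                          n_restarts_used = n_tried, rss = best_rss),
       fit = best)
}

#' Fit the degenerate step model
#'
#' Fits \eqn{C(m) = c + P I(m \ge 0)} by (weighted) least squares; this is
#' the fallback when the recovery slope `r` of the full model is
#' unidentifiable (post-onset curve flat, `P` close to `delta`).
#'
#' @inheritParams fit_full_model
#' @return Same structure as [fit_full_model()], with a `"step"` variant
#'   parameter set and `df = n - 2`.
#' @export
fit_step_model <- function(profile,
                           weighting = c("inverse_variance", "unweighted")) {
  weighting <- match.arg(weighting)
  d <- usable_points(profile, need_se = weighting == "inverse_variance")
  if (nrow(d) < 3 || sum(d$m < 0) < 1 || sum(d$m >= 0) < 1) {
    stop("profile has too few usable points for the step model",
         call. = FALSE)
  }
  w <- if (weighting == "inverse_variance") 1 / d$se^2 else rep(1, nrow(d))
  post <- as.numeric(d$m >= 0)
  fit <- lm(d$mean ~ post, weights = w)
  cf <- coef(fit)
  if (weighting == "inverse_variance") {
    X <- cbind(1, post)
    vc <- solve(crossprod(X * sqrt(w)))
  } else {
    vc <- suppressWarnings(vcov(fit))
  }
  se <- sqrt(diag(vc))
  names(cf) <- names(se) <- c("c", "P")
  dimnames(vc) <- list(names(cf), names(cf))
  params <- cost_model_params(c = cf[["c"]], P = cf[["P"]], se = se,
                              covariance = vc, variant = "step")
  df <- nrow(d) - 2L
  chi2 <- if (all(is.finite(d$se) & d$se > 0)) {
    sum((d$mean - evaluate_cost(d$m, params))^2 / d$se^2) / df
  } else NA_real_
  list(params = params,
       diagnostics = list(chi2_per_df = chi2, df = df, converged = TRUE,
                          n_restarts_used = 1L, rss = deviance(fit)),
       fit = fit)
}

#' Choose between the full and step model variants
#'
#' The step model is selected when the full fit failed to converge, or when
#' the recovery slope is unidentifiable: relative standard error
#' `se_r / |r|` above `rel_se_threshold`, or a non-positive slope estimate
#' with an undetermined acquired-comorbidity level.
#'
#' @param full_fit Result of [fit_full_model()].
#' @param rel_se_threshold Relative-SE cutoff for `r` (default 10).
#' @return `"full"` or `"step"`.
#' @export
select_model <- function(full_fit, rel_se_threshold = 10) {
  if (is.null(full_fit$params) || !isTRUE(full_fit$diagnostics$converged)) {
    return("step")
  }
  p <- full_fit$params
  se_r <- if (!is.null(p$se)) p$se[["r"]] else NA_real_
  se_d <- if (!is.null(p$se)) p$se[["delta"]] else NA_real_
  if (!is.finite(p$r) || !is.finite(se_r)) return("step")
  if (abs(p$r) < .Machine$double.eps) return("step")
  if (se_r / abs(p$r) > rel_se_threshold) return("step")
  if (p$r <= 0 && (!is.finite(se_d) || !is.finite(p$delta))) return("step")
  "full"
}

#' Fit a profile with automatic model selection
#'
#' Runs [fit_full_model()], applies [select_model()], and refits with
#' [fit_step_model()] when the recovery slope is unidentifiable.
#'
#' @inheritParams fit_full_model
#' @param rel_se_threshold Passed to [select_model()].
#' @return As [fit_full_model()], for the selected variant.
#' @export
fit_trajectory <- function(profile,
                           weighting = c("inverse_variance", "unweighted"),
                           rel_se_threshold = 10) {
  weighting <- match.arg(weighting)
  if (weighting == "inverse_variance") {
    # degenerate (e.g. noiseless) profiles carry no usable variances:
    # either too few positive ones, or only floating-point dust
    ok <- is.finite(profile$se) & profile$se > 0 & is.finite(profile$mean)
    scale <- suppressWarnings(max(abs(profile$mean), na.rm = TRUE))
    if (sum(ok) < 5 || max(profile$se[ok]) <= 1e-9 * scale) {
      weighting <- "unweighted"
    }
  }
  full <- tryCatch(fit_full_model(profile, weighting),
                   error = function(e) list(params = NULL,
                                            diagnostics = list(converged = FALSE)))
  if (select_model(full, rel_se_threshold) == "full") full
  else fit_step_model(profile, weighting)
}

#' Goodness of fit: chi-square per degree of freedom
#'
#' Computes \eqn{df^{-1} \sum_i (C_i - C(m_i))^2 / \sigma_i^2} over the
#' usable profile points, where `df` is the number of monthly points used
#' minus the number of model parameters (4 for the full model: 41 - 4 = 37
#' on a complete profile). Setting `aggregate_months = 2` pools adjacent
#' months into two-month groups (inverse-variance weighted means) before
#' computing the residual sum, the grouping used for display; the default
#' is the monthly sum.
#'
#' @param profile Profile tibble.
#' @param params Fitted [cost_model_params()].
#' @param aggregate_months 1 (monthly, default) or 2.
#' @return The chi-square per degree of freedom, with the degrees of
#'   freedom attached as attribute `"df"`.
#' @export
chi2_per_df <- function(profile, params, aggregate_months = 1) {
  d <- profile[is.finite(profile$mean), , drop = FALSE]
  if (any(!is.finite(d$se) | d$se <= 0)) {
    stop("chi2_per_df requires a positive standard error on every used point",
         call. = FALSE)
  }
  n_params <- if (params$variant == "step") 2L else 4L
  df <- nrow(d) - n_params
  if (df <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  if (aggregate_months > 1) {
    grp <- (d$m - min(d$m)) %/% aggregate_months
    w <- 1 / d$se^2
    model <- evaluate_cost(d$m, params)
    agg <- tibble(grp = grp, w = w, y = d$mean, mu = model) |>
      group_by(grp) |>
      summarise(y = sum(w * y) / sum(w),
                mu = sum(w * mu) / sum(w),
                se = sqrt(1 / sum(w)), .groups = "drop")
    chi2 <- sum((agg$y - agg$mu)^2 / agg$se^2)
  } else {
    chi2 <- sum((d$mean - evaluate_cost(d$m, params))^2 / d$se^2)
  }
  structure(chi2 / df, df = df)
}
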