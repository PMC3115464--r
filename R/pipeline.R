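#' Pipeline configuration
#'
#' Describes an end-to-end run: either a simulation config (synthetic
#' input) or a directory of `persons.csv` / `claims.csv` (and optionally
#' `cpi.csv`), plus the analysis knobs.
#'
#' @param simulation A [sim_config()], or `NULL` when reading files.
#' @param input_dir Directory with `persons.csv` and `claims.csv`, or
#'   `NULL` when simulating. Exactly one of `simulation` / `input_dir`
#'   must be supplied.
#' @param diseases Disease table (with `patterns` and, for simulated runs,
#'   generating truth); defaults to the simulation's disease table.
#' @param strata Character subset of
#'   `c("total", "disability", "charlson", "age", "survival")`.
#' @param weighting Fit weighting, `"inverse_variance"` or `"unweighted"`.
#' @param rel_se_threshold Model-selection threshold on `se_r / |r|`.
#' @param window Profile half-width in months (default 20).
#' @param horizon_years Incident-selection horizon (default 5).
#' @param interview_date Interview date (required for file input; taken
#'   from the simulation config otherwise).
#' @param forecast_months Forecast grid upper end in months (default 40).
#' @param seed Seed for the simulated run.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            input_dir = NULL,
                            diseases = NULL,
                            strata = "total",
                            weighting = c("inverse_variance", "unweighted"),
                            rel_se_threshold = 10,
                            window = 20,
                            horizon_years = 5,
                            interview_date = NULL,
                            forecast_months = 40,
                            seed = NULL,
                            out_dir = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(simulation) == is.null(input_dir)) {
    stop("supply exactly one of `simulation` or `input_dir`", call. = FALSE)
  }
  strata <- match.arg(strata,
                      c("total", "disability", "charlson", "age", "survival"),
                      several.ok = TRUE)
  if (!is.null(simulation)) {
    diseases <- diseases %||% simulation$diseases
    interview_date <- interview_date %||% simulation$interview_date
    seed <- seed %||% simulation$seed
  } else {
    if (is.null(interview_date)) {
      stop("interview_date is required for file input", call. = FALSE)
    }
    diseases <- diseases %||% disease_definition_list()
  }
  structure(list(simulation = simulation, input_dir = input_dir,
                 diseases = diseases, strata = strata, weighting = weighting,
                 rel_se_threshold = rel_se_threshold, window = window,
                 horizon_years = horizon_years,
                 interview_date = as.Date(interview_date),
                 forecast_months = forecast_months,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

read_population_dir <- function(dir) {
  persons <- read.csv(file.path(dir, "persons.csv"),
                      stringsAsFactors = FALSE) |> as_tibble()
  claims <- read.csv(file.path(dir, "claims.csv"),
                     stringsAsFactors = FALSE) |> as_tibble()
  for (col in c("birth_date", "interview_date", "death_date",
                "enrollment_start", "enrollment_end")) {
    if (col %in% names(persons)) persons[[col]] <- as.Date(persons[[col]])
  }
  claims$service_date <- as.Date(claims$service_date)
  cpi_path <- file.path(dir, "cpi.csv")
  cpi <- if (file.exists(cpi_path)) cpi_series(read.csv(cpi_path)) else
    default_medical_cpi()
  list(persons = persons, claims = claims, cpi = cpi)
}

estimates_row <- function(disease, stratum, fitres, n_persons) {
  p <- fitres$params
  d <- fitres$diagnostics
  if (is.null(p)) {
    return(tibble(disease = disease, stratum = stratum, variant = "failed",
                  c = NA_real_, se_c = NA_real_, P = NA_real_,
                  se_P = NA_real_, r = NA_real_, se_r = NA_real_,
                  delta = NA_real_, se_delta = NA_real_,
                  chi2_per_df = NA_real_, df = d$df %||% NA_integer_,
                  n_persons = n_persons))
  }
  getse <- function(nm) if (!is.null(p$se) && nm %in% names(p$se))
    p$se[[nm]] else NA_real_
  tibble(disease = disease, stratum = stratum, variant = p$variant,
         c = p$c, se_c = getse("c"), P = p$P, se_P = getse("P"),
         r = p$r, se_r = getse("r"), delta = p$delta,
         se_delta = getse("delta"),
         chi2_per_df = d$chi2_per_df %||% NA_real_, df = d$df,
         n_persons = n_persons)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the population, detect onsets per disease
#' (prevalence exclusion, two-record rule, incident selection), build
#' stratified 41-point profiles, fit the trajectory model with automatic
#' step-model fallback, and forecast population cost under a constant
#' onset hazard. When `out_dir` is set, writes `persons.csv`,
#' `claims.csv`, `ground_truth.json` (simulated runs), `onsets.csv`,
#' `profiles.csv`, `estimates.csv`, `forecast.csv` and `run.log`.
#'
#' @param config A [pipeline_config()].
#' @return A list with `onsets`, `profiles`, `estimates`, `forecast`,
#'   `strata`, and (simulated runs) `population`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    pop <- simulate_population(config$simulation, seed = config$seed)
    persons <- pop$persons
    claims <- pop$claims
    cpi <- config$simulation$cpi
  } else {
    pop <- NULL
    inp <- read_population_dir(config$input_dir)
    persons <- inp$persons
    claims <- inp$claims
    cpi <- inp$cpi
  }
  interview <- config$interview_date
  dis <- config$diseases

  onsets_all <- list()
  profiles_all <- list()
  estimates_all <- list()
  forecast_all <- list()
  strata_all <- list()

  for (i in seq_len(nrow(dis))) {
    d <- dis[i, ]
    eligible <- exclude_prevalent(persons, claims, d, interview)
    onsets <- detect_onsets(claims, d)
    cohort <- select_incident_cohort(eligible, onsets, d, interview,
                                     config$horizon_years)
    onsets_all[[d$disease]] <- cohort
    if (nrow(cohort) < 5) next

    strat <- stratify(cohort, persons, claims, interview)
    strata_all[[d$disease]] <- strat |> mutate(disease = d$disease)
    mc <- cohort_month_costs(claims, persons, cohort, config$window, cpi)

    for (var in config$strata) {
      for (lev in unique(strat[[var]])) {
        ids <- strat$person_id[strat[[var]] == lev]
        if (length(ids) < 5) next
        label <- if (var == "total") "total" else paste0(var, ":", lev)
        prof <- tryCatch(
          build_profile(mc |> filter(person_id %in% ids),
                        disease = d$disease, stratum = label),
          error = function(e) NULL)
        if (is.null(prof)) next
        profiles_all[[paste(d$disease, label)]] <- prof
        fitres <- tryCatch(
          fit_trajectory(prof, config$weighting, config$rel_se_threshold),
          error = function(e) list(params = NULL,
                                   diagnostics = list(df = NA_integer_)))
        estimates_all[[paste(d$disease, label)]] <-
          estimates_row(d$disease, label, fitres, length(ids))
        if (label == "total" && !is.null(fitres$params) &&
            fitres$params$variant == "full") {
          h <- col_or(d, "onset_hazard", NA_real_)[1]
          if (is.finite(h) && h > 0) {
            fc <- forecast_curve(seq(0, config$forecast_months),
                                 fitres$params, constant_hazard_survival(h))
            forecast_all[[d$disease]] <- fc |> mutate(disease = d$disease,
                                                      h = h)
          }
        }
      }
    }
  }

  onsets <- bind_rows(onsets_all)
  profiles <- bind_rows(profiles_all)
  estimates <- bind_rows(estimates_all)
  forecast <- bind_rows(forecast_all)
  strata <- bind_rows(strata_all)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(pop)) write_population(pop, config$out_dir)
    write.csv(onsets, file.path(config$out_dir, "onsets.csv"),
              row.names = FALSE)
    write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
              row.names = FALSE)
    write.csv(estimates, file.path(config$out_dir, "estimates.csv"),
              row.names = FALSE)
    write.csv(forecast, file.path(config$out_dir, "forecast.csv"),
              row.names = FALSE)
    log_lines <- c(
      sprintf("costtraj %s", as.character(packageVersion("costtraj"))),
      sprintf("seed: %s", config$seed %||% "none"),
      sprintf("interview_date: %s", interview),
      sprintf("confirm window: gap <= %.3f days (0.3 years)",
              CONFIRM_WINDOW_DAYS),
      "month binning: calendar-month offsets, onset month = m 0",
      "censoring: months strictly after the death month are not at risk",
      sprintf("weighting: %s", config$weighting),
      sprintf("model selection: step when se_r/|r| > %g",
              config$rel_se_threshold),
      sprintf("strata: %s", paste(config$strata, collapse = ", ")))
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }

  out <- list(onsets = onsets, profiles = profiles, estimates = estimates,
              forecast = forecast, strata = strata)
  if (!is.null(pop)) out$population <- pop
  invisible(out)
}

#' Plot empirical profiles with fitted curves
#'
#' One panel per disease: dots are the per-month empirical means with
#' standard-error bars (aggregated into two-month groups for display),
#' the line is the fitted trajectory model, and each panel is annotated
#' with its chi-square per degree of freedom.
#'
#' @param profiles Profile tibble (stratum `"total"` rows are used).
#' @param estimates Estimates tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, estimates) {
  prof <- profiles |> filter(stratum == "total")
  est <- estimates |> filter(stratum == "total")
  if (!setequal(unique(prof$disease), unique(est$disease))) {
    stop("profiles and estimates cover different disease sets",
         call. = FALSE)
  }
  dots <- prof |>
    filter(is.finite(mean)) |>
    mutate(grp = (m - min(m)) %/% 2) |>
    group_by(disease, grp) |>
    summarise(m = mean(m),
              se_g = sqrt(sum(se^2)) / dplyr::n(),
              mean = mean(mean),
              .groups = "drop")
  grid <- expand.grid(disease = unique(est$disease),
                      m = seq(min(prof$m), max(prof$m), by = 0.05))
  lines <- grid |>
    left_join(est, by = "disease") |>
    mutate(fit = ifelse(variant == "step",
                        c + P * (m >= 0),
                        c + (m >= 0) * (delta + (P - delta) *
                                          exp(-r * pmax(m, 0)))))
  ann <- est |>
    mutate(label = sprintf("chi2/df = %.2f", chi2_per_df))
  ggplot2::ggplot(dots, ggplot2::aes(x = m, y = mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se_g,
                                        ymax = mean + se_g),
                           width = 0.4, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = lines, ggplot2::aes(y = fit),
                       colour = "steelblue") +
    ggplot2::geom_text(data = ann,
                       ggplot2::aes(x = Inf, y = Inf, label = label),
                       hjust = 1.1, vjust = 1.5, size = 2.8,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~disease, scales = "free_y") +
    ggplot2::labs(x = "months since onset",
                  y = "cost per month per capita (year-2000 USD)") +
    ggplot2::theme_minimal(base_size = 9)
}
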