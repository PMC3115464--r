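iv <- as.Date("1994-10-01")

test_that("the Charlson index maps codes to weighted condition groups", {
  # empty window is a valid zero
  expect_equal(charlson_index(make_claims(character(0), character(0),
                                          character(0)), "p1", iv), 0L)
  # MI + uncomplicated diabetes: both weight 1
  cl <- make_claims(c("1994-05-01", "1994-06-01"),
                    c("inpatient", "physician"), c("410", "25000"))
  expect_equal(charlson_index(cl, "p1", iv), 2)
  # metastatic solid tumour alone: weight 6
  cl2 <- make_claims("1994-05-01", "physician", "1970")
  expect_equal(charlson_index(cl2, "p1", iv), 6)
  # secondary diagnoses count
  cl3 <- make_claims("1994-05-01", "carrier", "4019",
                     secondary = "42800|5855")
  expect_equal(charlson_index(cl3, "p1", iv), 3)  # CHF 1 + renal 2
})

test_that("Charlson hierarchy rules apply", {
  # metastatic supersedes malignancy: 6, not 8
  cl <- make_claims(c("1994-03-01", "1994-04-01"),
                    c("inpatient", "inpatient"), c("1970", "1629"))
  expect_equal(charlson_index(cl, "p1", iv), 6)
  # complicated supersedes uncomplicated diabetes: 2, not 3
  cl2 <- make_claims(c("1994-03-01", "1994-04-01"),
                     c("physician", "physician"), c("2504", "2500"))
  expect_equal(charlson_index(cl2, "p1", iv), 2)
  # moderate/severe liver supersedes mild: 3, not 4
  cl3 <- make_claims(c("1994-03-01", "1994-04-01"),
                     c("physician", "physician"), c("5722", "5715"))
  expect_equal(charlson_index(cl3, "p1", iv), 3)
  # each group counts once
  cl4 <- make_claims(c("1994-03-01", "1994-04-01"),
                     c("inpatient", "inpatient"), c("410", "412"))
  expect_equal(charlson_index(cl4, "p1", iv), 1)
})

test_that("the Charlson lookback window is [index - 365, index)", {
  cl <- make_claims(c("1994-10-01", "1993-10-01", "1993-09-30"),
                    rep("physician", 3), rep("410", 3))
  # claim on the index date itself is outside the window
  expect_equal(charlson_index(cl[1, ], "p1", iv), 0)
  # exactly 365 days before is inside
  expect_equal(charlson_index(cl[2, ], "p1", iv), 1)
  # 366 days before is outside
  expect_equal(charlson_index(cl[3, ], "p1", iv), 0)
})

test_that("vectorized Charlson scoring matches the per-person index", {
  cfg <- sim_config(n_persons = 120, seed = 17)
  pop <- simulate_population(cfg)
  ids <- pop$persons$person_id[1:40]
  vec <- costtraj:::charlson_scores(pop$claims, ids, iv)
  for (k in seq_along(ids)) {
    expect_equal(vec$charlson[k], charlson_index(pop$claims, ids[k], iv))
  }
})

test_that("charlson_category bins 0/1/2/>2", {
  expect_equal(charlson_category(c(0, 1, 2, 3, 6)),
               c("0", "1", "2", ">2", ">2"))
})

test_that("disability_category implements the three-level index", {
  expect_equal(disability_category(0, FALSE), "nondisabled")
  expect_equal(disability_category(2, FALSE), "IADL only or/and 1-2 ADLs")
  expect_equal(disability_category(0, TRUE), "IADL only or/and 1-2 ADLs")
  expect_equal(disability_category(4, TRUE), "3-6 ADLs")  # (iii) precedence
  expect_equal(disability_category(3, FALSE), "3-6 ADLs")
  expect_error(disability_category(7, FALSE), "0..6")
})

test_that("CPI adjustment is the base-year ratio and inverts cleanly", {
  expect_equal(adjust_to_2000_dollars(100, 2000), 100)
  toy <- cpi_series(data.frame(year = c(2000, 2003),
                               index = c(100, 200)))
  expect_equal(adjust_to_2000_dollars(100, 2003, toy), 50)
  # round trip through nominal dollars
  x <- c(12.5, 900, 1e5)
  nom <- costtraj:::to_nominal_dollars(x, 1995)
  expect_equal(adjust_to_2000_dollars(nom, 1995), x, tolerance = 1e-12)
  # idempotence: already-adjusted amounts pass through at the base year
  expect_equal(adjust_to_2000_dollars(
    adjust_to_2000_dollars(100, 1994), 2000), adjust_to_2000_dollars(100, 1994))
  expect_error(adjust_to_2000_dollars(100, 1890), "missing")
})

test_that("person_month_costs bins claims on calendar-month offsets", {
  person <- tibble::tibble(person_id = "p1", death_date = as.Date(NA),
                           enrollment_start = as.Date("1991-01-01"),
                           enrollment_end = as.Date("2001-12-31"))
  onset <- as.Date("1996-06-15")
  # no claims: 41 real zero-cost months, all at risk
  pm0 <- person_month_costs(make_claims(character(0), character(0),
                                        character(0)), person, onset)
  expect_equal(nrow(pm0), 41)
  expect_true(all(pm0$at_risk))
  expect_true(all(pm0$cost == 0))
  # a claim on 1996-06-01 and one on 1996-07-31 land in m = 0 and m = 1
  cl <- make_claims(c("1996-06-01", "1996-07-31"), rep("carrier", 2),
                    rep("4019", 2))
  cl$paid_amount <- c(100, 50)
  pm <- person_month_costs(cl, person, onset)
  expect_equal(pm$cost[pm$m == 0],
               adjust_to_2000_dollars(100, 1996))
  expect_equal(pm$cost[pm$m == 1],
               adjust_to_2000_dollars(50, 1996))
})

test_that("right censoring frees months strictly after the death month", {
  person <- tibble::tibble(person_id = "p1",
                           death_date = as.Date("1996-09-20"),
                           enrollment_start = as.Date("1991-01-01"),
                           enrollment_end = as.Date("1996-09-20"))
  onset <- as.Date("1996-06-15")  # death 3 months after onset
  pm <- person_month_costs(make_claims(character(0), character(0),
                                       character(0)), person, onset)
  expect_true(all(pm$at_risk[pm$m <= 3]))
  expect_false(any(pm$at_risk[pm$m >= 4]))
  expect_true(all(is.na(pm$cost[pm$m >= 4])))
})

test_that("a noiseless simulated person reproduces the model exactly", {
  cfg <- achd_only_config(40, noise_sd = 0, hazard = 0.08, seed = 23)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  cand <- gt[!is.na(gt$disease) & is.na(gt$death_date), ]
  pid <- cand$person_id[1]
  person <- pop$persons[pop$persons$person_id == pid, ]
  pm <- person_month_costs(pop$claims, person, cand$onset_date[1],
                           cpi = cfg$cpi)
  at <- pm[pm$at_risk, ]
  expect_equal(at$cost, evaluate_cost(at$m, achd_truth()), tolerance = 1e-9)
})

test_that("build_profile produces 41 calibrated points", {
  cfg <- achd_only_config(500, noise_sd = 100, hazard = 1, seed = 29)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  cohort <- tibble::tibble(person_id = gt$person_id,
                           onset_date = gt$onset_date)
  mc <- cohort_month_costs(pop$claims, pop$persons, cohort, cpi = cfg$cpi)
  prof <- build_profile(mc, disease = "achd")
  expect_equal(nrow(prof), 41)
  expect_equal(prof$m, -20:20)
  pre <- prof[prof$m < 0, ]
  expect_true(all(abs(pre$mean - 815) < 3 * pre$se + 1e-9))
  # single person: profile reproduces the series exactly
  one <- mc[mc$person_id == cohort$person_id[1] & mc$at_risk, ]
  prof1 <- build_profile(one)
  expect_equal(prof1$mean[prof1$n == 1],
               one$cost[match(prof1$m[prof1$n == 1], one$m)])
  # empty stratum errors
  expect_error(build_profile(mc[0, ]), "empty stratum")
})

test_that("identical noiseless persons give zero-variance flagged months", {
  pm <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(id) {
    tibble::tibble(person_id = id, m = -20:20,
                   cost = evaluate_cost(-20:20, achd_truth()),
                   at_risk = TRUE)
  }))
  prof <- build_profile(pm)
  expect_equal(prof$mean, evaluate_cost(-20:20, achd_truth()))
  expect_true(all(prof$se < 1e-9))
  # degenerate variances: fit_trajectory falls back to an unweighted fit
  # and still recovers the generating parameters
  prof$se <- 0
  fit <- fit_trajectory(prof)
  expect_equal(fit$params$r, 1.15, tolerance = 1e-6)
})

test_that("earlier deaths never increase total at-risk months", {
  cfg <- achd_only_config(100, noise_sd = 0, hazard = 0.08, seed = 37,
                          death_hazard_post_onset = 0.05)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  cohort <- tibble::tibble(person_id = gt$person_id[!is.na(gt$disease)],
                           onset_date = gt$onset_date[!is.na(gt$disease)])
  base <- cohort_month_costs(pop$claims, pop$persons, cohort, cpi = cfg$cpi)
  persons2 <- pop$persons
  dying <- !is.na(persons2$death_date)
  persons2$death_date[dying] <- persons2$death_date[dying] - 90
  persons2$enrollment_end[dying] <- pmin(persons2$enrollment_end[dying],
                                         persons2$death_date[dying])
  moved <- cohort_month_costs(pop$claims, persons2, cohort, cpi = cfg$cpi)
  expect_lt(sum(moved$at_risk), sum(base$at_risk))
})

test_that("stratification partitions the cohort on every variable", {
  cfg <- sim_config(n_persons = 600, seed = 41)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  cohort <- tibble::tibble(person_id = gt$person_id[!is.na(gt$disease)],
                           onset_date = gt$onset_date[!is.na(gt$disease)])
  strat <- stratify(cohort, pop$persons, pop$claims, cfg$interview_date)
  expect_equal(nrow(strat), nrow(cohort))
  expect_setequal(strat$person_id, cohort$person_id)
  for (var in c("total", "disability", "charlson", "age", "survival")) {
    expect_false(anyNA(strat[[var]]))  # exhaustive
  }
  expect_true(all(strat$disability %in%
                    c("nondisabled", "IADL only or/and 1-2 ADLs",
                      "3-6 ADLs")))
  expect_true(all(strat$charlson %in% c("0", "1", "2", ">2")))
  # survival strata union the cohort
  expect_setequal(strat$person_id[strat$survival %in%
                                    c("died", "survived")],
                  cohort$person_id)
})

test_that("age at diagnosis splits at 80 inclusive and survival at 913 days", {
  persons <- tibble::tibble(
    person_id = c("a", "b", "c", "d"),
    birth_date = as.Date("1916-06-15"),
    death_date = as.Date(c(NA, NA, "1998-12-13", "1998-12-14")),
    n_adl = 0L, has_iadl = FALSE)
  onset <- as.Date("1996-06-15")
  cohort <- tibble::tibble(person_id = persons$person_id,
                           onset_date = onset)
  # exactly 80.0 years at onset -> "<=80"; death at 912/913 days -> died
  claims <- make_claims(character(0), character(0), character(0))
  strat <- stratify(cohort, persons, claims, iv)
  expect_equal(unique(strat$age), "<=80")
  expect_equal(strat$survival, c("survived", "survived", "died", "died"))
  # 914 days is a survivor
  persons$death_date[3] <- onset + 914
  strat2 <- stratify(cohort, persons, claims, iv)
  expect_equal(strat2$survival[3], "survived")
})
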