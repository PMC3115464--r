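test_that("disease presets carry the twelve generating quadruples", {
  pre <- disease_presets()
  expect_equal(nrow(pre), 12)
  achd <- pre[pre$disease == "achd", ]
  expect_equal(c(achd$c, achd$P, achd$r, achd$delta),
               c(815, 29842, 1.15, 1005))
  expect_equal(pre$sex_restriction[pre$disease == "breast_cancer"], "female")
  expect_equal(pre$sex_restriction[pre$disease == "prostate_cancer"], "male")
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_persons = 0), "n_persons")
  expect_error(sim_config(prevalent_fraction = 1.2), "prevalent_fraction")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(confirm_delay_days = c(0, 10)),
               "confirm_delay_days")
  expect_error(sim_config(death_hazard_post_onset = 2),
               "death_hazard_post_onset")
  expect_error(sim_config(background_condition_rates = c(bogus = 0.1)),
               "background_condition_rates")
})

test_that("simulate_cost_series reproduces the trajectory model", {
  truth <- achd_truth()
  # no onset, no noise: constant at c
  s <- simulate_cost_series(truth, onset_month = NA, n_months = 10)
  expect_equal(s$cost, rep(815, 10))
  # onset month carries c + P
  s2 <- simulate_cost_series(truth, onset_month = 5, n_months = 41)
  expect_equal(s2$cost[s2$month == 5], 815 + 29842)
  expect_equal(s2$cost[s2$month < 5], rep(815, 5))
  # tail approaches c + delta within the closed-form bound
  tail_val <- s2$cost[s2$month == 25]  # 20 months post onset
  expect_lt(abs(tail_val - (815 + 1005)),
            exp(-1.15 * 20) * (29842 - 1005) + 1e-9)
  # months after death are absent, not zero-filled
  s3 <- simulate_cost_series(truth, onset_month = 5, death_month = 8,
                             n_months = 41)
  expect_equal(max(s3$month), 8)
  expect_equal(nrow(s3), 9)
  # death before the first month yields an empty series
  s4 <- simulate_cost_series(truth, onset_month = 5, death_month = -1,
                             n_months = 41)
  expect_equal(nrow(s4), 0)
})

test_that("emit_claims produces role-consistent records", {
  person <- list(person_id = "p1", interview_date = as.Date("1994-10-01"))
  onset <- as.Date("1996-03-10")

  inc <- emit_claims(person, "achd", onset, confirm_delay_days = 60,
                     role = "incident")
  expect_equal(nrow(inc), 2)
  expect_true(all(inc$source %in% qualifying_sources))
  expect_equal(find_onset(inc, "achd")$onset_date, onset)

  # a 150-day confirmation gap exceeds 0.3 years -> no onset downstream
  late <- emit_claims(person, "achd", onset, confirm_delay_days = 150,
                      role = "incident")
  expect_null(find_onset(late, "achd"))

  single <- emit_claims(person, "achd", onset, role = "single_record")
  expect_equal(nrow(single), 1)
  expect_null(find_onset(single, "achd"))

  expect_error(emit_claims(person, "achd", onset, confirm_delay_days = 0,
                           role = "incident"), "different date")

  prev <- emit_claims(person, "achd", as.Date("1993-05-01"),
                      confirm_delay_days = 30, role = "prevalent")
  expect_true(all(prev$service_date < person$interview_date))
  expect_error(emit_claims(person, "achd", as.Date("1994-09-25"),
                           confirm_delay_days = 30, role = "prevalent"),
               "before the interview")
})

test_that("identical config and seed give byte-identical tables", {
  cfg <- sim_config(n_persons = 80, seed = 42)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$claims, b$claims)
  c <- simulate_population(cfg, seed = 43)
  expect_false(identical(a$claims, c$claims))
})

test_that("zero hazards and zero noise give flat disease-free costs", {
  dis <- disease_presets(onset_hazard = 0)
  cfg <- sim_config(n_persons = 25, seed = 3, diseases = dis, noise_sd = 0,
                    background_condition_rates = c(mi = 0)[0])
  pop <- simulate_population(cfg)
  monthly <- pop$claims |>
    dplyr::mutate(cost = adjust_to_2000_dollars(paid_amount, claim_year,
                                                cfg$cpi)) |>
    dplyr::group_by(person_id, mi = format(service_date, "%Y-%m")) |>
    dplyr::summarise(cost = sum(cost), .groups = "drop")
  expect_true(all(abs(monthly$cost - cfg$baseline_cost) < 1e-9))
  expect_true(all(is.na(pop$ground_truth$persons$onset_date)))
})

test_that("noiseless claims aggregate exactly to the trajectory model", {
  cfg <- achd_only_config(60, noise_sd = 0, hazard = 0.05, seed = 9)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  onset_people <- gt[!is.na(gt$disease), ]
  expect_gt(nrow(onset_people), 5)
  truth <- achd_truth()
  for (k in head(seq_len(nrow(onset_people)), 10)) {
    pid <- onset_people$person_id[k]
    omi <- costtraj:::month_index(onset_people$onset_date[k])
    monthly <- pop$claims |>
      dplyr::filter(person_id == pid) |>
      dplyr::mutate(m = costtraj:::month_index(service_date) - omi,
                    cost = adjust_to_2000_dollars(paid_amount, claim_year,
                                                  cfg$cpi)) |>
      dplyr::group_by(m) |>
      dplyr::summarise(cost = sum(cost), .groups = "drop")
    expect_equal(monthly$cost, evaluate_cost(monthly$m, truth),
                 tolerance = 1e-9)
  }
  # pre-onset plateau is exactly the preset c = 815
  pre <- onset_people$plateau
  expect_true(all(pre == 815))
})

test_that("no claim postdates its person's death", {
  cfg <- sim_config(n_persons = 300, seed = 8,
                    death_hazard_post_onset = 0.05)
  pop <- simulate_population(cfg)
  j <- dplyr::left_join(pop$claims,
                        pop$persons[, c("person_id", "death_date")],
                        by = "person_id")
  expect_equal(sum(!is.na(j$death_date) & j$service_date > j$death_date), 0)
  # enrollment bounds hold too
  j2 <- dplyr::left_join(pop$claims,
                         pop$persons[, c("person_id", "enrollment_start",
                                         "enrollment_end")],
                         by = "person_id")
  expect_true(all(j2$service_date >= j2$enrollment_start))
  expect_true(all(j2$service_date <= j2$enrollment_end))
})

test_that("sampled monthly means agree with the generating plateau", {
  # everyone onsets in month 1 (hazard 1), so all 500 persons contribute
  # an enrolled month -10
  cfg <- achd_only_config(500, noise_sd = 100, hazard = 1, seed = 12)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  omi <- costtraj:::month_index(gt$onset_date)
  monthly <- pop$claims |>
    dplyr::mutate(cost = adjust_to_2000_dollars(paid_amount, claim_year,
                                                cfg$cpi),
                  m = costtraj:::month_index(service_date) -
                    omi[match(person_id, gt$person_id)]) |>
    dplyr::filter(m == -10) |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(cost = sum(cost), .groups = "drop")
  # persons who turn 65 after month -10 are not yet enrolled there
  n <- nrow(monthly)
  expect_gte(n, 450)
  expect_lt(abs(mean(monthly$cost) - 815), 3 * 100 / sqrt(n))
})

test_that("prevalent contamination is excluded at the configured rate", {
  cfg <- achd_only_config(1200, noise_sd = 0, hazard = 1, seed = 21,
                          prevalent_fraction = 0.1,
                          single_record_fraction = 0)
  pop <- simulate_population(cfg)
  kept <- exclude_prevalent(pop$persons, pop$claims, "achd",
                            cfg$interview_date)
  # binomial 3-sigma band around 90% retention (background conditions do
  # not collide with the achd codes)
  p_kept <- nrow(kept) / nrow(pop$persons)
  expect_lt(abs(p_kept - 0.9), 3 * sqrt(0.9 * 0.1 / nrow(pop$persons)))
  gt <- pop$ground_truth$persons
  expect_true(all(!gt$person_id[gt$role %in% "prevalent"] %in%
                    kept$person_id))
})

test_that("onset detection recovers nearly all clean simulated onsets", {
  cfg <- sim_config(n_persons = 1000, seed = 31, prevalent_fraction = 0,
                    single_record_fraction = 0)
  pop <- simulate_population(cfg)
  gt <- pop$ground_truth$persons
  truth <- gt[!is.na(gt$disease), ]
  recovered <- 0L
  for (dz in unique(truth$disease)) {
    ons <- detect_onsets(pop$claims, dz)
    tt <- truth[truth$disease == dz, ]
    m <- merge(tt, ons, by = "person_id")
    recovered <- recovered + sum(as.Date(m$onset_date.x) == m$onset_date.y)
  }
  expect_gte(recovered / nrow(truth), 0.99)
})

test_that("write_population emits readable CSV/JSON", {
  cfg <- sim_config(n_persons = 20, seed = 2)
  pop <- simulate_population(cfg)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  expect_setequal(list.files(dir),
                  c("persons.csv", "claims.csv", "ground_truth.json"))
  p2 <- read.csv(file.path(dir, "persons.csv"))
  expect_equal(nrow(p2), 20)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt$persons), 20)
})
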