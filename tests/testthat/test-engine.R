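neutral_cfg <- risk_config(rr_incidence_per10 = 1, rr_case_fatality_per10 = 1,
                           rr_allcause_per10 = 1, depr_ratio_male = 1,
                           depr_ratio_female = 1)

test_that("initialization seeds the prevalent pool from the baseline tables", {
  prof <- uniform_profile(500, age = 62, sex = "male")
  all_h1 <- initialize_population(prof, const_tables(prevalence = 0), seed = 1)
  expect_true(all(all_h1$state == 1L))
  all_h2 <- initialize_population(prof, const_tables(prevalence = 99000), seed = 1)
  # prevalence probability 0.99: essentially the whole stratum starts diseased
  expect_gt(mean(all_h2$state == 2L), 0.95)

  big <- uniform_profile(10000, age = 60, sex = "male")
  coh <- initialize_population(big, const_tables(prevalence = 10000), seed = 3)
  expect_lt(abs(sum(coh$state == 2L) - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_error(initialize_population(uniform_profile(0), const_tables()),
               "empty")
})

test_that("zero transition probabilities leave the cohort untouched except aging", {
  prof <- uniform_profile(300, age = 20)
  tallies <- run_simulation(prof, const_tables(), neutral_cfg,
                            horizon_years = 10, seed = 1)
  expect_equal(sum(tallies$n_deaths_allcause), 0)
  expect_equal(sum(tallies$n_incident), 0)
  yearly <- aggregate_tallies(tallies, "year")
  expect_true(all(yearly$n_alive == 300))
  # the cohort of 20-year-olds appears in band 25-29 by year 6
  y6 <- tallies[tallies$year == 6 & tallies$n_population > 0, ]
  expect_equal(y6$age_group, "25-29")
})

test_that("certain mortality empties the cohort in the first year", {
  prof <- uniform_profile(400, age = 50)
  tallies <- run_simulation(prof, const_tables(allcause_mortality = 1e5),
                            neutral_cfg, horizon_years = 3, seed = 2)
  y1 <- aggregate_tallies(tallies[tallies$year == 1, ], "year")
  expect_equal(y1$n_deaths_allcause, y1$n_population)
  expect_equal(y1$n_deaths_allcause, 400)
  expect_equal(sum(tallies$n_population[tallies$year > 1]), 0)
})

test_that("pure incidence accumulates prevalence along the geometric closed form", {
  n <- 20000
  prof <- uniform_profile(n, age = 30)
  tallies <- run_simulation(prof, const_tables(incidence = 1000),
                            neutral_cfg, horizon_years = 10, seed = 5)
  p10 <- 1 - 0.99^10
  got <- sum(tallies$n_prevalent[tallies$year == 10])
  expect_lt(abs(got - n * p10), 3 * sqrt(n * p10 * (1 - p10)))
})

test_that("newly incident individuals can die of the disease in the incidence year", {
  # no prevalent pool at init is impossible with positive disease mortality,
  # so start from a small one; high incidence and high case fatality make
  # same-year incidence deaths near-certain under the diseased-state rule
  tabs <- const_tables(incidence = 90000, prevalence = 1000,
                       disease_mortality = 900, allcause_mortality = 1000)
  prof <- uniform_profile(2000, age = 40)
  cfg_dis <- neutral_cfg
  tallies <- run_simulation(prof, tabs, cfg_dis, horizon_years = 1, seed = 9)
  expect_gt(sum(tallies$n_deaths_disease), 0)
  expect_true(sum(tallies$n_deaths_disease) <= sum(tallies$n_deaths_allcause))

  # under the healthy-state rule the same seed produces fewer or equal deaths
  cfg_h <- risk_config(rr_incidence_per10 = 1, rr_case_fatality_per10 = 1,
                       rr_allcause_per10 = 1, depr_ratio_male = 1,
                       depr_ratio_female = 1,
                       incident_year_mortality = "healthy")
  tallies_h <- run_simulation(prof, tabs, cfg_h, horizon_years = 1, seed = 9)
  expect_lte(sum(tallies_h$n_deaths_allcause), sum(tallies$n_deaths_allcause))
})

test_that("births follow the fertility rate applied to women 15-44 at year end", {
  prof <- uniform_profile(1000, age = 29, sex = "female", gfr = 60)
  coh <- initialize_population(prof, const_tables(), seed = 1)
  set.seed(42)
  res <- apply_births(coh, prof, 1, risk_config())
  nb <- sum(res$n_births)
  expect_lt(abs(nb - 60), 3 * sqrt(1000 * 0.06 * 0.94))
  expect_equal(sum(res$cohort$age == 0L), nb)
  expect_true(all(res$cohort$state[res$cohort$age == 0L] == 1L))

  no_gfr <- uniform_profile(1000, age = 29, sex = "female", gfr = 0)
  expect_equal(sum(apply_births(coh, no_gfr, 1, risk_config())$n_births), 0)
  men <- initialize_population(uniform_profile(1000, age = 29, sex = "male",
                                               gfr = 60), const_tables(),
                               seed = 1)
  expect_equal(sum(apply_births(men, prof, 1, risk_config())$n_births), 0)
  bad <- uniform_profile(10, age = 29, sex = "female", gfr = 1200)
  expect_error(apply_births(coh, bad, 1, risk_config()), "gfr")
})

test_that("runs are bitwise reproducible and areas use independent streams", {
  cfg <- synth_config(n_areas = 3, mean_pop_per_area = 400, seed = 2)
  profiles <- generate_area_profiles(cfg)
  tables <- generate_rate_tables(2)
  a <- run_city(profiles, tables, risk_config(), NULL, 12, seed = 31)
  b <- run_city(profiles, tables, risk_config(), NULL, 12, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- run_city(profiles, tables, risk_config(), NULL, 12, seed = 32)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
  expect_false(area_seed(31, "A0001") == area_seed(31, "A0002"))
})

test_that("population is conserved year over year: alive plus births carries forward", {
  cfg <- synth_config(n_areas = 4, mean_pop_per_area = 600, seed = 6)
  profiles <- generate_area_profiles(cfg)
  tables <- generate_rate_tables(6)
  tallies <- run_city(profiles, tables, risk_config(), NULL, 15, seed = 8)
  for (aid in names(profiles)) {
    ta <- tallies[tallies$area_id == aid, ]
    yearly <- aggregate_tallies(ta, "year")
    expect_equal(yearly$n_alive, yearly$n_population - yearly$n_deaths_allcause)
    expect_equal(yearly$n_population[-1],
                 (yearly$n_alive + yearly$n_births)[-nrow(yearly)])
  }
  # stratum-level invariants
  expect_true(all(tallies$n_prevalent <= tallies$n_alive))
  expect_true(all(tallies$n_deaths_allcause <= tallies$n_population))
  expect_true(all(tallies$n_deaths_disease <= tallies$n_deaths_allcause))
})

test_that("no resurrection: an individual's states follow healthy, diseased, dead", {
  prof <- uniform_profile(3000, age = 55)
  tabs <- const_tables(incidence = 5000, prevalence = 10000,
                       disease_mortality = 2000, allcause_mortality = 6000)
  set.seed(77)
  coh <- initialize_population(prof, tabs)
  ex <- microhia:::expand_rate_tables(tabs)
  tm <- microhia:::.transition_matrix(ex, prof$imd_decile, 10, 10, 10,
                                      neutral_cfg)
  dead_prev <- integer(0)
  states_prev <- coh$state
  for (t in 1:20) {
    coh <- microhia:::.step_core(coh, tm, t, neutral_cfg)$cohort
    dead_now <- which(coh$state == 3L)
    expect_true(all(dead_prev %in% dead_now))
    # transitions only move forward through the state order
    expect_true(all(coh$state >= states_prev))
    dead_prev <- dead_now
    states_prev <- coh$state
  }
  df <- as.data.frame(coh)
  both <- !is.na(df$year_of_incidence) & !is.na(df$year_of_death)
  expect_true(all(df$year_of_incidence[both] <= df$year_of_death[both]))
})

test_that("lower exposure produces no more deaths in expectation (common random numbers)", {
  prof_hi <- uniform_profile(5000, age = 60, pm25 = 16, nonanth = 4)
  prof_lo <- uniform_profile(5000, age = 60, pm25 = 8, nonanth = 4)
  tabs <- const_tables(incidence = 2000, prevalence = 10000,
                       disease_mortality = 1500, allcause_mortality = 5000)
  cfg <- risk_config(reference_mean = 10)
  deaths <- function(prof, seed, years = 10) {
    tal <- run_simulation(prof, tabs, cfg, NULL, years, seed)
    tapply(tal$n_deaths_allcause, tal$year, sum)
  }
  d_hi <- vapply(1:8, function(s) sum(deaths(prof_hi, s)), numeric(1))
  d_lo <- vapply(1:8, function(s) sum(deaths(prof_lo, s)), numeric(1))
  expect_lt(mean(d_lo), mean(d_hi))
  # in year one the runs are perfectly coupled, so the ordering is pathwise
  y1_hi <- vapply(1:8, function(s) deaths(prof_hi, s, 1)[[1]], numeric(1))
  y1_lo <- vapply(1:8, function(s) deaths(prof_lo, s, 1)[[1]], numeric(1))
  expect_true(all(y1_lo <= y1_hi))
})
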