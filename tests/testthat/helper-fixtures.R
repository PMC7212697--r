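# Fixtures are built in code: constant-rate tables for analytic oracles and
# minimal hand-made profiles.

# One band 0-100 per (sex, metric): every age sees the same rate, so a cohort
# is a single stratum with constant transition probabilities regardless of
# aging. Rates are per 100k; male and female identical unless overridden.
const_tables <- function(incidence = 0, prevalence = 0, disease_mortality = 0,
                         allcause_mortality = 0,
                         male = NULL, female = NULL) {
  base <- list(incidence = incidence, prevalence = prevalence,
               disease_mortality = disease_mortality,
               allcause_mortality = allcause_mortality)
  per_sex <- list(male = utils::modifyList(base, male %||% list()),
                  female = utils::modifyList(base, female %||% list()))
  rows <- list()
  for (s in c("male", "female")) {
    for (m in names(base)) {
      rows[[length(rows) + 1L]] <- data.frame(
        age_lo = 0L, age_hi = 100L, sex = s, metric = m,
        rate_per_100k = per_sex[[s]][[m]])
    }
  }
  rate_table_set(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A one-stratum area: n individuals of one age and sex.
uniform_profile <- function(n, age = 40, sex = "male", area_id = "T0001",
                            decile = 5, pm25 = 10, nonanth = 4, gfr = 0) {
  pop <- data.frame(age = age, sex = sex, count = n)
  area_profile(area_id, decile, pm25, nonanth, gfr, pop)
}

# Closed-form expected (H1, H2) occupancy recursion for a single stratum with
# constant transition probabilities; newly incident individuals face the
# diseased-state mortality trial in the incidence year. Row t+1 holds the
# expectation after t simulated years.
markov_occupancy <- function(n, p_prev, p_i, p_m1, p_m2, horizon) {
  h1 <- n * (1 - p_prev)
  h2 <- n * p_prev
  out <- matrix(NA_real_, horizon + 1L, 2L, dimnames = list(NULL, c("h1", "h2")))
  out[1L, ] <- c(h1, h2)
  for (t in seq_len(horizon)) {
    h1_new <- h1 * (1 - p_i) * (1 - p_m1)
    h2_new <- h2 * (1 - p_m2) + h1 * p_i * (1 - p_m2)
    h1 <- h1_new
    h2 <- h2_new
    out[t + 1L, ] <- c(h1, h2)
  }
  out
}
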