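# Annual-cycle stochastic engine: initialization, sequential Bernoulli
# trials, aging, births, death bookkeeping, per-area reproducibility.
#
# A cohort is a column store (one vector per field) rather than a data.frame
# of individuals: a year step is then ~20 vectorised operations over the
# alive subset, which keeps 50-year runs over thousands of areas tractable.

.max_age <- 110L   # survivors beyond the top rate band keep top-band rates
.n_bands <- 20L    # 5-year bands 0-4 ... 90-94, 95+

.band_labels <- c(paste(seq(0, 90, 5), seq(4, 94, 5), sep = "-"), "95+")

# stratum index 1..40 from integer age and sex code (1 male, 2 female),
# banded by 5-year age group with 95+ open-ended
.stratum_index <- function(age, sex_code) {
  pmin(age %/% 5L, .n_bands - 1L) + 1L + .n_bands * (sex_code - 1L)
}

#' Derive a per-area RNG seed from a master seed and area id
#'
#' Each area owns an independent RNG stream seeded by a deterministic hash of
#' the master seed and the area id. Scenario runs that share the master seed
#' therefore reuse the same stream per area (common random numbers), so
#' scenario-minus-base deltas are not dominated by Monte-Carlo noise.
#'
#' @param master_seed Integer master seed.
#' @param area_id Character area id.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
area_seed <- function(master_seed, area_id) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps arithmetic exact in doubles
  h <- 0
  for (b in utf8ToInt(as.character(area_id))) h <- (h * 31 + b) %% m
  s <- (abs(as.numeric(master_seed)) %% m) * 48271 %% m
  as.integer((h + s) %% (m - 1)) + 1L
}

#' Initialize a simulated cohort from an area profile
#'
#' Creates one individual per head of the age-by-sex count table. Each is
#' assigned the ever-diagnosed state H2 by a Bernoulli draw on the baseline
#' prevalence probability for their age/sex stratum (prevalence rate /
#' 100,000), otherwise starts healthy (H1). Deterministic given the RNG
#' state (or `seed`).
#'
#' @param profile An [area_profile()].
#' @param tables A [rate_table_set()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `cohort`: parallel vectors `age`, `sex`
#'   (1 male, 2 female), `state` (1 H1, 2 H2, 3 dead), `year_of_incidence`,
#'   `year_of_death`.
#' @export
initialize_population <- function(profile, tables, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- profile$population
  total <- sum(pop$count)
  if (total == 0) stop("empty population table for area ", profile$area_id)
  age <- rep(as.integer(pop$age), pop$count)
  sex <- rep(match(pop$sex, .sexes), pop$count)
  n <- length(age)
  ex_prev <- expand_rate_tables(tables)$prevalence
  pv <- cbind(ex_prev$male, ex_prev$female)[cbind(pmin(age, .max_age) + 1L, sex)]
  state <- 1L + (stats::runif(n) < pv)
  structure(
    list(age = age, sex = sex, state = as.integer(state),
         year_of_incidence = rep(NA_integer_, n),
         year_of_death = rep(NA_integer_, n)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  alive <- x$state != 3L
  cat(sprintf("<cohort> %d individuals: %d alive (%d prevalent), %d dead\n",
              length(x$age), sum(alive), sum(x$state == 2L), sum(!alive)))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(person_id = seq_along(x$age), age = x$age,
             sex = .sexes[x$sex], state = c("H1", "H2", "H3")[x$state],
             year_of_incidence = x$year_of_incidence,
             year_of_death = x$year_of_death)
}

# Precompute the three state-conditional transition probabilities (plus the
# disease-death attribution fraction) for every (age 0..110, sex) stratum of
# one area-year. Returns 111x2 matrices and a clamp/floor event count.
.transition_matrix <- function(ex, decile, x_inc, x_ac, x_cf, config) {
  mu <- config$reference_mean
  n_age <- .max_age + 1L
  p_i <- p_m1 <- p_m2 <- q_dis <- matrix(0, n_age, 2L)
  clamps <- 0L
  for (si in 1:2) {
    s <- .sexes[si]
    d <- deprivation_rr(s, decile, config)
    inc <- ex$incidence[[s]] * config$rr_incidence_per10^((x_inc - mu) / 10)
    dm <- ex$disease_mortality[[s]] *
      config$rr_case_fatality_per10^((x_cf - mu) / 10) * d
    ac <- ex$allcause_mortality[[s]] *
      config$rr_allcause_per10^((x_ac - mu) / 10) * d
    pv <- ex$prevalence[[s]]
    if (any(pv >= 1)) stop("degenerate stratum: prevalence probability >= 1")
    if (any(dm > 0 & pv <= 0)) {
      stop("inconsistent rates: disease mortality positive where prevalence is zero")
    }
    clamps <- clamps + sum(inc > 1) + sum(dm > 1) + sum(ac > 1)
    inc <- pmin(inc, 1); dm <- pmin(dm, 1); ac <- pmin(ac, 1)
    m1 <- ac - dm
    clamps <- clamps + sum(m1 < 0)
    m1 <- pmax(m1, 0)
    pi_ <- inc / (1 - pv)
    clamps <- clamps + sum(pi_ > 1)
    pi_ <- pmin(pi_, 1)
    excess <- ifelse(pv > 0, dm / pv, 0)
    m2 <- excess + m1
    clamps <- clamps + sum(m2 > 1)
    m2 <- pmin(m2, 1)
    p_i[, si] <- pi_
    p_m1[, si] <- m1
    p_m2[, si] <- m2
    q_dis[, si] <- ifelse(m2 > 0, pmin(excess / m2, 1), 0)
  }
  list(p_i = p_i, p_m1 = p_m1, p_m2 = p_m2, q_dis = q_dis, clamps = clamps)
}

# One simulated year on the alive subset. Returns the updated cohort and a
# 40 x 6 count matrix (strata x {population, incident, deaths_allcause,
# deaths_disease, alive, prevalent}), strata banded by age at year start.
.step_core <- function(cohort, tm, year, config) {
  ia <- which(cohort$state != 3L)
  n <- length(ia)
  counts <- matrix(0L, .n_bands * 2L, 6L)
  if (n == 0L) return(list(cohort = cohort, counts = counts))
  age <- cohort$age[ia]
  sx <- cohort$sex[ia]
  st <- cohort$state[ia]
  ai <- pmin(age, .max_age) + 1L
  stratum <- .stratum_index(age, sx)
  idx <- cbind(ai, sx)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  inc <- (st == 1L) & (u1 < tm$p_i[idx])
  facing_dis <- (st == 2L) |
    (inc & config$incident_year_mortality == "diseased")
  pd <- ifelse(facing_dis, tm$p_m2[idx], tm$p_m1[idx])
  dies <- u2 < pd
  # attribute cause within the diseased-state trial by its composition
  dis_death <- rep(FALSE, n)
  dd <- which(dies & facing_dis)
  if (length(dd) > 0L) {
    dis_death[dd] <- stats::runif(length(dd)) < tm$q_dis[cbind(ai[dd], sx[dd])]
  }
  tab <- function(cond) tabulate(stratum[cond], nbins = .n_bands * 2L)
  counts[, 1L] <- tabulate(stratum, nbins = .n_bands * 2L)
  counts[, 2L] <- tab(inc)
  counts[, 3L] <- tab(dies)
  counts[, 4L] <- tab(dis_death)
  counts[, 5L] <- counts[, 1L] - counts[, 3L]
  st_new <- st
  st_new[inc] <- 2L
  st_new[dies] <- 3L
  counts[, 6L] <- tab(st_new == 2L & !dies)
  cohort$year_of_incidence[ia[inc]] <- year
  cohort$year_of_death[ia[dies]] <- year
  cohort$state[ia] <- st_new
  surv <- ia[!dies]
  cohort$age[surv] <- cohort$age[surv] + 1L
  list(cohort = cohort, counts = counts)
}

#' Add newborns for one simulation year
#'
#' The general fertility rate is applied to the alive female population aged
#' 15-44 at the end of the simulation year: each eligible woman independently
#' bears a child with probability `gfr / 1000`. Newborns enter at the year
#' boundary with age 0, state H1, and male sex with probability
#' `config$p_male_birth`; they face no trials in their birth year.
#'
#' @param cohort A `cohort` (after this year's trials and aging).
#' @param profile The [area_profile()] supplying the GFR.
#' @param year Simulation year (recorded for bookkeeping only).
#' @param config A [risk_config()].
#' @return List with the updated `cohort` and `n_births`, a length-2 integer
#'   vector of newborn counts (male, female).
#' @export
apply_births <- function(cohort, profile, year, config = risk_config()) {
  if (profile$gfr > 1000) stop("gfr exceeds 1000 births per 1000 women")
  eligible <- cohort$state != 3L & cohort$sex == 2L &
    cohort$age >= 15L & cohort$age <= 44L
  ne <- sum(eligible)
  nb <- if (ne > 0L && profile$gfr > 0) {
    sum(stats::runif(ne) < profile$gfr / 1000)
  } else 0L
  births <- c(0L, 0L)
  if (nb > 0L) {
    nb_sex <- 1L + (stats::runif(nb) >= config$p_male_birth)
    births <- c(sum(nb_sex == 1L), sum(nb_sex == 2L))
    cohort$age <- c(cohort$age, rep(0L, nb))
    cohort$sex <- c(cohort$sex, as.integer(nb_sex))
    cohort$state <- c(cohort$state, rep(1L, nb))
    cohort$year_of_incidence <- c(cohort$year_of_incidence, rep(NA_integer_, nb))
    cohort$year_of_death <- c(cohort$year_of_death, rep(NA_integer_, nb))
  }
  list(cohort = cohort, n_births = births)
}

#' Simulate one year of the annual cycle
#'
#' For each alive individual, transition probabilities are assembled for
#' their (age-at-year-start, sex) stratum at the supplied effective
#' concentrations. Healthy (H1) individuals face an incidence trial; if it
#' fires they face the diseased-state mortality trial in the same year
#' (configurable), otherwise the healthy-state (non-disease) mortality trial.
#' Prevalent (H2) individuals face the diseased-state trial only. Deaths move
#' to H3 and are excluded from all later years; survivors age by one year
#' after the trials. Births are *not* applied here - see [apply_births()].
#'
#' @param cohort A `cohort`.
#' @param profile The [area_profile()] (supplies the deprivation decile).
#' @param tables A [rate_table_set()].
#' @param config A [risk_config()].
#' @param x Effective concentration for the incidence channel, ug/m3.
#' @param year Simulation year recorded in the tally.
#' @param x_mort_allcause,x_mort_disease Effective concentrations for the two
#'   mortality channels (default `x`).
#' @return List with the updated `cohort` and `tally`, a data.frame of
#'   per-stratum annual counts.
#' @export
step_year <- function(cohort, profile, tables, config, x, year,
                      x_mort_allcause = x, x_mort_disease = x) {
  ex <- expand_rate_tables(tables)
  tm <- .transition_matrix(ex, profile$imd_decile, x, x_mort_allcause,
                           x_mort_disease, config)
  res <- .step_core(cohort, tm, year, config)
  tally <- .tally_frame(profile, year, res$counts, c(0L, 0L))
  list(cohort = res$cohort, tally = tally)
}

# Assemble one year's 40-strata count matrix into the tally data.frame.
.tally_frame <- function(profile, year, counts, n_births) {
  births_col <- integer(.n_bands * 2L)
  births_col[1L] <- n_births[1L]                 # male newborns, band 0-4
  births_col[.n_bands + 1L] <- n_births[2L]      # female newborns, band 0-4
  data.frame(
    year = year,
    area_id = profile$area_id,
    imd_decile = profile$imd_decile,
    sex = rep(.sexes, each = .n_bands),
    age_group = rep(.band_labels, 2L),
    age_lo = rep(seq(0L, by = 5L, length.out = .n_bands), 2L),
    n_population = counts[, 1L],
    n_incident = counts[, 2L],
    n_deaths_allcause = counts[, 3L],
    n_deaths_disease = counts[, 4L],
    n_alive = counts[, 5L],
    n_prevalent = counts[, 6L],
    n_births = births_col)
}

#' Run the full annual-cycle simulation for one area
#'
#' Initializes the cohort from the area profile, then for each year computes
#' the (lag-attenuated) effective concentrations, performs the Bernoulli
#' trials, and applies births. Baseline rates are held constant at their
#' base-year values throughout; migration is zero. The run is bitwise
#' reproducible given (profile, seed, scenario), and areas are fully
#' independent: each derives its own RNG stream via [area_seed()], so
#' per-area runs can be executed in parallel and scenario runs sharing a
#' master seed use common random numbers.
#'
#' Under a scenario that reduces the concentration, the incidence channel
#' sees the scenario concentration immediately while the two mortality
#' channels approach it along their cessation-lag curves
#' ([effective_concentration()]).
#'
#' @param profile An [area_profile()].
#' @param tables A [rate_table_set()].
#' @param config A [risk_config()].
#' @param scenario A [scenario_spec()], or `NULL` for the base case.
#' @param horizon_years Number of simulated years (>= 1).
#' @param seed Master integer seed.
#' @return A data.frame of per-stratum annual tallies (rows = year x sex x
#'   5-year age band) with columns `year`, `area_id`, `imd_decile`, `sex`,
#'   `age_group`, `age_lo`, `n_population`, `n_incident`,
#'   `n_deaths_allcause`, `n_deaths_disease`, `n_alive`, `n_prevalent`,
#'   `n_births`. Counts are banded by age at year start; `n_population` is
#'   alive at year start (the rate denominator), `n_alive` and `n_prevalent`
#'   are measured at year end, `n_births` enter the following year's
#'   population. A run log (clamp counts, per-area seed) is attached as
#'   attribute `"run_log"`.
#' @export
run_simulation <- function(profile, tables, config = risk_config(),
                           scenario = NULL, horizon_years = 50, seed = 1) {
  if (horizon_years < 1) stop("horizon_years must be >= 1")
  x_base <- profile$pm25_total
  x_scen <- if (is.null(scenario)) x_base else
    transform_concentration(profile, scenario)
  applies_at <- if (is.null(scenario)) 0L else scenario$applies_at_year
  ac_curve <- lag_curve(config$allcause_lag, config$ihd_lag_tau)
  cf_curve <- lag_curve(config$ihd_lag, config$ihd_lag_tau)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(area_seed(seed, profile$area_id))

  ex <- expand_rate_tables(tables)
  cohort <- initialize_population(profile, tables)
  tallies <- vector("list", horizon_years)
  clamps <- 0L
  tm <- NULL
  tm_key <- NULL
  for (t in seq_len(horizon_years)) {
    ts <- t - applies_at
    if (ts <= 0) {
      x_inc <- x_ac <- x_cf <- x_base
    } else {
      x_inc <- x_scen
      x_ac <- effective_concentration(x_base, x_scen, ts, ac_curve)
      x_cf <- effective_concentration(x_base, x_scen, ts, cf_curve)
    }
    key <- c(x_inc, x_ac, x_cf)
    if (is.null(tm_key) || !identical(key, tm_key)) {
      tm <- .transition_matrix(ex, profile$imd_decile, x_inc, x_ac, x_cf, config)
      tm_key <- key
      clamps <- clamps + tm$clamps
    }
    stepped <- .step_core(cohort, tm, t, config)
    born <- apply_births(stepped$cohort, profile, t, config)
    cohort <- born$cohort
    tallies[[t]] <- .tally_frame(profile, t, stepped$counts, born$n_births)
  }
  out <- do.call(rbind, tallies)
  attr(out, "run_log") <- list(area_id = profile$area_id,
                               area_seed = area_seed(seed, profile$area_id),
                               clamp_events = clamps)
  out
}

#' Run the simulation over many areas
#'
#' Areas are simulated independently (no cross-area state), each with its own
#' RNG stream derived from the master seed, and their tallies concatenated.
#'
#' @param profiles A list of [area_profile()] objects.
#' @param tables,config,scenario,horizon_years,seed As in [run_simulation()].
#' @return Combined tally data.frame over all areas; run logs as attribute
#'   `"run_log"` (one element per area).
#' @export
run_city <- function(profiles, tables, config = risk_config(), scenario = NULL,
                     horizon_years = 50, seed = 1) {
  runs <- lapply(profiles, run_simulation, tables = tables, config = config,
                 scenario = scenario, horizon_years = horizon_years, seed = seed)
  out <- do.call(rbind, c(runs, list(make.row.names = FALSE)))
  attr(out, "run_log") <- lapply(runs, attr, "run_log")
  out
}
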