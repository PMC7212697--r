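# Counterfactual exposure scenarios and stratified delta reporting.

#' Define an exposure scenario
#'
#' Scenario kinds transform each area's annual-mean PM2.5:
#' * `baseline` - concentrations unchanged;
#' * `cap` - concentrations above `cap_value` are capped (WHO-guideline
#'   style: only affects areas above the cap);
#' * `uniform_reduction` - all areas reduced by `decrement`, floored at the
#'   area's non-anthropogenic component (a policy decrement cannot remove
#'   natural background);
#' * `remove_anthropogenic` - concentration set to the non-anthropogenic
#'   component.
#'
#' The change is instantaneous at `applies_at_year` (default 0, i.e. at
#' simulation initialization) and static thereafter; mortality benefits then
#' accrue along the configured cessation lags.
#'
#' @param name Scenario label.
#' @param kind One of `"baseline"`, `"cap"`, `"uniform_reduction"`,
#'   `"remove_anthropogenic"`.
#' @param cap_value Cap, ug/m3 (default 10, the WHO annual guideline).
#' @param decrement Uniform reduction, ug/m3 (e.g. 3.6 for an
#'   emissions-directive-style city-wide cut).
#' @param applies_at_year Simulation year of the instantaneous change.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name,
                          kind = c("baseline", "cap", "uniform_reduction",
                                   "remove_anthropogenic"),
                          cap_value = 10, decrement = 0, applies_at_year = 0L) {
  kind <- match.arg(kind)
  if (cap_value <= 0) stop("cap_value must be positive")
  if (decrement < 0) stop("decrement must be non-negative")
  if (applies_at_year < 0) stop("applies_at_year must be non-negative")
  structure(list(name = as.character(name), kind = kind,
                 cap_value = as.numeric(cap_value),
                 decrement = as.numeric(decrement),
                 applies_at_year = as.integer(applies_at_year)),
            class = "scenario_spec")
}

#' Apply a scenario transform to an area's concentration
#'
#' @param profile An [area_profile()].
#' @param spec A [scenario_spec()].
#' @return Scenario concentration, ug/m3; never below the area's
#'   non-anthropogenic component nor below 0.
#' @export
transform_concentration <- function(profile, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  switch(spec$kind,
    baseline = profile$pm25_total,
    cap = min(profile$pm25_total, spec$cap_value),
    uniform_reduction = max(profile$pm25_total - spec$decrement,
                            profile$pm25_nonanthropogenic),
    remove_anthropogenic = profile$pm25_nonanthropogenic)
}

#' Aggregate annual tallies to a chosen stratification
#'
#' Sums the tally counts over everything not in `group_by` and derives
#' per-100,000 rates against the alive-at-year-start denominator
#' (`n_population`). The working-age filter of the reporting convention
#' (ages 15-64) is expressed via `age_range`, which keeps the 5-year bands
#' fully contained in the closed range.
#'
#' @param tallies Tally data.frame from [run_simulation()]/[run_city()].
#' @param group_by Character subset of
#'   `c("year", "sex", "age_group", "imd_decile", "area_id")`.
#' @param age_range Optional `c(lo, hi)` in years, e.g. `c(15, 64)`.
#' @return data.frame with the grouping keys, summed counts, and
#'   `prevalence_per_100k`, `mortality_per_100k`, `incidence_per_100k`
#'   (NA where the denominator is 0).
#' @export
aggregate_tallies <- function(tallies, group_by = "year", age_range = NULL) {
  keys <- c("year", "sex", "age_group", "imd_decile", "area_id")
  bad <- setdiff(group_by, keys)
  if (length(bad) > 0) stop("unknown group key(s): ", paste(bad, collapse = ", "))
  dt <- data.table::as.data.table(tallies)
  if (!is.null(age_range)) {
    dt <- dt[dt$age_lo >= age_range[1] & (dt$age_lo + 4L) <= age_range[2], ]
  }
  count_cols <- c("n_population", "n_incident", "n_deaths_allcause",
                  "n_deaths_disease", "n_alive", "n_prevalent", "n_births")
  agg <- dt[, lapply(.SD, sum), by = group_by, .SDcols = count_cols]
  data.table::setorderv(agg, group_by)
  agg <- as.data.frame(agg)
  denom <- ifelse(agg$n_population > 0, agg$n_population, NA_real_)
  agg$prevalence_per_100k <- agg$n_prevalent / denom * 1e5
  agg$mortality_per_100k <- agg$n_deaths_allcause / denom * 1e5
  agg$incidence_per_100k <- agg$n_incident / denom * 1e5
  agg
}

# Shared delta machinery: aggregate both runs to the same strata, join, and
# difference the per-100k ratios of totals (not averages of per-area deltas).
.delta_metric <- function(scenario_tallies, base_tallies, numerator,
                          group_by, age_range) {
  a <- aggregate_tallies(scenario_tallies, group_by, age_range)
  b <- aggregate_tallies(base_tallies, group_by, age_range)
  m <- merge(a, b, by = group_by, suffixes = c("_scenario", "_base"))
  m <- m[do.call(order, m[group_by]), , drop = FALSE]
  num_s <- m[[paste0(numerator, "_scenario")]]
  num_b <- m[[paste0(numerator, "_base")]]
  den_s <- m[[paste0("n_population", "_scenario")]]
  den_b <- m[[paste0("n_population", "_base")]]
  delta <- ifelse(den_s > 0 & den_b > 0,
                  (num_s / den_s - num_b / den_b) * 1e5, NA_real_)
  out <- m[group_by]
  out$delta_per_100k <- delta
  rownames(out) <- NULL
  out
}

#' Scenario-minus-base prevalence difference per 100,000
#'
#' For each stratum and year, computes
#' `N_diseased_scenario / N_population_scenario -
#'  N_diseased_base / N_population_base`, scaled to per-100,000. Ratios use
#' totals aggregated to the requested grouping. Years with a zero denominator
#' in either run yield `NA`.
#'
#' @param scenario_tallies,base_tallies Tally data.frames of the two runs.
#' @param group_by Stratification keys (default `"year"`).
#' @param age_range Optional age filter, e.g. `c(15, 64)`.
#' @return data.frame of grouping keys plus `delta_per_100k`.
#' @export
delta_prevalence <- function(scenario_tallies, base_tallies,
                             group_by = "year", age_range = NULL) {
  .delta_metric(scenario_tallies, base_tallies, "n_prevalent",
                group_by, age_range)
}

#' Scenario-minus-base all-cause mortality difference per 100,000
#'
#' As [delta_prevalence()] with all-cause deaths in the numerator.
#'
#' @inheritParams delta_prevalence
#' @return data.frame of grouping keys plus `delta_per_100k`.
#' @export
delta_mortality <- function(scenario_tallies, base_tallies,
                            group_by = "year", age_range = NULL) {
  .delta_metric(scenario_tallies, base_tallies, "n_deaths_allcause",
                group_by, age_range)
}

#' Centered running mean for reporting series
#'
#' Smooths a per-year series with a centered moving average of odd `window`
#' width, symmetrically truncated at the edges (position `i` averages over
#' `i - h .. i + h` with `h = min((window-1)/2, i-1, n-i)`), which removes
#' single-year statistical anomalies without dropping edge years.
#'
#' @param series Numeric vector (one value per year, in year order).
#' @param window Odd window width in years (default 5).
#' @return Smoothed numeric vector of the same length.
#' @export
running_mean <- function(series, window = 5) {
  n <- length(series)
  if (n == 0) stop("empty series")
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  k <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    h <- min(k, i - 1, n - i)
    mean(series[(i - h):(i + h)])
  }, numeric(1))
}
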