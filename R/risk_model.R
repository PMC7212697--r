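# Relative-risk model: deprivation multipliers, exposure-response scaling,
# cessation-lag time courses.

#' Risk-model configuration
#'
#' Holds the relative risks (RRs) and lag parameters that modify baseline
#' transition probabilities. RRs are expressed per 10 ug/m3 of annual-mean
#' PM2.5 and scaled to an area's concentration `x` relative to the national
#' population-weighted mean `reference_mean` as `RR^((x - mu)/10)`. Deprivation
#' ratios are the most-deprived to least-deprived decile mortality risk ratios.
#'
#' @param rr_incidence_per10 RR of disease incidence per 10 ug/m3 (default 1.08).
#' @param rr_case_fatality_per10 RR of case fatality (death after diagnosis)
#'   per 10 ug/m3 (default 1.21).
#' @param rr_allcause_per10 RR of all-cause mortality per 10 ug/m3 (default 1.06).
#' @param depr_ratio_male Decile-1 / decile-10 mortality risk ratio, males
#'   (default 1.7).
#' @param depr_ratio_female As above for females (default 1.5).
#' @param reference_mean National population-weighted mean PM2.5 `mu`, ug/m3.
#'   The exposure RR equals 1 at `x = mu`. Default 10.
#' @param ihd_lag_tau Time constant (years) of the exponential cessation lag
#'   applied to the case-fatality RR (default 5).
#' @param allcause_lag Lag curve kind for the all-cause mortality RR:
#'   `"epa_smooth"` (default), `"exponential"` or `"none"`.
#' @param ihd_lag Lag curve kind for the case-fatality RR: `"exponential"`
#'   (default) or `"none"`.
#' @param incident_year_mortality Which mortality trial a newly incident
#'   individual faces in the incidence year: `"diseased"` (default) or
#'   `"healthy"`.
#' @param p_male_birth Probability a newborn is male (default 0.512).
#' @return Object of class `risk_config`.
#' @export
risk_config <- function(rr_incidence_per10 = 1.08,
                        rr_case_fatality_per10 = 1.21,
                        rr_allcause_per10 = 1.06,
                        depr_ratio_male = 1.7,
                        depr_ratio_female = 1.5,
                        reference_mean = 10,
                        ihd_lag_tau = 5,
                        allcause_lag = c("epa_smooth", "exponential", "none"),
                        ihd_lag = c("exponential", "none"),
                        incident_year_mortality = c("diseased", "healthy"),
                        p_male_birth = 0.512) {
  allcause_lag <- match.arg(allcause_lag)
  ihd_lag <- match.arg(ihd_lag)
  incident_year_mortality <- match.arg(incident_year_mortality)
  rrs <- c(rr_incidence_per10, rr_case_fatality_per10, rr_allcause_per10,
           depr_ratio_male, depr_ratio_female)
  if (any(rrs <= 0)) stop("all relative risks must be positive")
  if (reference_mean < 0) stop("reference_mean must be non-negative")
  if (ihd_lag_tau <= 0) stop("ihd_lag_tau must be positive")
  if (p_male_birth < 0 || p_male_birth > 1) stop("p_male_birth must be in [0,1]")
  structure(
    list(rr_incidence_per10 = rr_incidence_per10,
         rr_case_fatality_per10 = rr_case_fatality_per10,
         rr_allcause_per10 = rr_allcause_per10,
         depr_ratio_male = depr_ratio_male,
         depr_ratio_female = depr_ratio_female,
         reference_mean = reference_mean,
         ihd_lag_tau = ihd_lag_tau,
         allcause_lag = allcause_lag,
         ihd_lag = ihd_lag,
         incident_year_mortality = incident_year_mortality,
         p_male_birth = p_male_birth),
    class = "risk_config")
}

#' Deprivation relative-risk multiplier
#'
#' Mortality risk varies roughly linearly with deprivation decile. To adjust a
#' population-average risk (centred at the mean decile 5.5) for an area of
#' decile `j`, the multiplier is `ratio^((5.5 - j)/9)` where `ratio` is the
#' sex-specific decile-1/decile-10 risk ratio. The multiplier exceeds 1 for
#' deciles below 5.5 (more deprived) and is below 1 above it; the ratio
#' between decile 1 and decile 10 equals `ratio` exactly, and the geometric
#' mean over the ten deciles is 1. Applied to mortality only, never to
#' incidence.
#'
#' @param sex `"male"` or `"female"`.
#' @param decile Integer decile(s) in 1..10 (1 = most deprived).
#' @param config A [risk_config()].
#' @return Dimensionless multiplier(s).
#' @export
deprivation_rr <- function(sex, decile, config = risk_config()) {
  sex <- match.arg(sex, .sexes)
  if (any(decile != round(decile)) || any(decile < 1) || any(decile > 10)) {
    stop("decile must be an integer in 1..10")
  }
  ratio <- if (sex == "male") config$depr_ratio_male else config$depr_ratio_female
  ratio^((5.5 - decile) / 9)
}

#' Exposure-response relative risk at a given concentration
#'
#' Scales a per-10-ug/m3 relative risk to an area concentration `x` relative
#' to the reference mean `mu`: `base_rr_per10^((x - mu)/10)`. Equals 1 at
#' `x = mu` and is monotone increasing in `x` for base RRs above 1.
#'
#' @param base_rr_per10 Positive RR per 10 ug/m3.
#' @param x Concentration(s), ug/m3.
#' @param mu Reference (population-weighted mean) concentration, ug/m3.
#' @return Dimensionless multiplier(s).
#' @export
pollution_rr <- function(base_rr_per10, x, mu) {
  if (any(base_rr_per10 <= 0)) stop("base_rr_per10 must be positive")
  if (any(x < 0)) stop("concentration must be non-negative")
  base_rr_per10^((x - mu) / 10)
}

#' Cessation-lag curve
#'
#' A cumulative fraction `f(t)` in `[0, 1]` of the asymptotic health benefit
#' realised `t` years after an exposure reduction, with `f(0) = 0`,
#' non-decreasing, tending to 1.
#'
#' * `epa_smooth`: 30% of the benefit accrues in the first year, 50% spread
#'   uniformly over years 2-5 (0.125/year), 20% uniformly over years 6-20
#'   (0.2/15 per year); `f(1) = 0.30`, `f(5) = 0.80`, `f(t >= 20) = 1`.
#' * `exponential`: `f(t) = 1 - exp(-t/tau)` (smoking-cessation-style decay).
#' * `none`: the full benefit from year 1 (`f(t) = 1` for `t >= 1`).
#'
#' @param kind `"epa_smooth"`, `"exponential"` or `"none"`.
#' @param tau Time constant (years) for the exponential kind.
#' @return Object of class `lag_curve`.
#' @export
lag_curve <- function(kind = c("epa_smooth", "exponential", "none"), tau = 5) {
  kind <- match.arg(kind)
  if (tau <= 0) stop("tau must be positive")
  structure(list(kind = kind, tau = tau), class = "lag_curve")
}

#' Cumulative lag fraction at time t
#'
#' @param curve A [lag_curve()].
#' @param t Years since the exposure change; non-negative, vectorised.
#' @return Cumulative fraction(s) in `[0, 1]`.
#' @export
lag_fraction <- function(curve, t) {
  stopifnot(inherits(curve, "lag_curve"))
  if (any(t < 0)) stop("t must be non-negative")
  switch(curve$kind,
    epa_smooth = 0.30 * pmin(t, 1) +
      0.125 * pmin(pmax(t - 1, 0), 4) +
      (0.20 / 15) * pmin(pmax(t - 5, 0), 15),
    exponential = 1 - exp(-t / curve$tau),
    none = as.numeric(t >= 1))
}

#' Lag-attenuated effective concentration
#'
#' After an intervention lowers the concentration from `x_base` to
#' `x_scenario`, the mortality-relevant exposure at year `t` is
#' `x_base - f(t) * (x_base - x_scenario)`: the lag interpolates the
#' concentration (equivalently the log relative risk, given the exponential
#' exposure-response form) between base and scenario. Concentration
#' *increases* take effect immediately from year 1 - the cessation lag only
#' delays benefits, not harms.
#'
#' @param x_base Base-case concentration, ug/m3.
#' @param x_scenario Scenario concentration, ug/m3.
#' @param t Years since the intervention (vectorised).
#' @param curve A [lag_curve()].
#' @return Effective concentration(s), ug/m3.
#' @export
effective_concentration <- function(x_base, x_scenario, t, curve) {
  if (x_scenario >= x_base) {
    f <- as.numeric(t >= 1)
  } else {
    f <- lag_fraction(curve, t)
  }
  x_base - f * (x_base - x_scenario)
}
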