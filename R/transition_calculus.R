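# Transition calculus: inverts population-level rates into the three
# state-conditional annual transition probabilities of the three-state model
# (healthy H1, ever-diagnosed H2, dead H3), after relative-risk adjustment.
#
# The probability identities rest on two assumptions: (i) non-disease
# mortality is equal in H1 and H2 (independence of prevalence and other-cause
# death), and (ii) disease-specific death occurs only from the prevalent
# state, so P(H2 | M_disease) = 1.

#' Incidence probability conditional on being disease-free
#'
#' Population incidence rates count events per head of the *total* population,
#' including the prevalent pool who cannot be newly diagnosed. Bayes inversion
#' gives the at-risk probability: `P(I|H1) = P(I) / (1 - P(H2))`. Values
#' above 1 are clamped with a warning.
#'
#' @param p_incidence Population incidence probability `P(I)` in `[0,1]`.
#' @param p_prevalence Population prevalence `P(H2)` in `[0,1)`.
#' @return `P(I|H1)` in `[0,1]`. Vectorised.
#' @export
incidence_given_healthy <- function(p_incidence, p_prevalence) {
  if (any(p_prevalence < 0) || any(p_prevalence >= 1)) {
    stop("degenerate stratum: p_prevalence must lie in [0, 1)")
  }
  if (any(p_incidence < 0) || any(p_incidence > 1)) {
    stop("p_incidence must lie in [0, 1]")
  }
  p <- p_incidence / (1 - p_prevalence)
  over <- p > 1
  if (any(over)) {
    warning(sum(over), " conditional incidence probability(ies) clamped to 1")
    p[over] <- 1
  }
  p
}

#' Non-disease mortality probability
#'
#' `P(M_~dis) = P(M_allcause) - P(M_disease)`, evaluated on the
#' *already RR-adjusted* probabilities so mortality multipliers are not double
#' counted; by the equal-other-cause-mortality assumption this is also
#' `P(M_~dis | H1)`. Negative differences (possible when the case-fatality RR
#' exceeds the all-cause RR at high exposure) are floored at 0 with a warning.
#'
#' @param p_allcause_adj Adjusted all-cause mortality probability.
#' @param p_disease_mortality_adj Adjusted disease-specific mortality
#'   probability.
#' @return `P(M_~dis)` in `[0,1]`. Vectorised.
#' @export
nonihd_mortality <- function(p_allcause_adj, p_disease_mortality_adj) {
  p <- p_allcause_adj - p_disease_mortality_adj
  neg <- p < 0
  if (any(neg)) {
    warning(sum(neg), " non-disease mortality probability(ies) floored at 0")
    p[neg] <- 0
  }
  p
}

#' Mortality probability conditional on prevalent disease
#'
#' `P(M|H2) = P(M_disease)/P(H2) + P(M_~dis)`: the disease-specific hazard is
#' concentrated onto the prevalent pool (disease death only occurs from H2)
#' and the shared other-cause hazard is added. Values above 1 are clamped with
#' a warning.
#'
#' @param p_disease_mortality_adj Adjusted disease-specific mortality
#'   probability (population level).
#' @param p_prevalence Population prevalence `P(H2)`; must be positive
#'   wherever disease mortality is positive.
#' @param p_nonihd Non-disease mortality probability `P(M_~dis)`.
#' @return `P(M|H2)` in `[0,1]`. Vectorised.
#' @export
mortality_given_diseased <- function(p_disease_mortality_adj, p_prevalence,
                                     p_nonihd) {
  bad <- p_prevalence <= 0 & p_disease_mortality_adj > 0
  if (any(bad)) {
    stop("inconsistent rates: disease mortality positive where prevalence is zero")
  }
  excess <- ifelse(p_prevalence > 0, p_disease_mortality_adj / p_prevalence, 0)
  p <- excess + p_nonihd
  over <- p > 1
  if (any(over)) {
    warning(sum(over), " diseased-state mortality probability(ies) clamped to 1")
    p[over] <- 1
  }
  p
}

#' Assemble the state-conditional transition probabilities for a stratum
#'
#' The full pipeline for one (age, sex, area) stratum:
#' 1. look up the four population probabilities (incidence, prevalence,
#'    disease mortality, all-cause mortality) from the rate tables;
#' 2. adjust: incidence by the incidence exposure RR; disease mortality by the
#'    case-fatality exposure RR and the deprivation RR; all-cause mortality by
#'    the all-cause exposure RR and the deprivation RR. Deprivation never
#'    multiplies incidence (no empirical support for a deprivation effect on
#'    disease incidence);
#' 3. subtract the adjusted disease mortality from the adjusted all-cause
#'    mortality (after step 2, so multipliers are not double counted);
#' 4. invert to the conditional probabilities `P(I|H1)`, `P(M_~dis|H1)`,
#'    `P(M|H2)`. The prevalence in the `P(M|H2)` denominator is the baseline
#'    table prevalence for the stratum, not the evolving simulated prevalence.
#'
#' Because mortality benefits of an exposure reduction accrue with a cessation
#' lag while incidence responds immediately, the mortality channels may see a
#' different effective concentration than incidence: `x_mort_allcause` and
#' `x_mort_disease` default to `x`.
#'
#' @param age Integer age(s) in years (vectorised).
#' @param sex `"male"` or `"female"`.
#' @param decile IMD decile 1-10.
#' @param x Concentration seen by the incidence channel, ug/m3.
#' @param tables A [rate_table_set()].
#' @param config A [risk_config()].
#' @param x_mort_allcause Effective concentration for the all-cause mortality
#'   channel (default `x`).
#' @param x_mort_disease Effective concentration for the case-fatality channel
#'   (default `x`).
#' @param warn Emit clamp/floor warnings (default TRUE); the engine disables
#'   them and aggregates clamp counts in its run log instead.
#' @return A list of class `transition_probabilities` with elements
#'   `p_incidence_h1`, `p_mortality_h1`, `p_mortality_h2` (each vectorised
#'   over `age`) and `adjusted`, the intermediate adjusted population
#'   probabilities.
#' @export
assemble_transitions <- function(age, sex, decile, x, tables, config,
                                 x_mort_allcause = x, x_mort_disease = x,
                                 warn = TRUE) {
  sex <- match.arg(sex, .sexes)
  mu <- config$reference_mean

  p_inc <- rate_to_probability(lookup_rate(tables, "incidence", sex, age))
  p_prev <- rate_to_probability(lookup_rate(tables, "prevalence", sex, age))
  p_dmort <- rate_to_probability(lookup_rate(tables, "disease_mortality", sex, age))
  p_acm <- rate_to_probability(lookup_rate(tables, "allcause_mortality", sex, age))

  d_rr <- deprivation_rr(sex, decile, config)
  p_inc_adj <- pmin(p_inc * pollution_rr(config$rr_incidence_per10, x, mu), 1)
  p_dmort_adj <- pmin(p_dmort * pollution_rr(config$rr_case_fatality_per10,
                                             x_mort_disease, mu) * d_rr, 1)
  p_acm_adj <- pmin(p_acm * pollution_rr(config$rr_allcause_per10,
                                         x_mort_allcause, mu) * d_rr, 1)

  wrap <- if (warn) identity else suppressWarnings
  p_nonihd <- wrap(nonihd_mortality(p_acm_adj, p_dmort_adj))
  p_i_h1 <- wrap(incidence_given_healthy(p_inc_adj, p_prev))
  p_m_h2 <- wrap(mortality_given_diseased(p_dmort_adj, p_prev, p_nonihd))

  structure(
    list(p_incidence_h1 = p_i_h1,
         p_mortality_h1 = p_nonihd,
         p_mortality_h2 = p_m_h2,
         adjusted = list(p_incidence = p_inc_adj,
                         p_disease_mortality = p_dmort_adj,
                         p_allcause_mortality = p_acm_adj,
                         p_nonihd = p_nonihd,
                         p_prevalence = p_prev)),
    class = "transition_probabilities")
}
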