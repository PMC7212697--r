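# YAML configuration: risk parameters, scenarios, synthetic-generator settings.

#' Read a model configuration YAML
#'
#' The file has a `risk` block whose keys mirror [risk_config()] arguments
#' (`rr_incidence_per10`, `rr_case_fatality_per10`, `rr_allcause_per10`,
#' `depr_ratio_male`, `depr_ratio_female`, `reference_mean`, `ihd_lag_tau`,
#' `allcause_lag`, `ihd_lag`) and an optional `scenarios` list whose entries
#' mirror [scenario_spec()] fields (`name`, `kind`, `cap_value`, `decrement`,
#' `applies_at_year`).
#'
#' @param path Path to the YAML file.
#' @return List with elements `risk` (a [risk_config()]) and `scenarios`
#'   (named list of [scenario_spec()], possibly empty).
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  risk <- do.call(risk_config, raw$risk %||% list())
  scenarios <- lapply(raw$scenarios %||% list(), function(s) {
    do.call(scenario_spec, s)
  })
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  list(risk = risk, scenarios = scenarios)
}

#' Read a synthetic-generator configuration YAML
#'
#' Keys mirror [synth_config()] arguments.
#'
#' @param path Path to the YAML file.
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  do.call(synth_config, yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
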