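# Synthetic study inputs: schema-complete area profiles and age-sex rate
# tables with realistic statistical structure, so the whole pipeline is
# testable without restricted census/burden-of-disease/dispersion extracts.
# Everything produced here is synthetic and is labelled as such.

#' Configuration for the synthetic-area generator
#'
#' @param n_areas Number of small areas to generate (>= 1).
#' @param mean_pop_per_area Expected residents per area (default 1500, the
#'   size of a UK LSOA-style census unit).
#' @param age_pyramid_mode `"young-urban"` (default; bulk of the population
#'   centred near age 30 with child and elderly tails, a large-city shape) or
#'   `"uniform"`.
#' @param pm25_range Interval (ug/m3) from which areas' total annual-mean
#'   PM2.5 is drawn uniformly; default `c(8, 16)`, an urban-background span.
#' @param nonanthropogenic_floor Lower bound (ug/m3) of the non-anthropogenic
#'   component; must not exceed `min(pm25_range)`. Default 3.
#' @param gfr_range Interval of general fertility rates (live births per 1000
#'   females 15-44); default `c(50, 70)` around the mid-2010s UK value.
#' @param pm25_decile_correlation Probability in `[0, 1]` that an area's
#'   deprivation decile is tied to its pollution rank (most polluted = most
#'   deprived) rather than drawn uniformly; default 0 (independent).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_areas = 100, mean_pop_per_area = 1500,
                         age_pyramid_mode = c("young-urban", "uniform"),
                         pm25_range = c(8, 16), nonanthropogenic_floor = 3,
                         gfr_range = c(50, 70),
                         pm25_decile_correlation = 0, seed = 1) {
  age_pyramid_mode <- match.arg(age_pyramid_mode)
  if (n_areas < 1) stop("n_areas must be >= 1")
  if (mean_pop_per_area < 1) stop("mean_pop_per_area must be >= 1")
  if (length(pm25_range) != 2 || diff(pm25_range) < 0 || pm25_range[1] < 0) {
    stop("pm25_range must be a non-empty non-negative interval c(lo, hi)")
  }
  if (nonanthropogenic_floor < 0 || nonanthropogenic_floor > min(pm25_range)) {
    stop("nonanthropogenic_floor must lie in [0, min(pm25_range)]")
  }
  if (length(gfr_range) != 2 || diff(gfr_range) < 0 || gfr_range[1] < 0 ||
      gfr_range[2] > 1000) {
    stop("gfr_range must be a non-empty interval within [0, 1000]")
  }
  if (pm25_decile_correlation < 0 || pm25_decile_correlation > 1) {
    stop("pm25_decile_correlation must lie in [0, 1]")
  }
  structure(list(n_areas = as.integer(n_areas),
                 mean_pop_per_area = mean_pop_per_area,
                 age_pyramid_mode = age_pyramid_mode,
                 pm25_range = as.numeric(pm25_range),
                 nonanthropogenic_floor = as.numeric(nonanthropogenic_floor),
                 gfr_range = as.numeric(gfr_range),
                 pm25_decile_correlation = pm25_decile_correlation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Sample n single-year ages (0..100) from the configured pyramid shape.
.sample_ages <- function(n, mode) {
  if (mode == "uniform") return(sample(0:90, n, replace = TRUE))
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.22, 0.58, 0.20))
  ages <- integer(n)
  ages[comp == 1L] <- sample(0:17, sum(comp == 1L), replace = TRUE)
  ages[comp == 2L] <- round(stats::rnorm(sum(comp == 2L), 30, 10))
  ages[comp == 3L] <- round(stats::rnorm(sum(comp == 3L), 62, 14))
  pmin(pmax(ages, 0L), 100L)
}

#' Generate synthetic area profiles
#'
#' Draws `n_areas` small areas: an age(0-100) x sex population count table of
#' expected size `mean_pop_per_area` (Poisson total, ages from the configured
#' pyramid, sex male with probability 0.512), a deprivation decile (uniform
#' over 1-10, optionally rank-correlated with pollution), a total PM2.5
#' concentration uniform in `pm25_range`, a non-anthropogenic component
#' uniform in `[nonanthropogenic_floor, pm25_total]`, and a general fertility
#' rate uniform in `gfr_range`. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return Named list of [area_profile()] objects.
#' @export
generate_area_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_areas
  pm25 <- stats::runif(n, config$pm25_range[1], config$pm25_range[2])
  # decile 1 (most deprived) optionally tied to the most polluted rank
  decile_pollution <- 11L - as.integer(ceiling(rank(pm25, ties.method = "first") /
                                                 n * 10))
  use_corr <- stats::runif(n) < config$pm25_decile_correlation
  decile <- ifelse(use_corr, decile_pollution, sample.int(10L, n, replace = TRUE))
  nonanth <- stats::runif(n, config$nonanthropogenic_floor, pm25)
  gfr <- stats::runif(n, config$gfr_range[1], config$gfr_range[2])
  profiles <- lapply(seq_len(n), function(i) {
    size <- stats::rpois(1, config$mean_pop_per_area)
    ages <- .sample_ages(size, config$age_pyramid_mode)
    sexes <- ifelse(stats::runif(size) < 0.512, "male", "female")
    grid <- expand.grid(age = 0:100, sex = .sexes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- table(factor(ages, levels = 0:100), factor(sexes, levels = .sexes))
    grid$count <- as.integer(tab[cbind(as.character(grid$age), grid$sex)])
    area_profile(sprintf("A%04d", i), decile[i], pm25[i], nonanth[i], gfr[i],
                 grid)
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "area_id")
  profiles
}

#' Generate a synthetic age-sex rate-table set
#'
#' Builds 5-year age bands 0-4 ... 90-94, 95+ for both sexes and the four
#' metrics, with the qualitative structure of national statistics:
#' all-cause mortality grows Gompertz-like (strictly monotone in age);
#' disease mortality is an age-increasing fraction (at most ~25%) of
#' all-cause mortality, so it never exceeds it; incidence and prevalence are
#' non-decreasing in age; male rates exceed female rates for every disease
#' metric by fixed sex ratios. Band-level multiplicative jitter is applied
#' through positive growth factors, which preserves every monotonicity
#' constraint. All rates stay below 100,000 so converted probabilities are
#' strictly inside `[0, 1)`. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @return A [rate_table_set()].
#' @export
generate_rate_tables <- function(seed = 1) {
  set.seed(seed)
  age_lo <- seq(0L, 95L, 5L)
  age_hi <- c(seq(4L, 94L, 5L), 100L)
  nb <- length(age_lo)

  # shared band-growth jitter keeps sexes ordered and curves monotone
  grow <- function(base_rate, log_step, sd = 0.02) {
    base_rate * cumprod(c(1, exp(log_step + stats::rnorm(nb - 1, 0, sd))))
  }
  # Gompertz anchored to national life-table magnitudes: ~0.5% annual
  # mortality in the late 50s rising to ~16% in the 95+ band
  acm_f <- grow(5 * exp(stats::rnorm(1, 0, 0.05)), 0.085 * 5)
  acm_m <- acm_f * 1.15
  inc_f <- grow(8 * exp(stats::rnorm(1, 0, 0.05)), 0.060 * 5)
  inc_m <- inc_f * 1.4
  prev_f <- grow(90 * exp(stats::rnorm(1, 0, 0.05)), 0.055 * 5)
  prev_m <- prev_f * 1.5
  mid <- (age_lo + age_hi) / 2
  frac <- pmin(0.02 + 0.13 / (1 + exp(-(mid - 60) / 15)) *
                 exp(stats::rnorm(nb, 0, 0.05)), 0.25)
  dm_f <- acm_f * frac
  dm_m <- acm_m * frac * 1.05   # male case fatality a little higher still
  dm_m <- pmin(dm_m, acm_m)

  series <- list(
    list("female", "allcause_mortality", acm_f),
    list("male", "allcause_mortality", acm_m),
    list("female", "incidence", inc_f),
    list("male", "incidence", inc_m),
    list("female", "prevalence", prev_f),
    list("male", "prevalence", prev_m),
    list("female", "disease_mortality", dm_f),
    list("male", "disease_mortality", dm_m))
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(age_lo = age_lo, age_hi = age_hi, sex = s[[1]], metric = s[[2]],
               rate_per_100k = round(pmin(s[[3]], 99000), 3))
  }))
  rate_table_set(df)
}

#' Write a complete synthetic input set to a directory
#'
#' Emits `areas.csv`, `population.csv` and `rates.csv` in the package's CSV
#' schemas.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic_inputs <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- generate_area_profiles(config)
  tables <- generate_rate_tables(config$seed)
  paths <- c(areas = file.path(out_dir, "areas.csv"),
             population = file.path(out_dir, "population.csv"),
             rates = file.path(out_dir, "rates.csv"))
  write_area_profiles(profiles, paths[["areas"]], paths[["population"]])
  write_rate_tables(tables, paths[["rates"]])
  invisible(paths)
}
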