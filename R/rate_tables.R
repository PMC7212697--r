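# Age-sex rate tables: reading, validation, band expansion, unit conversion.

#' @keywords internal
.metrics <- c("incidence", "prevalence", "disease_mortality", "allcause_mortality")
#' @keywords internal
.sexes <- c("male", "female")

#' Construct a validated rate-table set
#'
#' A rate-table set holds annual rates per 100,000 population in age bands,
#' for both sexes and four metrics: disease `incidence`, disease `prevalence`
#' (persons per 100k), `disease_mortality` and `allcause_mortality`. Bands are
#' inclusive at both ends (`age_lo`..`age_hi`); within each (sex, metric)
#' series bands must start at age 0, be contiguous and non-overlapping. The
#' top band is treated as open-ended: lookups above its upper edge resolve to
#' it.
#'
#' @param df data.frame with columns `age_lo`, `age_hi`, `sex`, `metric`,
#'   `rate_per_100k`.
#' @return An object of class `rate_table_set` (a validated data.frame).
#' @export
rate_table_set <- function(df) {
  required <- c("age_lo", "age_hi", "sex", "metric", "rate_per_100k")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("rate table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$age_lo <- as.integer(df$age_lo)
  df$age_hi <- as.integer(df$age_hi)
  df$sex <- as.character(df$sex)
  df$metric <- as.character(df$metric)
  df$rate_per_100k <- as.numeric(df$rate_per_100k)

  bad_sex <- which(!df$sex %in% .sexes)
  if (length(bad_sex) > 0) {
    stop("invalid sex value(s) at row(s) ", paste(bad_sex, collapse = ", "),
         " (expected 'male' or 'female')")
  }
  bad_metric <- which(!df$metric %in% .metrics)
  if (length(bad_metric) > 0) {
    stop("invalid metric value(s) at row(s) ", paste(bad_metric, collapse = ", "))
  }
  bad_rate <- which(is.na(df$rate_per_100k) | df$rate_per_100k < 0)
  if (length(bad_rate) > 0) {
    stop("negative or missing rate_per_100k at row(s) ", paste(bad_rate, collapse = ", "))
  }
  bad_band <- which(df$age_lo > df$age_hi | df$age_lo < 0)
  if (length(bad_band) > 0) {
    stop("invalid age band (age_lo > age_hi or negative) at row(s) ",
         paste(bad_band, collapse = ", "))
  }

  # Coverage: each (sex, metric) series must tile 0..age_hi_max contiguously.
  for (s in .sexes) {
    for (m in .metrics) {
      b <- df[df$sex == s & df$metric == m, , drop = FALSE]
      if (nrow(b) == 0) {
        stop("coverage error: no bands at all for ", s, "/", m)
      }
      b <- b[order(b$age_lo), , drop = FALSE]
      if (b$age_lo[1] != 0) {
        stop("coverage error: ", s, "/", m, "/0 not covered (first band starts at ",
             b$age_lo[1], ")")
      }
      if (nrow(b) > 1) {
        nxt <- b$age_lo[-1]
        prv <- b$age_hi[-nrow(b)]
        gap <- which(nxt > prv + 1L)
        if (length(gap) > 0) {
          stop("coverage error: ", s, "/", m, "/", prv[gap[1]] + 1L, " not covered")
        }
        ovl <- which(nxt <= prv)
        if (length(ovl) > 0) {
          stop("coverage error: overlapping bands for ", s, "/", m, " at age ",
               nxt[ovl[1]])
        }
      }
    }
  }
  structure(df, class = c("rate_table_set", "data.frame"))
}

#' Read a rate-table CSV
#'
#' Expects a UTF-8 CSV with header
#' `age_lo,age_hi,sex,metric,rate_per_100k`. Malformed rows are reported with
#' row numbers; gaps or overlaps in band coverage are reported naming the
#' offending (sex, metric, age).
#'
#' @param path Path to the CSV file.
#' @return A [rate_table_set()].
#' @export
read_rate_tables <- function(path) {
  if (!file.exists(path)) stop("rate table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rate_table_set(df)
}

#' Write a rate-table set to CSV
#'
#' @param tables A [rate_table_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_tables <- function(tables, path) {
  utils::write.csv(as.data.frame(tables), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up an annual rate per 100k for a single-year age
#'
#' Rates are piecewise constant within bands; ages above the top band's upper
#' edge resolve to the top (open-ended) band. Vectorised over `age`.
#'
#' @param tables A [rate_table_set()].
#' @param metric One of `"incidence"`, `"prevalence"`, `"disease_mortality"`,
#'   `"allcause_mortality"`.
#' @param sex `"male"` or `"female"`.
#' @param age Integer age(s) in years, >= 0.
#' @return Numeric rate(s) per 100,000 per year.
#' @export
lookup_rate <- function(tables, metric, sex, age) {
  stopifnot(inherits(tables, "rate_table_set"))
  metric <- match.arg(metric, .metrics)
  sex <- match.arg(sex, .sexes)
  if (any(age < 0)) stop("age must be non-negative")
  b <- tables[tables$sex == sex & tables$metric == metric, , drop = FALSE]
  b <- b[order(b$age_lo), , drop = FALSE]
  # findInterval on band lower edges; ages beyond the top edge stay in the top band
  idx <- findInterval(age, b$age_lo)
  b$rate_per_100k[idx]
}

#' Convert an annual rate per 100k to an annual probability
#'
#' The conversion is the direct quotient `rate / 100000` (no actuarial
#' `1 - exp(-r)` transformation): at the magnitudes of national disease and
#' mortality rates the difference is negligible, and the direct quotient is
#' what the Bernoulli-trial annual cycle uses. Values that would exceed 1 are
#' clamped to 1 with a warning.
#'
#' @param rate Numeric rate(s) per 100,000 per year; must be >= 0.
#' @return Probability in `[0, 1]`.
#' @export
rate_to_probability <- function(rate) {
  if (any(is.na(rate)) || any(rate < 0)) stop("rate must be non-negative")
  p <- rate / 1e5
  over <- p > 1
  if (any(over)) {
    warning(sum(over), " rate(s) above 100000 per 100k clamped to probability 1")
    p[over] <- 1
  }
  p
}

# Expand a rate_table_set to per-single-year-of-age probability vectors,
# ages 0..max_age, as a list [[metric]][[sex]] of numeric vectors (index age+1).
# Ages above the top band reuse the open-ended top band. Internal fast path
# for the engine; clamping here is silent (the engine aggregates clamp counts).
expand_rate_tables <- function(tables, max_age = 110L) {
  ages <- 0:max_age
  out <- list()
  for (m in .metrics) {
    out[[m]] <- list()
    for (s in .sexes) {
      r <- lookup_rate(tables, m, s, ages)
      out[[m]][[s]] <- pmin(r / 1e5, 1)
    }
  }
  out
}
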