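# Small-area profiles: deprivation decile, exposure, fertility, population table.

#' Construct an area profile
#'
#' One small area (census-geography unit of roughly 1500 residents) carries a
#' deprivation decile, annual-mean PM2.5 concentrations (total and
#' non-anthropogenic component), a general fertility rate, and an age-by-sex
#' population count table.
#'
#' @param area_id Character id.
#' @param imd_decile Integer 1-10, 1 = most deprived.
#' @param pm25_total Annual-mean PM2.5, ug/m3.
#' @param pm25_nonanthropogenic Non-anthropogenic component, ug/m3; must not
#'   exceed `pm25_total`.
#' @param gfr General fertility rate: live births per 1000 females aged 15-44
#'   per year.
#' @param population data.frame with columns `age` (integer years), `sex`
#'   (`"male"`/`"female"`), `count` (non-negative integer).
#' @return Object of class `area_profile`.
#' @export
area_profile <- function(area_id, imd_decile, pm25_total, pm25_nonanthropogenic,
                         gfr, population) {
  imd_decile <- as.integer(imd_decile)
  if (is.na(imd_decile) || imd_decile < 1L || imd_decile > 10L) {
    stop("imd_decile must be an integer in 1..10")
  }
  if (pm25_nonanthropogenic < 0 || pm25_nonanthropogenic > pm25_total) {
    stop("pm25_nonanthropogenic must lie in [0, pm25_total]")
  }
  if (gfr < 0) stop("gfr must be non-negative")
  population <- as.data.frame(population)
  stopifnot(all(c("age", "sex", "count") %in% names(population)))
  if (any(population$count < 0)) stop("population counts must be non-negative")
  if (any(!population$sex %in% .sexes)) stop("population sex must be male/female")
  structure(
    list(area_id = as.character(area_id), imd_decile = imd_decile,
         pm25_total = as.numeric(pm25_total),
         pm25_nonanthropogenic = as.numeric(pm25_nonanthropogenic),
         gfr = as.numeric(gfr), population = population),
    class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf(
    "<area_profile %s> IMD decile %d | PM2.5 %.2f (non-anth %.2f) ug/m3 | GFR %.1f | pop %d\n",
    x$area_id, x$imd_decile, x$pm25_total, x$pm25_nonanthropogenic, x$gfr,
    sum(x$population$count)))
  invisible(x)
}

#' Read area profiles from the areas/population CSV pair
#'
#' `areas.csv` has header `area_id,imd_decile,pm25_total,pm25_nonanthropogenic,gfr`;
#' `population.csv` has header `area_id,age,sex,count`. Every area must appear
#' in both files.
#'
#' @param areas_path Path to `areas.csv`.
#' @param population_path Path to `population.csv`.
#' @return Named list of [area_profile()] objects (names = area ids).
#' @export
read_area_profiles <- function(areas_path, population_path) {
  areas <- utils::read.csv(areas_path, stringsAsFactors = FALSE)
  pop <- utils::read.csv(population_path, stringsAsFactors = FALSE)
  required <- c("area_id", "imd_decile", "pm25_total", "pm25_nonanthropogenic", "gfr")
  if (!all(required %in% names(areas))) {
    stop("areas file must have columns: ", paste(required, collapse = ", "))
  }
  if (!all(c("area_id", "age", "sex", "count") %in% names(pop))) {
    stop("population file must have columns: area_id, age, sex, count")
  }
  pop_split <- split(pop[c("age", "sex", "count")], pop$area_id)
  profiles <- lapply(seq_len(nrow(areas)), function(i) {
    aid <- as.character(areas$area_id[i])
    ptab <- pop_split[[aid]]
    if (is.null(ptab)) stop("no population rows for area ", aid)
    area_profile(aid, areas$imd_decile[i], areas$pm25_total[i],
                 areas$pm25_nonanthropogenic[i], areas$gfr[i],
                 ptab[order(ptab$sex, ptab$age), , drop = FALSE])
  })
  names(profiles) <- as.character(areas$area_id)
  profiles
}

#' Write area profiles to the areas/population CSV pair
#'
#' @param profiles List of [area_profile()].
#' @param areas_path Output path for `areas.csv`.
#' @param population_path Output path for `population.csv`.
#' @return Invisibly, the two paths.
#' @export
write_area_profiles <- function(profiles, areas_path, population_path) {
  areas <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(area_id = p$area_id, imd_decile = p$imd_decile,
               pm25_total = p$pm25_total,
               pm25_nonanthropogenic = p$pm25_nonanthropogenic, gfr = p$gfr)
  }))
  pop <- do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(area_id = p$area_id), p$population)
  }))
  utils::write.csv(areas, areas_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(pop, population_path, row.names = FALSE, quote = FALSE)
  invisible(c(areas_path, population_path))
}
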