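#' Population-weighted regional life expectancy
#'
#' The regional life expectancy for one period/sex slice is the weighted
#' average of member-country life expectancies, with each country's
#' population size as the weight. Members absent from the slice are
#' reported via a message and the mean is taken over the available
#' members; no imputation is performed.
#'
#' @param panel An [panel()] object.
#' @param region A [region_definition()].
#' @param period Period label.
#' @param sex Sex code (`"female"`, `"male"`, `"both"`).
#' @return Weighted life expectancy in years (scalar).
#' @examples
#' p <- generate_equality_panel(3, "1965-1970", le = 65)
#' r <- region_definition("toy", c("C01", "C02", "C03"))
#' weighted_regional_le(p, r, "1965-1970", "both")
#' @export
weighted_regional_le <- function(panel, region, period, sex) {
  sl <- panel_slice(panel, region$members, period, sex)
  if (!nrow(sl)) {
    stop("no records for region ", dQuote(region$name), " in ",
         canonical_period(period), " / ", sex, call. = FALSE)
  }
  n_missing <- length(region$members) - nrow(sl)
  if (n_missing > 0) {
    message(n_missing, " member(s) of ", region$name,
            " missing from slice ", canonical_period(period), " / ", sex)
  }
  total_pop <- sum(sl$population)
  if (total_pop <= 0) {
    stop("total population is zero for region ", dQuote(region$name),
         " in ", canonical_period(period), " / ", sex,
         ": weights are degenerate", call. = FALSE)
  }
  sum(sl$population * sl$le) / total_pop
}

#' Life-expectancy gap against the world average
#'
#' Signed difference between a regional life expectancy and the world
#' average for the same period; positive values mean the region is above
#' the world average.
#'
#' @param region_le,world_le Life expectancies in years (vectorized).
#' @return `region_le - world_le`, in years.
#' @export
le_gap <- function(region_le, world_le) {
  stopifnot(is.finite(region_le), is.finite(world_le))
  region_le - world_le
}

#' Life-expectancy shortfall against the best comparator
#'
#' The deficit of a regional life expectancy relative to the best value in
#' a caller-supplied comparator set (for example, the weighted LE of each
#' of the world's sub-regions for the same period). When the comparator
#' set contains the region itself the shortfall is non-negative, and
#' exactly zero for the best-performing region.
#'
#' @param region_le Regional life expectancy in years (scalar).
#' @param comparator_les Non-empty numeric vector of comparator life
#'   expectancies in years.
#' @return `max(comparator_les) - region_le`, in years.
#' @examples
#' le_shortfall(60.8, c(71.5, 68.2, 60.8))   # 10.7
#' @export
le_shortfall <- function(region_le, comparator_les) {
  if (!length(comparator_les)) {
    stop("comparator set for the shortfall is empty", call. = FALSE)
  }
  stopifnot(is.finite(region_le), all(is.finite(comparator_les)))
  max(comparator_les) - region_le
}

#' Gender disparity summary
#'
#' Computes the female-minus-male difference, the percent difference with
#' the female life expectancy as denominator, and the female-to-male
#' ratio. All values are computed at full precision; rounding is deferred
#' to display.
#'
#' @param le_female,le_male Life expectancies in years (vectorized,
#'   strictly positive).
#' @return A tibble with columns `le_female`, `le_male`, `difference`
#'   (years), `pct_difference` (percent), `ratio`.
#' @examples
#' gender_summary(74.42, 69.26)
#' @export
gender_summary <- function(le_female, le_male) {
  if (any(le_female <= 0) || any(le_male <= 0)) {
    stop("life expectancies must be strictly positive", call. = FALSE)
  }
  tibble::tibble(
    le_female = le_female,
    le_male = le_male,
    difference = le_female - le_male,
    pct_difference = 100 * (le_female - le_male) / le_female,
    ratio = le_female / le_male
  )
}

#' Combine sex-specific life expectancies into a both-sex value
#'
#' Population-weighted mean of the female and male life expectancies,
#' used to derive "women & men" slices when the panel carries no explicit
#' `both` rows.
#'
#' @param le_female,le_male Life expectancies in years.
#' @param pop_female,pop_male Population sizes (non-negative, not both
#'   zero). Vectorized.
#' @return Combined life expectancy in years.
#' @export
both_sex_le <- function(le_female, le_male, pop_female, pop_male) {
  if (any(pop_female < 0) || any(pop_male < 0)) {
    stop("populations must be non-negative", call. = FALSE)
  }
  total <- pop_female + pop_male
  if (any(total == 0)) {
    stop("female and male populations cannot both be zero", call. = FALSE)
  }
  (pop_female * le_female + pop_male * le_male) / total
}

#' Regional life-expectancy series with gap and shortfall
#'
#' Builds the per-period weighted regional series for one sex, optionally
#' attaching the gap against a supplied world series and the shortfall
#' against a comparator series (one or more comparator values per period;
#' the per-period maximum is used).
#'
#' @param panel An [panel()] object.
#' @param region A [region_definition()].
#' @param sex Sex code.
#' @param world_le Optional data frame with columns `period` and `le`
#'   giving the world average per period.
#' @param comparator_les Optional data frame with columns `period` and
#'   `le`; multiple rows per period are allowed (e.g. all world
#'   sub-regions).
#' @return A tibble of class `regional_series`: `region`, `sex`, `period`,
#'   `weighted_le`, `gap`, `shortfall`, `total_population`, ordered by
#'   period.
#' @export
regional_series <- function(panel, region, sex = "both", world_le = NULL,
                            comparator_les = NULL) {
  sx <- normalize_sex(sex)
  periods <- sort_periods(unique(panel_slice(panel, region$members,
                                             sex = sx)$period))
  if (!length(periods)) {
    stop("panel has no records for region ", dQuote(region$name),
         " and sex ", sx, call. = FALSE)
  }
  rows <- lapply(periods, function(per) {
    sl <- panel_slice(panel, region$members, per, sx)
    tibble::tibble(
      region = region$name, sex = sx, period = per,
      weighted_le = sum(sl$population * sl$le) / sum(sl$population),
      total_population = sum(sl$population))
  })
  out <- dplyr::bind_rows(rows)
  out$gap <- NA_real_
  if (!is.null(world_le)) {
    w <- tibble::tibble(period = canonical_period(world_le$period),
                        world = world_le$le)
    out$gap <- out$weighted_le - w$world[match(out$period, w$period)]
  }
  out$shortfall <- NA_real_
  if (!is.null(comparator_les)) {
    cmp <- tibble::tibble(period = canonical_period(comparator_les$period),
                          le = comparator_les$le)
    best <- tapply(cmp$le, cmp$period, max)
    out$shortfall <- as.vector(best[out$period]) - out$weighted_le
  }
  out[c("region", "sex", "period", "weighted_le", "gap", "shortfall",
        "total_population")]
}
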