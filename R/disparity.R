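#' Range-based disparity: difference and ratio between best and worst
#'
#' `range_difference()` (LED) is the arithmetic difference in years
#' between the countries with the best and worst life expectancy;
#' `range_ratio()` (LER) divides the best by the worst. Both ignore every
#' country between the two extremes. Zero (LED) and one (LER) mean
#' equality.
#'
#' @param les Non-empty numeric vector of life expectancies in years.
#' @return LED in years, or LER (dimensionless).
#' @examples
#' range_difference(c(60.7, 80.1))  # 19.4
#' range_ratio(c(60.7, 80.1))       # 1.3196
#' @export
range_difference <- function(les) {
  check_les(les)
  max(les) - min(les)
}

#' @rdname range_difference
#' @export
range_ratio <- function(les) {
  check_les(les)
  if (min(les) <= 0) {
    stop("life expectancies must be strictly positive for the ratio",
         call. = FALSE)
  }
  max(les) / min(les)
}

#' Mean difference from the best-performing country
#'
#' For each country the deficit from the best life expectancy in the group
#' is taken; the deficits are summed and divided by the number of
#' countries. By default the reference (best) country is included in the
#' denominator with a zero term (`mode = "n"`); `mode = "n-1"` excludes
#' it, a variant found in the disparity literature.
#'
#' @param les Non-empty numeric vector of life expectancies in years.
#' @param mode Denominator convention, `"n"` (default) or `"n-1"`.
#' @return MD in years.
#' @examples
#' mean_difference_from_best(c(70, 68, 64))  # 8/3
#' @export
mean_difference_from_best <- function(les, mode = c("n", "n-1")) {
  check_les(les)
  mode <- match.arg(mode)
  n <- if (mode == "n") length(les) else max(length(les) - 1L, 1L)
  sum(max(les) - les) / n
}

#' Index of disparity
#'
#' The mean difference from best expressed as a percentage of the
#' reference (best) country's life expectancy; the relative counterpart
#' of [mean_difference_from_best()].
#'
#' @inheritParams mean_difference_from_best
#' @return ID in percent.
#' @export
index_of_disparity <- function(les, mode = c("n", "n-1")) {
  check_les(les)
  if (max(les) <= 0) {
    stop("reference life expectancy must be strictly positive", call. = FALSE)
  }
  100 * mean_difference_from_best(les, mode) / max(les)
}

#' Between-group variance
#'
#' Population-share-weighted variance of country life expectancies about
#' the weighted regional mean: `sum(p_i * (le_i - mu)^2)` with
#' `p_i = pop_i / sum(pop)` and `mu = sum(p_i * le_i)`. The squared term
#' makes BGV sensitive to large deviations. Units: years squared.
#'
#' @param les Numeric vector of life expectancies in years.
#' @param populations Population sizes, same length as `les`, with a
#'   positive total.
#' @return BGV in years^2.
#' @examples
#' between_group_variance(c(60, 70), c(1, 1))  # 25
#' @export
between_group_variance <- function(les, populations) {
  check_les(les)
  if (length(les) != length(populations)) {
    stop("les and populations must have the same length", call. = FALSE)
  }
  if (any(populations < 0) || sum(populations) <= 0) {
    stop("populations must be non-negative with a positive total",
         call. = FALSE)
  }
  p <- populations / sum(populations)
  mu <- sum(p * les)
  sum(p * (les - mu)^2)
}

#' Theil index, mean log deviation, and the symmetric Theil index
#'
#' Entropy-based relative inequality measures on population shares `p_i`
#' and the weighted mean `mu`:
#' Theil `T = sum(p_i * (le_i/mu) * log(le_i/mu))`, mean log deviation
#' `MLD = sum(p_i * log(mu/le_i))`. The symmetric Theil index is their
#' average, `scale * (T + MLD) / 2`, equally sensitive to deviations above
#' and below the mean. For life-expectancy data the unscaled values are
#' tiny, so a reporting multiplier (conventionally 1000) is applied to the
#' STI; `theil` and `mld` are always returned unscaled.
#'
#' @inheritParams between_group_variance
#' @param scale Reporting multiplier applied to the STI (default 1000).
#' @return A list with `theil`, `mld` (unscaled) and `sti` (scaled).
#' @export
symmetric_theil <- function(les, populations, scale = 1000) {
  check_les(les)
  if (any(les <= 0)) {
    stop("life expectancies must be strictly positive for entropy measures",
         call. = FALSE)
  }
  if (length(les) != length(populations)) {
    stop("les and populations must have the same length", call. = FALSE)
  }
  if (any(populations < 0) || sum(populations) <= 0) {
    stop("populations must be non-negative with a positive total",
         call. = FALSE)
  }
  p <- populations / sum(populations)
  mu <- sum(p * les)
  r <- les / mu
  theil <- sum(p * r * log(r))
  mld <- sum(p * log(1 / r))
  list(theil = theil, mld = mld, sti = scale * (theil + mld) / 2)
}

check_les <- function(les) {
  if (!length(les)) stop("life-expectancy vector is empty", call. = FALSE)
  if (any(!is.finite(les))) {
    stop("life expectancies must be finite", call. = FALSE)
  }
  invisible(les)
}

#' Full disparity suite for one region/period/sex slice
#'
#' Computes all six between-country disparity metrics on the same member
#' slice: three absolute (LED, MD, BGV) and three relative (LER, ID, STI)
#' measures. The reference country is the member with the highest life
#' expectancy; ties are broken lexicographically by country id and the
#' tie-break is reported with a message.
#'
#' @param panel An [panel()] object.
#' @param region A [region_definition()].
#' @param period Period label.
#' @param sex Sex code.
#' @param sti_scale Reporting multiplier for the STI.
#' @param md_mode Denominator convention for MD and ID, `"n"` or `"n-1"`.
#' @return A one-row tibble of class `disparity_suite`: `region`,
#'   `period`, `sex`, `n_countries`, `led`, `ler`, `md`, `id_pct`, `bgv`,
#'   `sti`, `theil`, `mld`, `reference_country`, `weighted_mean`,
#'   `sti_scale`.
#' @examples
#' p <- generate_panel(generator_config(n_countries = 5, seed = 1))
#' r <- region_definition("toy", paste0("C0", 1:5))
#' disparity_suite(p, r, "1965-1970", "both")
#' @export
disparity_suite <- function(panel, region, period, sex, sti_scale = 1000,
                            md_mode = c("n", "n-1")) {
  md_mode <- match.arg(md_mode)
  sl <- panel_slice(panel, region$members, period, sex)
  if (!nrow(sl)) {
    stop("no records for region ", dQuote(region$name), " in ",
         canonical_period(period), " / ", sex, call. = FALSE)
  }
  best <- sl$le == max(sl$le)
  if (sum(best) > 1) {
    message("tie for best life expectancy in ", region$name, " ",
            canonical_period(period), "; broken lexicographically")
  }
  reference <- sort(sl$country[best])[1]
  st <- symmetric_theil(sl$le, sl$population, scale = sti_scale)
  p <- sl$population / sum(sl$population)
  structure(tibble::tibble(
    region = region$name,
    period = canonical_period(period),
    sex = normalize_sex(sex),
    n_countries = nrow(sl),
    led = range_difference(sl$le),
    ler = range_ratio(sl$le),
    md = mean_difference_from_best(sl$le, md_mode),
    id_pct = index_of_disparity(sl$le, md_mode),
    bgv = between_group_variance(sl$le, sl$population),
    sti = st$sti,
    theil = st$theil,
    mld = st$mld,
    reference_country = reference,
    weighted_mean = sum(p * sl$le),
    sti_scale = sti_scale
  ), class = c("disparity_suite", class(tibble::tibble())))
}

#' Percent change between two values
#'
#' @param v_from Baseline value (non-zero).
#' @param v_to Final value. Vectorized.
#' @return `100 * (v_to - v_from) / v_from`, in percent.
#' @examples
#' percent_change(1.55, 1.33)  # -14.19
#' @export
percent_change <- function(v_from, v_to) {
  if (any(v_from == 0)) {
    stop("percent change is undefined for a zero baseline", call. = FALSE)
  }
  100 * (v_to - v_from) / v_from
}

#' Per-metric percent change between two disparity suites
#'
#' @param suite_from,suite_to One-row [disparity_suite()] results for the
#'   baseline and final periods of the same region/sex.
#' @return A one-row tibble: `from_period`, `to_period`, the six
#'   per-metric percent changes (`ler`, `led`, `md`, `id_pct`, `sti`,
#'   `bgv`), and the averaged `avg_absolute`/`avg_relative` reductions.
#' @export
suite_change <- function(suite_from, suite_to) {
  stopifnot(inherits(suite_from, "disparity_suite"),
            inherits(suite_to, "disparity_suite"))
  metrics <- c("ler", "led", "md", "id_pct", "sti", "bgv")
  # a metric resting at its equality value in both periods is an unchanged
  # (0%) trend, not an undefined one
  ch <- vapply(metrics, function(m) {
    from <- suite_from[[m]]
    to <- suite_to[[m]]
    if (from == 0 && to == 0) 0 else percent_change(from, to)
  }, numeric(1))
  avg <- average_reduction(ch)
  tibble::tibble(
    region = suite_from$region, sex = suite_from$sex,
    from_period = suite_from$period, to_period = suite_to$period,
    ler = ch[["ler"]], led = ch[["led"]], md = ch[["md"]],
    id_pct = ch[["id_pct"]], sti = ch[["sti"]], bgv = ch[["bgv"]],
    avg_absolute = avg$avg_absolute, avg_relative = avg$avg_relative
  )
}

#' Averaged absolute and relative disparity reductions
#'
#' The headline trend summary: the arithmetic mean of the percent changes
#' of the three absolute metrics (LED, MD, BGV) and of the three relative
#' metrics (LER, ID, STI).
#'
#' @param changes Named numeric vector (or list) of six per-metric percent
#'   changes with names `ler`, `led`, `md`, `id_pct`, `sti`, `bgv`
#'   (`id`/`id_pct` both accepted).
#' @return A list with `avg_absolute` and `avg_relative`, in percent.
#' @examples
#' average_reduction(c(ler = -13.73, led = -20.6, md = -6.02,
#'                     id_pct = -16.94, sti = -39.66, bgv = -15.09))
#' @export
average_reduction <- function(changes) {
  ch <- unlist(changes)
  names(ch)[names(ch) == "id"] <- "id_pct"
  needed <- c("ler", "led", "md", "id_pct", "sti", "bgv")
  missing_m <- setdiff(needed, names(ch))
  if (length(missing_m)) {
    stop("missing per-metric change(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  list(avg_absolute = mean(ch[c("led", "md", "bgv")]),
       avg_relative = mean(ch[c("ler", "id_pct", "sti")]))
}
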