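#' Configuration for the synthetic panel generator
#'
#' Describes a synthetic country-period life-expectancy panel with the
#' structure of five-yearly United Nations demographic summaries: a
#' cohort of countries observed over the nine periods 1965-1970 to
#' 2005-2010, sex-specific life expectancy with women outliving men,
#' log-normally spread population sizes held constant over time, linear
#' secular gains with country-specific slopes, and an optional
#' heavy-population low-longevity outlier member.
#'
#' Defaults echo mid-1960s developing-region magnitudes: a both-sex
#' baseline around 60 years, gains near 0.3 years of life per calendar
#' year, and a 5-year female advantage. The outlier scenario (deficit 15
#' years, 22% of regional population) mimics a large low-longevity member
#' of an otherwise typical region.
#'
#' @param n_countries Number of countries (>= 1).
#' @param periods Character vector of period labels.
#' @param baseline_mean,baseline_sd Both-sex baseline LE (years) drawn per
#'   country from a normal distribution.
#' @param annual_gain_mean,annual_gain_sd Per-country secular gain in
#'   years of life per calendar year.
#' @param gender_gap_mean,gender_gap_sd Female-minus-male gap in years,
#'   drawn per country.
#' @param population_log_mean,population_log_sd Log-normal population
#'   parameters (log persons).
#' @param outlier `NULL`, or a list with `le_deficit` (years subtracted
#'   from the first country's baseline) and `population_share` (its share
#'   of total regional population, in (0, 1)).
#' @param noise_sd Per-observation noise on both-sex LE, years.
#' @param seed Integer seed making the panel reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_countries = 21,
                             periods = default_periods(),
                             baseline_mean = 60, baseline_sd = 4,
                             annual_gain_mean = 0.3, annual_gain_sd = 0.08,
                             gender_gap_mean = 5, gender_gap_sd = 1,
                             population_log_mean = log(5e5),
                             population_log_sd = 1.2,
                             outlier = NULL, noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              periods = canonical_period(periods),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              annual_gain_mean = annual_gain_mean,
              annual_gain_sd = annual_gain_sd,
              gender_gap_mean = gender_gap_mean,
              gender_gap_sd = gender_gap_sd,
              population_log_mean = population_log_mean,
              population_log_sd = population_log_sd,
              outlier = outlier, noise_sd = noise_sd, seed = as.integer(seed))
  sds <- c(cfg$baseline_sd, cfg$annual_gain_sd, cfg$gender_gap_sd,
           cfg$population_log_sd, cfg$noise_sd)
  if (cfg$n_countries < 1L) stop("n_countries must be >= 1", call. = FALSE)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (!is.null(outlier)) {
    if (is.null(outlier$le_deficit) || is.null(outlier$population_share) ||
        outlier$population_share <= 0 || outlier$population_share >= 1) {
      stop("outlier needs le_deficit and population_share in (0, 1)",
           call. = FALSE)
    }
  }
  structure(cfg, class = "generator_config")
}

#' The outlier scenario configuration
#'
#' Convenience wrapper for a 21-country region containing one
#' heavy-population low-longevity member: baseline deficit 15 years,
#' 22% of the regional population.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
outlier_config <- function(seed = 1L, ...) {
  generator_config(outlier = list(le_deficit = 15, population_share = 0.22),
                   seed = seed, ...)
}

#' Generate a synthetic country-period life-expectancy panel
#'
#' For each country a both-sex baseline, a linear secular gain and a
#' gender gap are drawn once; each period's both-sex LE is the baseline
#' plus the gain times the years elapsed since the first period's
#' midpoint, plus observation noise. Female and male rows sit half a
#' gender gap above and below the both-sex value (floored so both stay
#' positive), so the `both` row equals the equal-weight mean of the sexes,
#' consistent with the sex-specific populations being half the country
#' total. Populations are log-normal and constant over time. With an
#' outlier configured, the first country's baseline is lowered by
#' `le_deficit` and its population set so that it holds
#' `population_share` of the regional total.
#'
#' @param config A [generator_config()].
#' @return An [panel()] with rows for sexes `female`, `male` and `both`
#'   for every country x period.
#' @examples
#' p <- generate_panel(generator_config(n_countries = 3, seed = 42))
#' dplyr::count(p, sex)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_countries
  ids <- sprintf("C%02d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  gain <- stats::rnorm(n, config$annual_gain_mean, config$annual_gain_sd)
  gap <- stats::rnorm(n, config$gender_gap_mean, config$gender_gap_sd)
  pop <- stats::rlnorm(n, config$population_log_mean, config$population_log_sd)
  if (!is.null(config$outlier)) {
    baseline[1] <- baseline[1] - config$outlier$le_deficit
    share <- config$outlier$population_share
    pop[1] <- share / (1 - share) * sum(pop[-1])
  }
  mid <- period_midpoint(config$periods)
  elapsed <- mid - mid[1]
  grid <- expand.grid(country = seq_len(n), t = seq_along(config$periods))
  le_both <- baseline[grid$country] + gain[grid$country] * elapsed[grid$t] +
    stats::rnorm(nrow(grid), 0, config$noise_sd)
  half_gap <- gap[grid$country] / 2
  # keep both sexes strictly positive even under extreme draws
  half_gap <- pmin(half_gap, le_both - 0.1)
  half_gap <- pmax(half_gap, -(le_both - 0.1))
  le_f <- le_both + half_gap
  le_m <- le_both - half_gap
  base_rows <- tibble::tibble(country = ids[grid$country],
                              period = config$periods[grid$t],
                              pop = pop[grid$country])
  records <- dplyr::bind_rows(
    dplyr::mutate(base_rows, sex = "female", le = le_f,
                  population = pop / 2),
    dplyr::mutate(base_rows, sex = "male", le = le_m,
                  population = pop / 2),
    dplyr::mutate(base_rows, sex = "both", le = le_both,
                  population = pop))
  records$pop <- NULL
  panel(records, provenance = sprintf(
    "synthetic panel (n_countries=%d, seed=%d)", n, config$seed))
}

#' Generate a degenerate equal-LE panel
#'
#' Every country, period, and sex shares one life expectancy with unit
#' populations: a fixture on which every disparity metric is at its
#' equality value (zero, or one for the range ratio).
#'
#' @param n_countries Number of countries.
#' @param periods Character vector of period labels.
#' @param le The shared life expectancy in years (> 0).
#' @return An [panel()].
#' @export
generate_equality_panel <- function(n_countries, periods = default_periods(),
                                    le = 65) {
  stopifnot(le > 0, n_countries >= 1)
  ids <- sprintf("C%02d", seq_len(n_countries))
  grid <- expand.grid(country = ids, period = canonical_period(periods),
                      sex = c("female", "male", "both"),
                      stringsAsFactors = FALSE)
  panel(tibble::tibble(country = grid$country, period = grid$period,
                       sex = grid$sex, le = le, population = 1),
        provenance = "synthetic equality panel")
}

#' Region definition covering every country of a generated panel
#'
#' @param panel A generated [panel()].
#' @param name Region name.
#' @return A [region_definition()] whose members are all panel countries.
#' @export
panel_region <- function(panel, name = "synthetic-region") {
  region_definition(name, sort(unique(panel$country)))
}
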