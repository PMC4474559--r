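#' Leave-one-out region-membership sensitivity analysis
#'
#' Removes each member country in turn and recomputes the region's
#' weighted life expectancy in a baseline and an end period, the change
#' between them (years and percent), and the percent change over time of
#' selected disparity metrics (mean difference from best and index of
#' disparity by default). This quantifies how much any single country
#' drives the regional aggregate and its disparity trend.
#'
#' @param panel An [panel()] object.
#' @param region A [region_definition()] with at least two members.
#' @param periods Length-2 vector `c(base, end)` of period labels.
#' @param sex Sex code.
#' @param sti_scale Reporting multiplier for the STI (relevant when `sti`
#'   is among `metrics`).
#' @param metrics Disparity-suite columns whose between-period percent
#'   change is recomputed under each removal; any of `led`, `ler`, `md`,
#'   `id_pct`, `sti`, `bgv`.
#' @param md_mode Denominator convention for MD/ID.
#' @return A tibble with one row per removed country: `removed_country`,
#'   `le_without_base`, `le_without_end`, `delta_le_base`, `delta_le_end`
#'   (change in the aggregate caused by the removal), `le_change_years`,
#'   `le_change_pct` (between-period change of the reduced region), one
#'   `<metric>_change_pct` column per requested metric, and `flag`
#'   (non-`NA` when the removed country is absent from a period). The
#'   full-region baseline is attached as attribute `"baseline"`.
#' @examples
#' p <- generate_panel(generator_config(n_countries = 5, seed = 1))
#' r <- region_definition("toy", paste0("C0", 1:5))
#' rows <- leave_one_out(p, r, c("1965-1970", "2005-2010"), "both")
#' summarize_sensitivity(rows)
#' @export
leave_one_out <- function(panel, region, periods, sex = "both",
                          sti_scale = 1000, metrics = c("md", "id_pct"),
                          md_mode = c("n", "n-1")) {
  md_mode <- match.arg(md_mode)
  stopifnot(length(periods) == 2L)
  metrics <- match.arg(metrics, c("led", "ler", "md", "id_pct", "sti", "bgv"),
                       several.ok = TRUE)
  if (length(region$members) < 2L) {
    stop("leave-one-out needs a region with at least two members",
         call. = FALSE)
  }
  base <- canonical_period(periods[1])
  end <- canonical_period(periods[2])
  sx <- normalize_sex(sex)

  slice_stats <- function(members, per) {
    sl <- panel_slice(panel, members, per, sx)
    if (!nrow(sl) || sum(sl$population) <= 0) return(NULL)
    suite <- disparity_suite(panel, region_definition(region$name, members),
                             per, sx, sti_scale = sti_scale,
                             md_mode = md_mode)
    list(le = sum(sl$population * sl$le) / sum(sl$population), suite = suite)
  }

  full_base <- slice_stats(region$members, base)
  full_end <- slice_stats(region$members, end)
  if (is.null(full_base) || is.null(full_end)) {
    stop("region ", dQuote(region$name),
         " has no usable records in one of the requested periods",
         call. = FALSE)
  }
  baseline <- list(
    le_base = full_base$le, le_end = full_end$le,
    le_change_years = full_end$le - full_base$le,
    le_change_pct = percent_change(full_base$le, full_end$le))
  # a metric at its equality value in both periods is an unchanged trend;
  # a move off an exact zero has no defined percent change and yields NA
  metric_change <- function(from, to) {
    if (from == 0 && to == 0) 0
    else if (from == 0) NA_real_
    else percent_change(from, to)
  }
  for (m in metrics) {
    baseline[[paste0(m, "_change_pct")]] <-
      metric_change(full_base$suite[[m]], full_end$suite[[m]])
  }

  present_base <- panel_slice(panel, region$members, base, sx)$country
  present_end <- panel_slice(panel, region$members, end, sx)$country

  rows <- lapply(region$members, function(cty) {
    keep <- setdiff(region$members, cty)
    rb <- slice_stats(keep, base)
    re <- slice_stats(keep, end)
    flag <- NA_character_
    if (!cty %in% present_base || !cty %in% present_end) {
      flag <- "removed country absent from a period; removal is a no-op there"
    }
    row <- tibble::tibble(
      removed_country = cty,
      le_without_base = if (is.null(rb)) NA_real_ else rb$le,
      le_without_end = if (is.null(re)) NA_real_ else re$le,
      delta_le_base = if (is.null(rb)) NA_real_ else rb$le - full_base$le,
      delta_le_end = if (is.null(re)) NA_real_ else re$le - full_end$le)
    row$le_change_years <- row$le_without_end - row$le_without_base
    row$le_change_pct <- if (is.null(rb) || is.null(re)) NA_real_ else
      percent_change(rb$le, re$le)
    for (m in metrics) {
      row[[paste0(m, "_change_pct")]] <- if (is.null(rb) || is.null(re))
        NA_real_ else metric_change(rb$suite[[m]], re$suite[[m]])
    }
    row$flag <- flag
    row
  })
  structure(dplyr::bind_rows(rows), baseline = baseline,
            periods = c(base = base, end = end))
}

#' Summarize a leave-one-out sensitivity analysis
#'
#' Reports, for each period, the range of the reduced-region life
#' expectancy across removals together with the country whose removal is
#' responsible for each extreme, and likewise for the index-of-disparity
#' trend change (when present in the rows). The full-region baseline is
#' carried over for comparison.
#'
#' @param rows Output of [leave_one_out()].
#' @return A list with elements `le_base`, `le_end` (each: `min`, `max`,
#'   `min_country`, `max_country`), `id_change_pct` when available, and
#'   `baseline`.
#' @export
summarize_sensitivity <- function(rows) {
  if (!nrow(rows)) stop("no sensitivity rows to summarize", call. = FALSE)
  range_of <- function(v) {
    ok <- which(!is.na(v))
    list(min = min(v[ok]), max = max(v[ok]),
         min_country = rows$removed_country[ok[which.min(v[ok])]],
         max_country = rows$removed_country[ok[which.max(v[ok])]])
  }
  out <- list(le_base = range_of(rows$le_without_base),
              le_end = range_of(rows$le_without_end))
  if ("id_pct_change_pct" %in% names(rows)) {
    out$id_change_pct <- range_of(rows$id_pct_change_pct)
  }
  if ("md_change_pct" %in% names(rows)) {
    out$md_change_pct <- range_of(rows$md_change_pct)
  }
  out$baseline <- attr(rows, "baseline")
  out
}
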