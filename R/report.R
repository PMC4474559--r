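#' Derive missing both-sex rows from sex-specific rows
#'
#' For each country x period with `female` and `male` rows but no `both`
#' row, adds a `both` row whose life expectancy is the population-weighted
#' mean of the two sexes (see [both_sex_le()]) and whose population is the
#' sex total.
#'
#' @param panel An [panel()] object.
#' @return An [panel()] with `both` rows present wherever both sexes are.
#' @export
ensure_both_sex <- function(panel) {
  df <- tibble::as_tibble(panel)
  wide <- tidyr::pivot_wider(df, id_cols = c("country", "period"),
                             names_from = "sex",
                             values_from = c("le", "population"))
  need <- c("le_female", "le_male", "population_female", "population_male")
  if (!all(need %in% names(wide))) return(panel)
  has_both <- if ("le_both" %in% names(wide)) !is.na(wide$le_both) else
    rep(FALSE, nrow(wide))
  derivable <- !has_both & !is.na(wide$le_female) & !is.na(wide$le_male)
  if (!any(derivable)) return(panel)
  w <- wide[derivable, ]
  new_rows <- tibble::tibble(
    country = w$country, period = w$period, sex = "both",
    le = both_sex_le(w$le_female, w$le_male,
                     w$population_female, w$population_male),
    population = w$population_female + w$population_male)
  panel(dplyr::bind_rows(df, new_rows), provenance = attr(panel, "provenance"))
}

#' Configuration for a full trend-analysis run
#'
#' @param panel Path to a panel CSV, or an [panel()] object.
#' @param regions Path to a region config, or a list of
#'   [region_definition()]s.
#' @param period_pair Length-2 vector `c(base, end)` for the change
#'   analysis.
#' @param sexes Sex modes to compute (`"female"`, `"male"`, `"both"`).
#' @param comparator_les Optional data frame (`period`, `le`) of external
#'   comparator life expectancies for the shortfall; when `NULL` the
#'   per-period best among the configured regions is used.
#' @param world_le Optional data frame (`period`, `le`) of world averages
#'   for the gap; when `NULL` the gap is left `NA`.
#' @param sti_scale Reporting multiplier for the STI.
#' @param md_mode MD/ID denominator convention, `"n"` or `"n-1"`.
#' @param combined_mode How "women & men" suites are obtained:
#'   `"both-sex"` computes on both-sex LE slices (derived with
#'   [ensure_both_sex()] when absent); `"average-of-suites"` averages the
#'   female and male suite values.
#' @param out_dir Output directory for the CSV bundle and run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel, regions, period_pair,
                       sexes = c("female", "male", "both"),
                       comparator_les = NULL, world_le = NULL,
                       sti_scale = 1000, md_mode = "n",
                       combined_mode = c("both-sex", "average-of-suites"),
                       out_dir = tempfile("dispaq-run-")) {
  stopifnot(length(period_pair) == 2L)
  pp <- canonical_period(period_pair)
  if (parse_period(pp[1])$start >= parse_period(pp[2])$start) {
    stop("period_pair must be ordered (base before end)", call. = FALSE)
  }
  structure(list(panel = panel, regions = regions, period_pair = pp,
                 sexes = normalize_sex(sexes),
                 comparator_les = comparator_les, world_le = world_le,
                 sti_scale = sti_scale, md_mode = md_mode,
                 combined_mode = match.arg(combined_mode),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full disparity trend analysis
#'
#' Ties the stages together for a set of regions: per-period weighted
#' regional series with gap and shortfall, gender disparity summaries for
#' the base and end periods, the six-metric disparity suite with percent
#' changes between the two periods per sex mode, and the averaged
#' absolute/relative reduction summary. Writes a CSV bundle plus a run
#' log recording the active analysis modes, and returns the tables
#' invisibly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with tibbles `series`, `gender`, `suites`,
#'   `changes`, `summary`, and `paths` (the files written).
#' @export
run_trend_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pan <- if (inherits(config$panel, "le_panel")) config$panel else
    read_panel(config$panel)
  regions <- if (is.character(config$regions))
    load_region_definitions(config$regions) else config$regions
  if (inherits(regions, "region_definition")) regions <- list(regions)
  pan <- ensure_both_sex(pan)
  pp <- config$period_pair
  log_lines <- c(
    sprintf("dispaq %s run", as.character(utils::packageVersion("dispaq"))),
    sprintf("regions: %s", paste(vapply(regions, `[[`, "", "name"),
                                 collapse = ", ")),
    sprintf("period pair: %s -> %s", pp[1], pp[2]),
    sprintf("mode md_denominator: %s", config$md_mode),
    sprintf("mode combined_sex: %s", config$combined_mode),
    sprintf("mode sti_scale: %g", config$sti_scale),
    sprintf("mode shortfall_comparators: %s",
            if (is.null(config$comparator_les)) "best configured region"
            else "external series"))
  note <- function(msg) log_lines <<- c(log_lines, paste("note:", msg))

  vr <- validate_panel(pan, regions)
  if (nrow(vr$issues)) {
    note(sprintf("%d validation issue(s); run continues", nrow(vr$issues)))
  }

  series <- withCallingHandlers(
    dplyr::bind_rows(lapply(regions, function(def) {
      dplyr::bind_rows(lapply(config$sexes, function(sx) {
        regional_series(pan, def, sx, world_le = config$world_le)
      }))
    })),
    message = function(m) {
      note(trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  cmp <- config$comparator_les
  if (is.null(cmp)) {
    cmp <- series[series$sex == "both", c("period", "weighted_le")]
    names(cmp) <- c("period", "le")
  }
  best <- tapply(cmp$le, canonical_period(cmp$period), max)
  idx <- match(series$period, names(best))
  series$shortfall <- ifelse(series$sex == "both" & !is.na(idx),
                             unname(best[idx]) - series$weighted_le,
                             series$shortfall)

  gender <- dplyr::bind_rows(lapply(regions, function(def) {
    dplyr::bind_rows(lapply(pp, function(per) {
      lf <- weighted_regional_le_quiet(pan, def, per, "female")
      lm <- weighted_regional_le_quiet(pan, def, per, "male")
      lo <- weighted_regional_le_quiet(pan, def, per, "both")
      dplyr::bind_cols(tibble::tibble(region = def$name, period = per,
                                      le_overall = lo),
                       gender_summary(lf, lm))
    }))
  }))

  one_suite <- function(def, per, sx) {
    if (sx == "both" && config$combined_mode == "average-of-suites") {
      sf <- disparity_suite(pan, def, per, "female",
                            sti_scale = config$sti_scale,
                            md_mode = config$md_mode)
      sm <- disparity_suite(pan, def, per, "male",
                            sti_scale = config$sti_scale,
                            md_mode = config$md_mode)
      out <- sf
      for (m in c("led", "ler", "md", "id_pct", "bgv", "sti", "theil",
                  "mld", "weighted_mean")) {
        out[[m]] <- (sf[[m]] + sm[[m]]) / 2
      }
      out$sex <- "both"
      out
    } else {
      disparity_suite(pan, def, per, sx, sti_scale = config$sti_scale,
                      md_mode = config$md_mode)
    }
  }
  suites <- list(); changes <- list()
  for (def in regions) {
    for (sx in config$sexes) {
      s_from <- withCallingHandlers(one_suite(def, pp[1], sx),
        message = function(m) { note(trimws(conditionMessage(m)))
                                invokeRestart("muffleMessage") })
      s_to <- withCallingHandlers(one_suite(def, pp[2], sx),
        message = function(m) { note(trimws(conditionMessage(m)))
                                invokeRestart("muffleMessage") })
      suites[[length(suites) + 1L]] <- dplyr::bind_rows(s_from, s_to)
      changes[[length(changes) + 1L]] <- suite_change(s_from, s_to)
    }
  }
  suites <- dplyr::bind_rows(suites)
  changes <- dplyr::bind_rows(changes)
  summary_tbl <- changes[c("region", "sex", "avg_absolute", "avg_relative")]

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(series = file.path(config$out_dir, "regional_series.csv"),
             gender = file.path(config$out_dir, "gender_disparity.csv"),
             suites = file.path(config$out_dir, "disparity_suites.csv"),
             changes = file.path(config$out_dir, "suite_changes.csv"),
             summary = file.path(config$out_dir, "reduction_summary.csv"),
             log = file.path(config$out_dir, "run.log"))
  readr::write_csv(series, paths[["series"]], progress = FALSE)
  readr::write_csv(gender, paths[["gender"]], progress = FALSE)
  readr::write_csv(suites, paths[["suites"]], progress = FALSE)
  readr::write_csv(changes, paths[["changes"]], progress = FALSE)
  readr::write_csv(summary_tbl, paths[["summary"]], progress = FALSE)
  writeLines(log_lines, paths[["log"]])

  invisible(list(series = series, gender = gender, suites = suites,
                 changes = changes, summary = summary_tbl, paths = paths,
                 validation = vr, log = log_lines))
}

weighted_regional_le_quiet <- function(...) {
  suppressMessages(weighted_regional_le(...))
}

#' Display-rounding helpers
#'
#' Life expectancies, metric values and percent changes are displayed at
#' two decimals; headline average reductions as a whole-percent magnitude
#' ("14%" for an average change of -13.90%). All internal arithmetic is
#' full precision; these helpers are applied only at the rendering stage.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_metric <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = 2))
}

#' @rdname format_metric
#' @export
format_headline_reduction <- function(x) {
  sprintf("%d%%", as.integer(round(abs(x))))
}

#' Render plain-text report tables
#'
#' Renders the gender table, the disparity-suite table with interleaved
#' percent-change rows (column order: LER, LED, then MD, ID, STI, BGV),
#' and the headline reduction summary as fixed-width text.
#'
#' @param outputs The list returned by [run_trend_analysis()].
#' @return A named character vector of rendered tables (`gender`,
#'   `suites`, `summary`), each a single multi-line string.
#' @export
format_report_tables <- function(outputs) {
  fmt_df <- function(df) {
    txt <- rbind(names(df), as.matrix(df))
    widths <- apply(nchar(txt), 2, max)
    lines <- apply(txt, 1, function(r)
      paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
    paste(trimws(lines, which = "right"), collapse = "\n")
  }

  g <- outputs$gender
  gender_tbl <- tibble::tibble(
    Region = g$region, Period = g$period,
    `LE (overall)` = format_metric(g$le_overall),
    `LE (women)` = format_metric(g$le_female),
    `LE (men)` = format_metric(g$le_male),
    `F:M Difference` = format_metric(g$difference),
    `% Difference` = format_metric(g$pct_difference),
    `F:M Ratio` = format_metric(g$ratio))

  s <- outputs$suites
  ch <- outputs$changes
  suite_rows <- list()
  for (i in seq_len(nrow(ch))) {
    blk <- s[s$region == ch$region[i] & s$sex == ch$sex[i], ]
    for (j in seq_len(nrow(blk))) {
      suite_rows[[length(suite_rows) + 1L]] <- tibble::tibble(
        Region = blk$region[j], Sex = blk$sex[j], Period = blk$period[j],
        LER = format_metric(blk$ler[j]), LED = format_metric(blk$led[j]),
        MD = format_metric(blk$md[j]), ID = format_metric(blk$id_pct[j]),
        STI = format_metric(blk$sti[j]), BGV = format_metric(blk$bgv[j]))
    }
    suite_rows[[length(suite_rows) + 1L]] <- tibble::tibble(
      Region = ch$region[i], Sex = ch$sex[i], Period = "% change",
      LER = format_metric(ch$ler[i]), LED = format_metric(ch$led[i]),
      MD = format_metric(ch$md[i]), ID = format_metric(ch$id_pct[i]),
      STI = format_metric(ch$sti[i]), BGV = format_metric(ch$bgv[i]))
  }
  suite_tbl <- if (length(suite_rows)) dplyr::bind_rows(suite_rows) else
    tibble::tibble(Region = character(), Sex = character(),
                   Period = character(), LER = character(),
                   LED = character(), MD = character(), ID = character(),
                   STI = character(), BGV = character())

  sm <- outputs$summary
  summary_tbl <- tibble::tibble(
    Region = sm$region, Sex = sm$sex,
    `Avg reduction (absolute)` = format_headline_reduction(sm$avg_absolute),
    `Avg reduction (relative)` = format_headline_reduction(sm$avg_relative))

  c(gender = fmt_df(gender_tbl), suites = fmt_df(suite_tbl),
    summary = fmt_df(summary_tbl))
}
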