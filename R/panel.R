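#' Construct a life-expectancy panel
#'
#' A panel holds one row per country x period x sex, with life expectancy
#' at birth (`le`, years) and population size (`population`, persons).
#' Period labels are normalized to `"YYYY-YYYY"` and the
#' (country, period, sex) key must be unique.
#'
#' @param data A data frame with columns `country`, `period`, `sex`, `le`,
#'   `population`.
#' @param provenance Free-text note recording where the data came from.
#' @return A tibble of class `le_panel` with normalized columns and a
#'   `provenance` attribute.
#' @examples
#' panel(data.frame(country = c("A", "B"), period = "1965-70",
#'                  sex = "both", le = c(60, 70), population = 1))
#' @export
panel <- function(data, provenance = "") {
  data <- tibble::as_tibble(data)
  required <- c("country", "period", "sex", "le", "population")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("panel data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    country = trimws(as.character(data$country)),
    period = canonical_period(data$period),
    sex = normalize_sex(data$sex),
    le = as.double(data$le),
    population = as.double(data$population)
  )
  check_panel_invariants(out)
  key <- paste(out$country, out$period, out$sex, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (country, period, sex) key(s): ",
         paste(gsub("\r", " / ", utils::head(dups, 5L)), collapse = "; "),
         call. = FALSE)
  }
  structure(out, provenance = provenance,
            class = c("le_panel", class(out)))
}

#' @export
print.le_panel <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<le_panel> %d records, %d countries, %d periods\n",
              nrow(x), length(unique(x$country)), length(unique(x$period))))
  if (nzchar(prov %||% "")) cat("provenance:", prov, "\n")
  NextMethod()
}

normalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  s[s %in% c("f", "women", "female")] <- "female"
  s[s %in% c("m", "men", "male")] <- "male"
  s[s %in% c("b", "all", "total", "both")] <- "both"
  bad <- !s %in% c("female", "male", "both")
  if (any(bad)) {
    stop("unrecognized sex code(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected female, male or both)", call. = FALSE)
  }
  s
}

check_panel_invariants <- function(df) {
  if (any(!is.finite(df$le)) || any(df$le <= 0) || any(df$le >= 130)) {
    stop("life expectancy must be finite and in (0, 130) years", call. = FALSE)
  }
  if (any(!is.finite(df$population)) || any(df$population < 0)) {
    stop("population must be finite and non-negative", call. = FALSE)
  }
  invisible(df)
}

#' Default delimited-file dialect for panel files
#'
#' Panel files are delimited text with a header. The default dialect is
#' comma-separated with columns `country`, `period`, `sex`, `le_years`,
#' `population`; the mapping from those roles to header names is
#' configurable for files that use different spellings.
#'
#' @param delim Field delimiter.
#' @param country,period,sex,le,population Header names holding each field.
#' @return A named list describing the dialect, for [read_panel()].
#' @export
panel_dialect <- function(delim = ",", country = "country", period = "period",
                          sex = "sex", le = "le_years",
                          population = "population") {
  list(delim = delim, country = country, period = period, sex = sex,
       le = le, population = population)
}

#' Read a panel from delimited text
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column mapping and delimiter, from [panel_dialect()].
#' @param provenance Optional provenance note; defaults to the file path.
#' @return An [panel()] object.
#' @export
read_panel <- function(path, dialect = panel_dialect(), provenance = path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  roles <- c("country", "period", "sex", "le", "population")
  header <- vapply(roles, function(r) dialect[[r]], character(1))
  missing_cols <- header[!header %in% names(raw)]
  if (length(missing_cols)) {
    stop("panel file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, role) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s value %s at data row %d of %s",
                   role, dQuote(raw[[col]][bad[1]]), bad[1], path),
           call. = FALSE)
    }
    v
  }
  panel(tibble::tibble(
    country = raw[[dialect$country]],
    period = raw[[dialect$period]],
    sex = raw[[dialect$sex]],
    le = parse_num(dialect$le, "life-expectancy"),
    population = parse_num(dialect$population, "population")
  ), provenance = provenance)
}

#' Write a panel to delimited text
#'
#' Writes columns in the fixed order `country`, `period`, `sex`,
#' `le_years`, `population`, re-readable by [read_panel()] with the
#' default dialect.
#'
#' @param panel An [panel()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "le_panel"))
  out <- tibble::tibble(
    country = panel$country, period = panel$period, sex = panel$sex,
    le_years = panel$le, population = panel$population
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract one region/period/sex slice of a panel
#'
#' @param panel An [panel()] object.
#' @param members Character vector of country ids to keep (e.g. a region's
#'   membership).
#' @param period Period label (any accepted spelling), or `NULL` to keep all.
#' @param sex Sex code, or `NULL` to keep all.
#' @return A tibble of matching records.
#' @export
panel_slice <- function(panel, members = NULL, period = NULL, sex = NULL) {
  df <- tibble::as_tibble(panel)
  if (!is.null(members)) df <- df[df$country %in% members, ]
  if (!is.null(period)) df <- df[df$period == canonical_period(period), ]
  if (!is.null(sex)) df <- df[df$sex == normalize_sex(sex), ]
  df
}
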