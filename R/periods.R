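#' Parse and normalize period labels
#'
#' Periods are half-open calendar intervals `[start, end)` labelled
#' `"YYYY-YYYY"` (e.g. `"1965-1970"` for the five years 1965 to 1969).
#' Common demographic shorthand is accepted on input: en/em dashes and
#' two-digit end years (`"1965–70"`, `"2005-10"`), which are expanded
#' against the start year's century with rollover (`"1995-00"` is
#' 1995-2000).
#'
#' @param x Character vector of period labels.
#' @return For `parse_period()`, a tibble with columns `label` (canonical
#'   form), `start`, and `end` (integer calendar years). For
#'   `canonical_period()`, the canonical labels as a character vector.
#' @examples
#' parse_period(c("1965-1970", "2005–10"))
#' canonical_period("1965–70")
#' @export
parse_period <- function(x) {
  x_chr <- trimws(as.character(x))
  parts <- regmatches(x_chr, regexec("^([0-9]{4})\\s*[-–—/]\\s*([0-9]{2}|[0-9]{4})$", x_chr))
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("unparseable period label(s): ",
         paste(utils::head(x_chr[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  start <- as.integer(vapply(parts, `[`, character(1), 2L))
  end_raw <- vapply(parts, `[`, character(1), 3L)
  end <- ifelse(nchar(end_raw) == 4L,
                as.integer(end_raw),
                {
                  e <- (start %/% 100L) * 100L + as.integer(end_raw)
                  ifelse(e <= start, e + 100L, e)
                })
  end <- as.integer(end)
  if (any(start >= end)) {
    stop("period start must precede end: ",
         paste(x_chr[start >= end], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(label = sprintf("%04d-%04d", start, end), start = start, end = end)
}

#' @rdname parse_period
#' @export
canonical_period <- function(x) parse_period(x)$label

#' Order period labels chronologically
#'
#' @param x Character vector of period labels (any accepted spelling).
#' @return `x` sorted by period start year, in canonical form.
#' @export
sort_periods <- function(x) {
  p <- parse_period(x)
  p$label[order(p$start)]
}

#' Default five-year period grid
#'
#' The nine five-year periods 1965-1970 through 2005-2010 used as the
#' default panel grid.
#'
#' @return Character vector of nine canonical period labels.
#' @export
default_periods <- function() {
  starts <- seq(1965L, 2005L, by = 5L)
  sprintf("%04d-%04d", starts, starts + 5L)
}

# midpoint calendar year of a period, used for elapsed-time axes
period_midpoint <- function(x) {
  p <- parse_period(x)
  (p$start + p$end) / 2
}
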