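#' Define an aggregation region
#'
#' A region is a named set of country ids over which weighted life
#' expectancy and disparity metrics are computed. Ids are opaque strings
#' matched exactly after whitespace trimming; no name harmonization is
#' attempted.
#'
#' @param name Region name.
#' @param members Character vector of country ids; must be non-empty with
#'   no duplicates.
#' @param notes Free-text note.
#' @return A list of class `region_definition`.
#' @export
region_definition <- function(name, members, notes = "") {
  members <- trimws(as.character(members))
  if (!length(members)) {
    stop("region ", dQuote(name), " has an empty member list", call. = FALSE)
  }
  if (anyDuplicated(members)) {
    stop("region ", dQuote(name), " has duplicate member ids: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = as.character(name), members = members,
                 notes = as.character(notes)),
            class = "region_definition")
}

#' @export
print.region_definition <- function(x, ...) {
  cat(sprintf("<region_definition> %s (%d members)\n", x$name, length(x$members)))
  if (nzchar(x$notes)) cat("notes:", x$notes, "\n")
  invisible(x)
}

#' Load region definitions from a YAML or JSON config
#'
#' The config maps region names to member lists, either directly
#' (`Caribbean: [Cuba, Haiti, ...]`) or under a top-level `regions:` key;
#' a member entry may also be a mapping with `members:` and `notes:`
#' fields. A country appearing in several regions is allowed but flagged
#' with a warning, since overlapping memberships double-count populations
#' in any cross-region comparison.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list of [region_definition()] objects, in file order.
#' @examples
#' cfg <- system.file("extdata", "caribbean_region.yaml", package = "dispaq")
#' regions <- load_region_definitions(cfg)
#' length(regions[[1]]$members)
#' @export
load_region_definitions <- function(path) {
  if (!file.exists(path)) stop("region config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.list(raw) && !is.null(raw$regions)) raw <- raw$regions
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("region config must map region names to member lists", call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("duplicate region name(s) in config: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  defs <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    if (is.list(entry) && !is.null(entry$members)) {
      region_definition(nm, unlist(entry$members, use.names = FALSE),
                        notes = entry$notes %||% "")
    } else {
      region_definition(nm, unlist(entry, use.names = FALSE))
    }
  })
  all_members <- unlist(lapply(defs, `[[`, "members"))
  shared <- unique(all_members[duplicated(all_members)])
  if (length(shared)) {
    warning("country id(s) shared by multiple regions: ",
            paste(shared, collapse = ", "), call. = FALSE)
  }
  defs
}

#' Validate a panel against region definitions
#'
#' Report-only check: lists region members absent from the panel for each
#' period/sex combination present, and per-region coverage fractions.
#' Record-level invariants are re-checked as well (a tibble can be mutated
#' after construction) and reported rather than thrown.
#'
#' @param panel An [panel()] object.
#' @param regions A list of [region_definition()] objects (or a single one).
#' @return A list with `issues` (tibble: region, period, sex, country,
#'   issue) and `coverage` (tibble: region, period, sex, n_present,
#'   n_members, completeness).
#' @export
validate_panel <- function(panel, regions) {
  stopifnot(inherits(panel, "le_panel"))
  if (inherits(regions, "region_definition")) regions <- list(regions)
  df <- tibble::as_tibble(panel)
  slices <- unique(df[c("period", "sex")])
  issues <- list()
  bad_le <- !is.finite(df$le) | df$le <= 0 | df$le >= 130
  bad_pop <- !is.finite(df$population) | df$population < 0
  if (any(bad_le | bad_pop)) {
    bad <- df[bad_le | bad_pop, ]
    issues[[1L]] <- tibble::tibble(
      region = NA_character_, period = bad$period, sex = bad$sex,
      country = bad$country,
      issue = ifelse(bad_le[bad_le | bad_pop],
                     "invariant violation: le outside (0, 130)",
                     "invariant violation: negative population"))
  }
  coverage <- list()
  for (def in regions) {
    for (i in seq_len(nrow(slices))) {
      per <- slices$period[i]
      sx <- slices$sex[i]
      present <- panel_slice(panel, def$members, per, sx)$country
      absent <- setdiff(def$members, present)
      if (length(absent)) {
        issues[[length(issues) + 1L]] <- tibble::tibble(
          region = def$name, period = per, sex = sx, country = absent,
          issue = "missing coverage")
      }
      coverage[[length(coverage) + 1L]] <- tibble::tibble(
        region = def$name, period = per, sex = sx,
        n_present = length(present), n_members = length(def$members),
        completeness = length(present) / length(def$members))
    }
  }
  empty <- tibble::tibble(region = character(), period = character(),
                          sex = character(), country = character(),
                          issue = character())
  list(issues = if (length(issues)) dplyr::bind_rows(issues) else empty,
       coverage = dplyr::bind_rows(coverage))
}
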