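#' Read Darwin Core occurrence records
#'
#' TSV with headers `countryCode`, `year`, `occurrenceStatus`, `issue`
#' (semicolon-separated flags), `recordedBy`, `identifiedBy`.
#'
#' @param path TSV path.
#' @return tibble of occurrence records.
#' @export
read_occurrences <- function(path) {
  occ <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  occ$year <- suppressWarnings(as.integer(occ$year))
  occ
}

#' Count distinct collector and identifier strings per country
#'
#' Filters occurrences to status "PRESENT" (case-insensitive), drops
#' records carrying the COUNTRY_COORDINATE_MISMATCH issue flag, and
#' restricts to the inclusive year window; then counts, per country,
#' the surviving records and the distinct non-empty `recordedBy` and
#' `identifiedBy` strings. Agent strings are compared verbatim (outer
#' whitespace trimmed, no case folding): they are uncontrolled text
#' that may name individuals, organisations or expeditions, and
#' normalising them would conflate genuinely distinct strings. Results
#' are sorted ascending by record count.
#'
#' @param occurrences tibble from [read_occurrences()].
#' @param year_start,year_end inclusive year bounds.
#' @return tibble with `countryCode`, `nRecords`, `nDistinctRecordedBy`,
#'   `nDistinctIdentifiedBy`.
#' @export
count_distinct_agents <- function(occurrences, year_start = 2014,
                                  year_end = 2023) {
  flag <- "COUNTRY_COORDINATE_MISMATCH"
  has_flag <- vapply(strsplit(occurrences$issue %||% "", ";", fixed = TRUE),
                     function(f) flag %in% f, logical(1))
  keep <- toupper(occurrences$occurrenceStatus) == "PRESENT" &
    !has_flag &
    !is.na(occurrences$year) &
    occurrences$year >= year_start & occurrences$year <= year_end
  occ <- occurrences[keep, , drop = FALSE]
  occ$recordedBy <- trimws(occ$recordedBy)
  occ$identifiedBy <- trimws(occ$identifiedBy)
  out <- dplyr::summarise(
    dplyr::group_by(occ, .data$countryCode),
    nRecords = dplyr::n(),
    nDistinctRecordedBy = dplyr::n_distinct(.data$recordedBy[nzchar(.data$recordedBy)]),
    nDistinctIdentifiedBy = dplyr::n_distinct(.data$identifiedBy[nzchar(.data$identifiedBy)]),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$nRecords, .data$countryCode)
}

#' Counts as a percentage of national population
#'
#' @param counts named numeric vector, country code to count.
#' @param population named numeric vector, country code to population.
#' @return named numeric vector of rates (`100 * count / population`);
#'   countries without population data get `NA` with a warning.
#' @export
per_capita <- function(counts, population) {
  pop <- population[names(counts)]
  missing_pop <- is.na(pop)
  if (any(missing_pop)) {
    warning("no population for: ",
            paste(names(counts)[missing_pop], collapse = ", "),
            call. = FALSE)
  }
  stats::setNames(ifelse(missing_pop, NA_real_, 100 * counts / pop),
                  names(counts))
}
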