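# Extraction patterns. Genus: capital + >=2 lowercase letters; epithet:
# >=3 lowercase letters (suppresses sentence fragments with short
# function words like "we" or "is"), optional internal hyphen. Unicode
# letter classes so diacritics count as letters; lookarounds forbid
# letters adjacent to the match so fragments of longer words never
# qualify.
.binomial_re <- paste0(
  "(?<!\\p{L})",
  "(\\p{Lu}\\p{Ll}{2,})",          # genus token
  " ",
  "(\\p{Ll}{3,}(?:-\\p{Ll}{2,})?)", # epithet token
  "(?!\\p{L})"
)

.abbrev_re <- paste0(
  "(?<!\\p{L})",
  "(\\p{Lu})\\. ?",
  "(\\p{Ll}{3,}(?:-\\p{Ll}{2,})?)",
  "(?!\\p{L})"
)

#' Extract candidate species binomials from text
#'
#' Scans whitespace-normalised text for word pairs capitalised like
#' "Genus species": a capitalised word of three or more letters followed
#' by an all-lowercase word of two or more letters (internal hyphen
#' allowed in the epithet). Matches are maximal, resolved left to right,
#' non-overlapping. Candidates are *not* validated here; see
#' [annotate_article_species()].
#'
#' @param text a character scalar.
#' @return tibble with columns `start`, `end` (character offsets in the
#'   normalised text) and `candidate`.
#' @export
extract_candidate_binomials <- function(text) {
  txt <- normalize_ws(text %||% "")
  empty <- tibble::tibble(start = integer(), end = integer(),
                          candidate = character())
  if (!nzchar(txt)) return(empty)
  m <- gregexpr(.binomial_re, txt, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  len <- attr(m, "match.length")
  tibble::tibble(
    start = as.integer(m),
    end = as.integer(m) + len - 1L,
    candidate = substring(txt, m, m + len - 1L)
  )
}

empty_mentions <- function() {
  tibble::tibble(
    verbatim = character(), canonicalName = character(),
    taxonId = character(), expandedFromAbbreviation = logical(),
    genus = character(), family = character(), order = character(),
    class = character(), phylum = character(), kingdom = character()
  )
}

mention_row <- function(verbatim, record, expanded) {
  tibble::tibble(
    verbatim = verbatim,
    canonicalName = record$scientificName,
    taxonId = record$taxonID,
    expandedFromAbbreviation = expanded,
    genus = record$genus, family = record$family, order = record$order,
    class = record$class, phylum = record$phylum, kingdom = record$kingdom
  )
}

#' Expand abbreviated "G. species" mentions
#'
#' After the full binomials of an article have been validated, the rest
#' of the text is searched for abbreviated forms like "C. monilis". An
#' abbreviation is expanded only when its initial matches exactly one
#' confirmed genus (ambiguous initials are skipped and logged), and the
#' expansion is kept only if the resulting binomial exists in the
#' backbone.
#'
#' @param text character scalar.
#' @param confirmed_genera genus names validated from full binomials in
#'   the same article.
#' @param index a `backbone_index`.
#' @return tibble of species mentions (see [annotate_article_species()])
#'   with `expandedFromAbbreviation = TRUE`.
#' @export
expand_abbreviations <- function(text, confirmed_genera, index) {
  txt <- normalize_ws(text %||% "")
  confirmed_genera <- unique(confirmed_genera)
  if (!nzchar(txt) || length(confirmed_genera) == 0) return(empty_mentions())
  m <- gregexpr(.abbrev_re, txt, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty_mentions())
  len <- attr(m, "match.length")
  verbatims <- substring(txt, m, m + len - 1L)
  initials <- substr(confirmed_genera, 1, 1)

  out <- empty_mentions()
  for (v in verbatims) {
    letter <- substr(v, 1, 1)
    epithet <- sub("^\\p{Lu}\\. ?", "", v, perl = TRUE)
    genera <- confirmed_genera[initials == letter]
    if (length(genera) > 1) {
      tc_log("expand_abbreviations: ambiguous initial '%s.' (%s); skipped",
             letter, paste(genera, collapse = ", "))
      next
    }
    if (length(genera) == 0) next
    rec <- match_binomial(index, paste(genera, epithet))
    if (!is.null(rec)) out <- rbind(out, mention_row(v, rec, TRUE))
  }
  out
}

#' Annotate an article with validated species mentions
#'
#' Extracts candidate binomials from title and abstract (concatenated
#' with a separator that cannot create a spurious adjacency), keeps the
#' ones that match the backbone exactly, then expands abbreviated
#' mentions against the genera so confirmed. Duplicate mentions of the
#' same taxon are collapsed, keeping the first occurrence. Idempotent.
#'
#' @param article an article record.
#' @param index a `backbone_index`.
#' @return the article with `speciesMentions` set to a mention tibble
#'   (columns `verbatim`, `canonicalName`, `taxonId`,
#'   `expandedFromAbbreviation`, and lineage `genus` to `kingdom`).
#' @export
annotate_article_species <- function(article, index) {
  text <- paste(article$title %||% "", article$abstract %||% "", sep = " • ")
  cands <- extract_candidate_binomials(text)
  mentions <- empty_mentions()
  for (cand in cands$candidate) {
    rec <- match_binomial(index, cand)
    if (!is.null(rec)) mentions <- rbind(mentions, mention_row(cand, rec, FALSE))
  }
  expansions <- expand_abbreviations(text, unique(mentions$genus), index)
  mentions <- rbind(mentions, expansions)
  mentions <- mentions[!duplicated(mentions$taxonId), , drop = FALSE]
  article$speciesMentions <- mentions
  article
}

#' Annotate every article in a corpus
#'
#' @param corpus list of article records (the filtered corpus).
#' @param index a `backbone_index`.
#' @return list of annotated article records.
#' @export
annotate_corpus <- function(corpus, index) {
  lapply(corpus, annotate_article_species, index = index)
}

# Mentions as a tibble regardless of whether the article was annotated
# in-memory (tibble) or round-tripped through JSONL (list of lists).
article_mentions <- function(article) {
  sm <- article$speciesMentions
  if (is.null(sm) || length(sm) == 0) return(empty_mentions())
  if (is.data.frame(sm)) return(tibble::as_tibble(sm))
  dplyr::bind_rows(lapply(sm, tibble::as_tibble))
}
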