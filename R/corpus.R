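#' Read a journal table
#'
#' Tab-separated journal records with columns `displayName`,
#' `wikidataId`, `openalexId`, `issnL`, `issn`, `ipniPubId`,
#' `zoobankPubId`, `dissolved`, `dissolvedYear`, `discoveryMethods`
#' (semicolon-separated). Empty strings denote missing identifiers.
#'
#' @param path TSV path.
#' @return tibble of journal records.
#' @export
read_journals <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE, na = character())
}

journal_id_cols <- c("wikidataId", "openalexId", "issnL", "issn",
                     "ipniPubId", "zoobankPubId")

#' Deduplicate journal records
#'
#' Journals discovered through different methods are merged when they
#' share a Wikidata identifier or share an OpenAlex identifier
#' (transitive closure over both links, via union-find). Merged records
#' take the union of identifier fields and discovery methods;
#' conflicting non-empty scalar fields keep the first-seen value, and
#' the conflict is logged.
#'
#' @param journals tibble as from [read_journals()].
#' @return deduplicated tibble. Idempotent.
#' @export
dedupe_journals <- function(journals) {
  n <- nrow(journals)
  if (n <= 1) return(journals)
  parent <- seq_len(n)
  for (col in c("wikidataId", "openalexId")) {
    ids <- journals[[col]]
    present <- which(nzchar(ids))
    groups <- split(present, ids[present])
    for (g in groups) {
      if (length(g) > 1) {
        for (k in seq_along(g)[-1]) parent <- uf_union(parent, g[1], g[k])
      }
    }
  }
  comp <- uf_components(parent)
  merged <- lapply(split(seq_len(n), comp), function(rows) {
    rec <- journals[rows[1], , drop = FALSE]
    if (length(rows) > 1) {
      for (col in names(journals)) {
        vals <- unique(journals[[col]][rows])
        vals <- vals[nzchar(vals)]
        if (col == "discoveryMethods") {
          methods <- unique(unlist(strsplit(vals, ";", fixed = TRUE)))
          rec[[col]] <- paste(sort(methods), collapse = ";")
        } else if (length(vals) > 1) {
          tc_log("dedupe_journals: conflicting %s (%s); keeping '%s'",
                 col, paste(vals, collapse = " / "), vals[1])
          rec[[col]] <- vals[1]
        } else if (length(vals) == 1) {
          rec[[col]] <- vals
        }
      }
    }
    rec
  })
  out <- dplyr::bind_rows(merged)
  tc_log("dedupe_journals: %d -> %d records", n, nrow(out))
  out
}

#' Select journals usable for article retrieval
#'
#' Articles are retrieved per journal through its OpenAlex identifier,
#' so journals lacking one cannot be used and are dropped. Dissolved
#' journals are retained: their publication window naturally yields no
#' in-window articles.
#'
#' @param journals deduplicated journal tibble.
#' @return tibble of usable journals.
#' @export
select_usable_journals <- function(journals) {
  keep <- nzchar(journals$openalexId)
  tc_log("select_usable_journals: %d retained, %d lacked an OpenAlex ID",
         sum(keep), sum(!keep))
  journals[keep, , drop = FALSE]
}

#' Decide whether an article is taxonomic
#'
#' True iff any general keyword (any configured language) occurs in the
#' title or abstract, or any abstract-only keyword (e.g. "nov.") occurs
#' in the abstract, or the article's concept tags intersect the
#' taxonomic concept identifiers. Matching is case-insensitive
#' contiguous-substring matching on whitespace-normalised text, so
#' "nov." matches inside "sp. nov.".
#'
#' @param article an article record (named list; see [read_articles()]).
#' @param config a `keyword_config`.
#' @return list with `decision` (logical) and `evidence` (character
#'   vector of matched phrases and concept ids).
#' @export
is_taxonomic_article <- function(article, config) {
  title <- normalize_ws(article$title %||% "")
  abstract <- normalize_ws(article$abstract %||% "")
  both <- paste(title, abstract, sep = " • ")
  general <- unique(unlist(config$keywords_by_language, use.names = FALSE))
  hit_general <- general[stringr::str_detect(
    both, stringr::fixed(general, ignore_case = TRUE))]
  hit_abs <- config$abstract_only_keywords[stringr::str_detect(
    abstract, stringr::fixed(config$abstract_only_keywords, ignore_case = TRUE))]
  hit_concepts <- intersect(as_chr(article$conceptIds),
                            config$taxonomic_concept_ids)
  evidence <- c(hit_general, hit_abs, hit_concepts)
  list(decision = length(evidence) > 0, evidence = evidence)
}

#' Filter articles down to the taxonomic corpus
#'
#' Applies, in order (the result is order-independent, each test is a
#' pure predicate): journal usability, the inclusive publication-date
#' window, the requirement of at least one authorship with a European
#' institution country code, membership of the Life Sciences domain,
#' and the keyword/concept test of [is_taxonomic_article()]. Articles
#' with unparseable dates are skipped with a warning. Per-filter removal
#' counts are logged and attached as the `"filter_counts"` attribute.
#'
#' @param articles list of article records.
#' @param usable_journals tibble from [select_usable_journals()].
#' @param config a `keyword_config`.
#' @return list of retained article records (the corpus), with a
#'   `filter_counts` attribute (named integer vector).
#' @export
filter_articles <- function(articles, usable_journals, config) {
  usable_ids <- usable_journals$openalexId
  start <- as.Date(config$window_start)
  end <- as.Date(config$window_end)

  dates <- as.Date(vapply(articles, function(a) a$publicationDate %||% "",
                          character(1)),
                   format = "%Y-%m-%d")
  bad_date <- is.na(dates)
  if (any(bad_date)) {
    warning(sum(bad_date), " article(s) with unparseable publicationDate skipped",
            call. = FALSE)
  }

  pass_journal <- vapply(articles, function(a)
    (a$journalId %||% "") %in% usable_ids, logical(1))
  pass_date <- !bad_date & dates >= start & dates <= end
  pass_euro <- vapply(articles, function(a) {
    codes <- unlist(lapply(a$authorships, function(au) as_chr(au$countryCodes)))
    any(codes %in% config$european_country_codes)
  }, logical(1))
  pass_domain <- vapply(articles, function(a)
    identical(a$domainId %||% "", config$life_sciences_domain_id), logical(1))
  pass_keyword <- vapply(articles, function(a)
    is_taxonomic_article(a, config)$decision, logical(1))

  keep <- pass_journal & pass_date & pass_euro & pass_domain & pass_keyword
  counts <- c(
    input = length(articles),
    removed_unparseable_date = sum(bad_date),
    removed_journal = sum(!pass_journal & !bad_date),
    removed_date = sum(pass_journal & !bad_date & !pass_date),
    removed_affiliation = sum(pass_journal & pass_date & !pass_euro),
    removed_domain = sum(pass_journal & pass_date & pass_euro & !pass_domain),
    removed_keyword = sum(pass_journal & pass_date & pass_euro & pass_domain &
                            !pass_keyword),
    corpus = sum(keep)
  )
  tc_log("filter_articles: %d -> %d (%s)", counts[["input"]], counts[["corpus"]],
         paste(names(counts)[2:7], counts[2:7], sep = "=", collapse = ", "))
  structure(articles[keep], filter_counts = counts)
}

#' Read and write article records as JSON lines
#'
#' @param path JSONL path.
#' @param articles list of article records.
#' @return `read_articles()` a list of article records;
#'   `write_articles()` the path, invisibly.
#' @export
read_articles <- function(path) read_jsonl(path)

#' @rdname read_articles
#' @export
write_articles <- function(articles, path) write_jsonl(articles, path)
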