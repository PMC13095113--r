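#' Build name keys for author disambiguation
#'
#' Two canonicalisations of a display name: the *stripped* name (spaces,
#' periods and hyphens removed) and the *truncated* name (first initial
#' plus last name, same characters removed). Comma-inverted names
#' ("Last, First") are re-ordered first; the last name is the final
#' whitespace token. Single-token names are flagged degenerate (the
#' initial then duplicates the only token). Downstream comparisons are
#' case-insensitive; diacritics are preserved.
#'
#' @param display_name non-empty author display name.
#' @return list with `stripped`, `truncated`, `degenerate`.
#' @examples
#' make_keys("Nils J. Broek")         # NilsJBroek / NBroek
#' make_keys("Vidal-Montes, Rosa")    # RosaVidalMontes / RVidalMontes
#' @export
make_keys <- function(display_name) {
  name <- normalize_ws(display_name %||% "")
  if (!nzchar(name)) stop("empty author display name", call. = FALSE)
  if (grepl(",", name, fixed = TRUE)) {
    parts <- strsplit(name, ",", fixed = TRUE)[[1]]
    name <- normalize_ws(paste(c(parts[-1], parts[1]), collapse = " "))
  }
  strip <- function(x) gsub("[ .-]", "", x)
  tokens <- strsplit(name, " ", fixed = TRUE)[[1]]
  list(
    stripped = strip(name),
    truncated = paste0(substr(tokens[1], 1, 1), strip(tokens[length(tokens)])),
    degenerate = length(tokens) == 1
  )
}

#' Extract European-affiliated authors from an annotated corpus
#'
#' One record per distinct author identifier having at least one
#' European institution country code. The orders and families an author
#' has published on are the union of the mention lineages of their
#' articles; these drive the second merge rule and the per-order author
#' counts.
#'
#' @param corpus list of annotated article records.
#' @param european_country_codes ISO alpha-2 codes.
#' @return tibble with columns `authorIds` (list), `displayName`,
#'   `strippedName`, `truncatedName`, `degenerateName`, `institutions`
#'   (list), `institutionNames` (list), `countryCodes` (list),
#'   `ordersPublished` (list), `familiesPublished` (list), `articleIds`
#'   (list).
#' @export
extract_authors <- function(corpus, european_country_codes = european_countries()) {
  rows <- list()
  for (article in corpus) {
    mentions <- article_mentions(article)
    orders <- unique(mentions$order[nzchar(mentions$order)])
    families <- unique(mentions$family[nzchar(mentions$family)])
    for (au in article$authorships) {
      codes <- as_chr(au$countryCodes)
      if (!any(codes %in% european_country_codes)) next
      rows[[length(rows) + 1]] <- list(
        authorId = au$authorId,
        displayName = au$displayName,
        institutions = as_chr(au$institutionIds),
        institutionNames = as_chr(au$institutionNames),
        countryCodes = codes,
        orders = orders,
        families = families,
        articleId = article$articleId
      )
    }
  }
  if (length(rows) == 0) return(empty_authors())

  by_id <- split(rows, vapply(rows, `[[`, character(1), "authorId"))
  recs <- lapply(by_id, function(g) {
    keys <- make_keys(g[[1]]$displayName)
    tibble::tibble(
      authorIds = list(g[[1]]$authorId),
      displayName = g[[1]]$displayName,
      strippedName = keys$stripped,
      truncatedName = keys$truncated,
      degenerateName = keys$degenerate,
      institutions = list(unique(unlist(lapply(g, `[[`, "institutions")))),
      institutionNames = list(unique(unlist(lapply(g, `[[`, "institutionNames")))),
      countryCodes = list(unique(unlist(lapply(g, `[[`, "countryCodes")))),
      ordersPublished = list(unique(unlist(lapply(g, `[[`, "orders")))),
      familiesPublished = list(unique(unlist(lapply(g, `[[`, "families")))),
      articleIds = list(unique(vapply(g, `[[`, character(1), "articleId")))
    )
  })
  dplyr::bind_rows(recs)
}

empty_authors <- function() {
  tibble::tibble(
    authorIds = list(), displayName = character(),
    strippedName = character(), truncatedName = character(),
    degenerateName = logical(),
    institutions = list(), institutionNames = list(),
    countryCodes = list(), ordersPublished = list(),
    familiesPublished = list(), articleIds = list()
  )
}

set0 <- function(x) if (is.null(x)) character(0) else x

shared_institution <- function(a, b, authors) {
  ia <- set0(authors$institutions[[a]]); ib <- set0(authors$institutions[[b]])
  if (length(ia) > 0 || length(ib) > 0) return(length(intersect(ia, ib)) > 0)
  # fall back to name-string equality only when both records lack ids
  na <- set0(authors$institutionNames[[a]]); nb <- set0(authors$institutionNames[[b]])
  length(intersect(na, nb)) > 0
}

shared_taxon <- function(a, b, authors) {
  oa <- set0(authors$ordersPublished[[a]]); ob <- set0(authors$ordersPublished[[b]])
  if (length(oa) > 0 && length(ob) > 0) return(length(intersect(oa, ob)) > 0)
  # family-rank fallback when either side has no order-rank taxa
  fa <- set0(authors$familiesPublished[[a]]); fb <- set0(authors$familiesPublished[[b]])
  length(intersect(fa, fb)) > 0
}

author_match_rule <- function(a, b, authors) {
  if (!shared_institution(a, b, authors)) return(NA_character_)
  if (tolower(authors$strippedName[a]) == tolower(authors$strippedName[b])) {
    return("stripped_institution")
  }
  if (tolower(authors$truncatedName[a]) == tolower(authors$truncatedName[b]) &&
      shared_taxon(a, b, authors)) {
    return("truncated_institution_taxon")
  }
  NA_character_
}

#' Merge duplicate author records
#'
#' Two author records are linked when (rule 1) they have the exact same
#' stripped name and a shared institution, or (rule 2) the same
#' truncated name, a shared institution, and intersecting published
#' orders — falling back to intersecting families when either record
#' has no order-rank taxa. Links are closed transitively (union-find)
#' and each connected component becomes one unified record whose set
#' fields are unions. Never increases the record count; idempotent.
#'
#' Candidate pairs are restricted to records sharing a truncated name
#' key (case-insensitive), which both rules require, so the pairwise
#' stage is quadratic only within key buckets.
#'
#' @param authors tibble from [extract_authors()].
#' @return list with `authors` (merged tibble) and `report`: a
#'   `merge_report` list with `nBefore`, `nAfter` and `mergedPairs`
#'   (tibble of `idA`, `idB`, `rule`, one row per linked pair).
#' @export
merge_duplicates <- function(authors) {
  n <- nrow(authors)
  report <- list(nBefore = n, nAfter = n,
                 mergedPairs = tibble::tibble(idA = character(),
                                              idB = character(),
                                              rule = character()))
  if (n <= 1) return(list(authors = authors, report = report))

  parent <- seq_len(n)
  pairs <- list()
  buckets <- split(seq_len(n), tolower(authors$truncatedName))
  for (bucket in buckets) {
    if (length(bucket) < 2) next
    for (pair in utils::combn(bucket, 2, simplify = FALSE)) {
      rule <- author_match_rule(pair[1], pair[2], authors)
      if (!is.na(rule)) {
        parent <- uf_union(parent, pair[1], pair[2])
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          idA = authors$authorIds[[pair[1]]][1],
          idB = authors$authorIds[[pair[2]]][1],
          rule = rule
        )
      }
    }
  }
  comp <- uf_components(parent)
  merged <- lapply(split(seq_len(n), comp), function(rows) {
    rec <- authors[rows[1], , drop = FALSE]
    if (length(rows) > 1) {
      for (col in c("authorIds", "institutions", "institutionNames",
                    "countryCodes", "ordersPublished", "familiesPublished",
                    "articleIds")) {
        rec[[col]] <- list(unique(unlist(authors[[col]][rows])))
      }
    }
    rec
  })
  out <- dplyr::bind_rows(merged)
  report$nAfter <- nrow(out)
  report$mergedPairs <- dplyr::bind_rows(report$mergedPairs, pairs)
  tc_log("merge_duplicates: %d -> %d records (%d linked pairs)",
         n, nrow(out), nrow(report$mergedPairs))
  list(authors = out, report = report)
}

cluster_pairs <- function(clusters) {
  out <- character(0)
  for (ids in clusters) {
    ids <- sort(unique(ids))
    if (length(ids) > 1) {
      pr <- utils::combn(ids, 2)
      out <- c(out, paste(pr[1, ], pr[2, ], sep = "\r"))
    }
  }
  unique(out)
}

#' Pairwise precision and recall of a merge against ground truth
#'
#' Both the merged result and the truth are read as partitions of the
#' same author-identifier universe; precision and recall are computed
#' over the implied sets of co-clustered pairs. With no predicted pairs,
#' precision is reported as 1 by convention (with a warning).
#'
#' @param merged_authors merged tibble from [merge_duplicates()].
#' @param truth tibble with columns `authorId`, `personId`.
#' @return list with `precision` and `recall`.
#' @export
merge_quality <- function(merged_authors, truth) {
  pred_ids <- sort(unique(unlist(merged_authors$authorIds)))
  truth_ids <- sort(unique(truth$authorId))
  if (!identical(pred_ids, truth_ids)) {
    stop("merged authors and ground truth cover different author-id universes",
         call. = FALSE)
  }
  pred <- cluster_pairs(merged_authors$authorIds)
  tru <- cluster_pairs(split(truth$authorId, truth$personId))
  precision <- if (length(pred) == 0) {
    warning("no merged pairs; precision reported as 1 by convention",
            call. = FALSE)
    1
  } else {
    length(intersect(pred, tru)) / length(pred)
  }
  recall <- if (length(tru) == 0) 1 else length(intersect(pred, tru)) / length(tru)
  list(precision = precision, recall = recall)
}

#' Upper bound on residual duplicate authors
#'
#' Validation arithmetic for the disambiguation step: the rate of
#' truly-duplicate pairs the merge missed in a manually checked sample,
#' multiplied by the share of all authors that share a truncated name
#' (only those can harbour missed duplicates), gives an upper bound on
#' the percentage of authors counted more than once.
#'
#' @param missed_pair_rate fraction of sampled pairs that were missed.
#' @param share_same_truncated fraction of authors sharing a truncated
#'   name with another author.
#' @return the bound, as a percentage.
#' @examples
#' inflation_bound(9 / 200, 0.10) # 0.45
#' @export
inflation_bound <- function(missed_pair_rate, share_same_truncated) {
  stopifnot(is.numeric(missed_pair_rate), is.numeric(share_same_truncated))
  if (missed_pair_rate < 0 || missed_pair_rate > 1 ||
      share_same_truncated < 0 || share_same_truncated > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  missed_pair_rate * share_same_truncated * 100
}
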