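#' The nine policy instruments used as demand predictors
#' @return character vector of policy identifiers.
#' @export
policy_ids <- function() {
  c("taxonomicResearchNeeded", "cropWildRelatives", "iasListConcern",
    "horizonInvasives", "habitatsDir", "marineDir", "redlistFull",
    "birdDir", "pollinators")
}

#' Load policy species lists
#'
#' Each list is a TSV with a `scientificName` column and optional
#' `category` (e.g. Red List threat status) and `group` columns.
#' Duplicate names within a list are collapsed with a warning.
#'
#' @param paths named character vector or list, policy id to TSV path.
#'   Names must be drawn from [policy_ids()].
#' @return named list of `policy_list` objects (`policyId`, `species`
#'   tibble).
#' @export
load_policy_lists <- function(paths) {
  unknown <- setdiff(names(paths), policy_ids())
  if (length(unknown) > 0) {
    stop("unknown policy id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(names(paths), function(pid) {
    tbl <- readr::read_tsv(paths[[pid]],
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, na = character())
    if (!"scientificName" %in% names(tbl)) {
      stop("policy list '", pid, "' lacks a scientificName column",
           call. = FALSE)
    }
    tbl$scientificName <- normalize_ws(tbl$scientificName)
    dup <- duplicated(tbl$scientificName)
    if (any(dup)) {
      warning("policy list '", pid, "': ", sum(dup),
              " duplicated name(s) collapsed", call. = FALSE)
      tbl <- tbl[!dup, , drop = FALSE]
    }
    structure(list(policyId = pid, species = tbl), class = "policy_list")
  })
  stats::setNames(out, names(paths))
}

resolve_to_order <- function(name, index, remap_synonyms) {
  rec <- match_binomial(index, name)
  if (is.null(rec)) return(NA_character_)
  if (remap_synonyms && rec$taxonomicStatus == "synonym" &&
      nzchar(rec$acceptedTaxonID)) {
    acc <- index$taxa[index$taxa$taxonID == rec$acceptedTaxonID, , drop = FALSE]
    if (nrow(acc) == 1) rec <- acc
  }
  if (!nzchar(rec$order)) return(NA_character_)
  rec$order
}

#' Build the order-by-policy demand matrix
#'
#' Resolves every policy species name against the backbone and counts,
#' per taxonomic order, the species each policy names; adds the
#' accepted-species richness of each order and (optionally) the number
#' of disambiguated authors publishing on it. Names that fail to
#' resolve — absent from the backbone, or resolving to a record without
#' an order — are kept in a per-policy unresolved ledger rather than
#' silently dropped, so resolved + unresolved = list size holds for
#' every policy.
#'
#' @param lists named list from [load_policy_lists()].
#' @param index a `backbone_index`.
#' @param authors_by_order optional named integer vector, order to
#'   author count (see [authors_by_order()]).
#' @param remap_synonyms when TRUE (default), a synonym hit with an
#'   `acceptedTaxonID` is counted in the accepted record's order.
#' @return tibble with one row per order (union of backbone orders and
#'   orders hit by policies): `order`, `speciesRichness`, one count
#'   column per policy in [policy_ids()], `authorCount`. The unresolved
#'   ledger is attached as attribute `"unresolved"` (named list of
#'   character vectors).
#' @export
build_policy_matrix <- function(lists, index, authors_by_order = NULL,
                                remap_synonyms = TRUE) {
  orders <- names(index$richness_by_order)
  unresolved <- list()
  policy_orders <- list()
  for (pid in names(lists)) {
    nms <- lists[[pid]]$species$scientificName
    res <- vapply(nms, resolve_to_order, character(1),
                  index = index, remap_synonyms = remap_synonyms,
                  USE.NAMES = FALSE)
    unresolved[[pid]] <- nms[is.na(res)]
    policy_orders[[pid]] <- res[!is.na(res)]
    orders <- union(orders, policy_orders[[pid]])
  }
  orders <- sort(orders)
  mat <- tibble::tibble(
    order = orders,
    speciesRichness = vapply(orders, function(o) order_richness(index, o),
                             integer(1), USE.NAMES = FALSE)
  )
  for (pid in policy_ids()) {
    hits <- policy_orders[[pid]]
    mat[[pid]] <- if (is.null(hits)) {
      0L
    } else {
      counts <- table(hits)
      as.integer(ifelse(is.na(counts[orders]), 0L, counts[orders]))
    }
  }
  mat$authorCount <- if (is.null(authors_by_order)) {
    0L
  } else {
    as.integer(ifelse(is.na(authors_by_order[orders]), 0L,
                      authors_by_order[orders]))
  }
  attr(mat, "unresolved") <- unresolved
  mat
}

#' Count disambiguated authors per taxonomic order
#'
#' @param authors merged author tibble from [merge_duplicates()].
#' @return named integer vector, order to number of authors whose
#'   published orders include it.
#' @export
authors_by_order <- function(authors) {
  orders <- unlist(authors$ordersPublished)
  if (is.null(orders) || length(orders) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  counts <- table(orders[nzchar(orders)])
  stats::setNames(as.integer(counts), names(counts))
}

# round half up at `digits` decimal places (printed-percentage style;
# base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage breakdown of counts over a total
#'
#' Used for Red List style summaries: each category count as a
#' percentage of the total, rounded half-up to one decimal place.
#'
#' @param counts named numeric vector, category to count.
#' @param total positive total the percentages refer to.
#' @return named numeric vector of percentages (one decimal).
#' @examples
#' redlist_summary(c(taxonomicResearchNeeded = 1866), 13918) # 13.4
#' @export
redlist_summary <- function(counts, total) {
  if (!is.numeric(total) || length(total) != 1 || total <= 0) {
    stop("total must be a single positive number", call. = FALSE)
  }
  if (any(counts > total) || any(counts < 0)) {
    stop("counts must lie in [0, total]", call. = FALSE)
  }
  round_half_up(100 * counts / total, 1)
}

#' Group totals for a policy list
#'
#' Partitions a policy list's species into groups (e.g. plants vs
#' animals) and counts each, with species missing from the partition
#' grouped as "other". The grand total always equals the list size.
#'
#' @param policy_list a `policy_list`.
#' @param partition named character vector, species name to group.
#' @return list with `groups` (named integer vector) and `total`.
#' @export
policy_totals <- function(policy_list, partition) {
  nms <- policy_list$species$scientificName
  if (length(nms) == 0) return(list(groups = integer(0), total = 0L))
  grp <- partition[nms]
  grp[is.na(grp)] <- "other"
  counts <- table(grp)
  list(groups = stats::setNames(as.integer(counts), names(counts)),
       total = length(nms))
}
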