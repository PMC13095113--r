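#' Load a taxonomic backbone table
#'
#' Reads a Darwin Core style taxon table (tab-separated, UTF-8, header
#' row) and builds an index supporting exact binomial matching, lineage
#' lookup and per-order accepted-species richness. The expected columns
#' are `taxonID`, `scientificName`, `taxonRank`, `taxonomicStatus`,
#' `genus`, `family`, `order`, `class`, `phylum`, `kingdom`; an optional
#' `acceptedTaxonID` column is carried through so synonym hits can be
#' remapped to their accepted taxa downstream.
#'
#' Scientific names are whitespace-normalised before indexing; no case
#' folding is applied, matching is exact on the stored canonical form.
#' Rows missing a scientific name or rank are skipped and counted.
#' Species-rank rows whose name is not a strict "Genus epithet" binomial
#' (hybrid markers, infraspecific epithets, bad capitalisation) are
#' skipped with a warning: they sit outside the extraction pattern's
#' universe. Synonyms are indexed and matchable, but only accepted
#' species contribute to richness.
#'
#' @param path path to the TSV file.
#' @return A `backbone_index` object: list with elements `taxa` (tibble
#'   of retained rows), `by_binomial` (hashed environment mapping
#'   canonical binomial to row number), `by_genus` (named list mapping
#'   genus to its epithets) and `richness_by_order` (named integer
#'   vector over orders of accepted species counts).
#' @seealso [match_binomial()], [order_richness()]
#' @export
load_backbone <- function(path) {
  if (!file.exists(path)) {
    stop("backbone file not found: ", path, call. = FALSE)
  }
  required <- c("taxonID", "scientificName", "taxonRank", "taxonomicStatus",
                "genus", "family", "order", "class", "phylum", "kingdom")
  taxa <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, na = character())
  missing_cols <- setdiff(required, names(taxa))
  if (length(missing_cols) > 0) {
    stop("backbone is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"acceptedTaxonID" %in% names(taxa)) taxa$acceptedTaxonID <- ""

  taxa$scientificName <- normalize_ws(taxa$scientificName)
  malformed <- !nzchar(taxa$scientificName) | !nzchar(taxa$taxonRank)
  if (any(malformed)) {
    tc_log("load_backbone: skipped %d malformed row(s) (missing name or rank)",
           sum(malformed))
    taxa <- taxa[!malformed, , drop = FALSE]
  }

  is_species <- taxa$taxonRank == "species"
  # strict binomial: capitalised genus token + single lowercase epithet
  ok_binomial <- grepl(
    "^(?:\\p{Lu}\\p{Ll}+) (?:\\p{Ll}+(?:-\\p{Ll}+)?)$",
    taxa$scientificName, perl = TRUE
  )
  bad_species <- is_species & !ok_binomial
  if (any(bad_species)) {
    warning(sum(bad_species), " species-rank row(s) with non-binomial names ",
            "(hybrids/infraspecifics) skipped", call. = FALSE)
    taxa <- taxa[!bad_species, , drop = FALSE]
    is_species <- taxa$taxonRank == "species"
  }

  # genus field must equal the first name token; fill when absent
  first_token <- sub(" .*$", "", taxa$scientificName)
  taxa$genus[is_species & !nzchar(taxa$genus)] <-
    first_token[is_species & !nzchar(taxa$genus)]

  by_binomial <- new.env(hash = TRUE, parent = emptyenv())
  sp_rows <- which(is_species)
  for (i in sp_rows) {
    nm <- taxa$scientificName[i]
    if (is.null(by_binomial[[nm]])) assign(nm, i, envir = by_binomial)
  }

  sp <- taxa[sp_rows, , drop = FALSE]
  by_genus <- lapply(split(sub("^[^ ]+ ", "", sp$scientificName), sp$genus),
                     unique)

  accepted <- sp[sp$taxonomicStatus == "accepted" & nzchar(sp$order), ,
                 drop = FALSE]
  richness <- table(accepted$order)
  richness_by_order <- stats::setNames(as.integer(richness), names(richness))

  structure(
    list(taxa = tibble::as_tibble(taxa), by_binomial = by_binomial,
         by_genus = by_genus, richness_by_order = richness_by_order),
    class = "backbone_index"
  )
}

#' @export
print.backbone_index <- function(x, ...) {
  cat("<backbone_index>", nrow(x$taxa), "taxa,",
      length(ls(x$by_binomial)), "species binomials,",
      length(x$richness_by_order), "orders with accepted species\n")
  invisible(x)
}

#' Exact binomial lookup in a backbone index
#'
#' Returns the backbone record whose canonical scientific name equals the
#' candidate exactly (after whitespace normalisation); never fuzzy.
#'
#' @param index a `backbone_index` from [load_backbone()].
#' @param candidate a two-token "Genus epithet" string.
#' @return a one-row tibble (the matched `TaxonRecord`), or `NULL` when
#'   the candidate is absent. Absence is a value, not an error.
#' @export
match_binomial <- function(index, candidate) {
  stopifnot(inherits(index, "backbone_index"))
  nm <- normalize_ws(candidate)
  i <- index$by_binomial[[nm]]
  if (is.null(i)) return(NULL)
  index$taxa[i, , drop = FALSE]
}

#' Accepted species richness of an order
#'
#' Count of accepted species-rank backbone records in the given order;
#' 0 for orders absent from the backbone.
#'
#' @param index a `backbone_index`.
#' @param order order name.
#' @return non-negative integer.
#' @export
order_richness <- function(index, order) {
  stopifnot(inherits(index, "backbone_index"))
  r <- index$richness_by_order[order]
  if (is.na(r)) 0L else unname(r)
}
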