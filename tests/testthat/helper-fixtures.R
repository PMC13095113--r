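options(taxcap.verbose = FALSE)

backbone_cols <- c("taxonID", "scientificName", "taxonRank",
                   "taxonomicStatus", "acceptedTaxonID", "genus", "family",
                   "order", "class", "phylum", "kingdom")

# write a backbone TSV from compact row specs:
# list(id, name, rank, status, accepted = "", family = "", order = "")
write_backbone <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                                              .local_envir = parent.frame())) {
  tbl <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      taxonID = r$id, scientificName = r$name, taxonRank = r$rank,
      taxonomicStatus = r$status, acceptedTaxonID = r$accepted %||% "",
      genus = sub(" .*$", "", r$name), family = r$family %||% "Fam1",
      order = r$order %||% "Ordales", class = "Cls", phylum = "Phy",
      kingdom = "King"
    )
  }))
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small five-species backbone used across tests
tiny_backbone <- function() {
  path <- write_backbone(list(
    list(id = "T1", name = "Carabus monilis", rank = "species",
         status = "accepted", order = "Carabales"),
    list(id = "T2", name = "Carabus solis", rank = "species",
         status = "accepted", order = "Carabales"),
    list(id = "T3", name = "Abies alba", rank = "species",
         status = "accepted", order = "Pinales", family = "Pinaceae"),
    list(id = "T4", name = "Abies vetula", rank = "species",
         status = "synonym", accepted = "T3", order = "Pinales",
         family = "Pinaceae"),
    list(id = "T5", name = "Carabus", rank = "genus", status = "accepted",
         order = "Carabales")
  ), path = tempfile(fileext = ".tsv"))
  on.exit(NULL)
  load_backbone(path)
}

# author record constructor for merge tests
author_rec <- function(id, name, inst, orders = character(0),
                       families = character(0)) {
  keys <- make_keys(name)
  tibble::tibble(
    authorIds = list(id), displayName = name,
    strippedName = keys$stripped, truncatedName = keys$truncated,
    degenerateName = keys$degenerate,
    institutions = list(inst), institutionNames = list(character(0)),
    countryCodes = list("BE"), ordersPublished = list(orders),
    familiesPublished = list(families), articleIds = list(character(0))
  )
}

# minimal article record
article_rec <- function(id = "W1", title = "", abstract = "",
                        journal = "S1", date = "2020-06-01",
                        concepts = list(), domain = "D1",
                        countries = "BE", author_id = "A1",
                        author_name = "Ann Author", inst = "I1") {
  list(
    articleId = id, journalId = journal, title = title, abstract = abstract,
    language = "en", publicationDate = date, conceptIds = concepts,
    domainId = domain,
    authorships = list(list(authorId = author_id, displayName = author_name,
                            institutionIds = list(inst),
                            institutionNames = list("Inst"),
                            countryCodes = as.list(countries)))
  )
}

journal_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      displayName = r$name %||% "J", wikidataId = r$wd %||% "",
      openalexId = r$oa %||% "", issnL = r$issnL %||% "",
      issn = "", ipniPubId = r$ipni %||% "", zoobankPubId = "",
      dissolved = "false", dissolvedYear = "",
      discoveryMethods = r$method %||% "wikidata_subject"
    )
  }))
}
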