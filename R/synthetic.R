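#' Configuration for the synthetic bibliographic-data generator
#'
#' The generator emulates every pipeline input with known ground truth:
#' a taxonomic backbone, journal and article records with planted
#' species names and multilingual keywords, authorship structure with
#' planted duplicate identities and name collisions, policy species
#' lists, an order-level regression dataset with stated coefficients,
#' and Darwin Core occurrence records. All randomness flows from the
#' single `seed`; the same configuration regenerates byte-identical
#' outputs.
#'
#' Defaults encode the study conditions: a 2014-2023 window with some
#' out-of-window and non-European records, regression data over 120
#' orders with Gaussian noise sigma 0.3 on the ln scale, and true
#' coefficients mirroring the magnitudes reported for the real harvest
#' (species richness 0.47; research-needed 0.54; Habitats 0.35; Birds
#' 0.37; marine -0.27; remaining policies small).
#'
#' @param seed integer seed.
#' @param n_orders orders in the backbone / rows in regression data.
#' @param species_per_order accepted species per order (exact).
#' @param synonym_rate fraction of accepted species given a synonym row.
#' @param family_only_rate extra species with family but no order rank,
#'   as a fraction of accepted species (drives the family-rank merge
#'   fallback).
#' @param n_journals journal records before deduplication.
#' @param duplicate_journal_rate fraction of journals re-listed under a
#'   second discovery method (same Wikidata id).
#' @param missing_openalex_rate fraction of journals lacking an
#'   OpenAlex id (unusable downstream).
#' @param n_articles article records.
#' @param taxonomic_fraction fraction of articles planted as taxonomic
#'   (keyword plus backbone names, passing every filter).
#' @param planted_names_per_article mean planted binomials per
#'   taxonomic article (at least one).
#' @param abbreviation_rate probability a taxonomic article carries an
#'   additional abbreviated "G. epithet" mention.
#' @param decoy_rate probability of planting a well-formed binomial
#'   absent from the backbone (must never be extracted as a mention).
#' @param keyword_collision_rate fraction of non-taxonomic articles
#'   that nevertheless contain a keyword (the planted false-positive
#'   rate of the corpus filter).
#' @param n_persons distinct persons behind the author ids.
#' @param duplicate_id_rate fraction of European persons appearing
#'   under two author ids (alternately satisfying merge rule 1 and
#'   rule 2 preconditions).
#' @param name_collision_rate fraction of additional persons planted as
#'   truncated-name collisions (distinct persons, different
#'   institutions and orders; must never be merged).
#' @param non_european_rate fraction of persons with only non-European
#'   affiliations (filtered out of the author set).
#' @param n_institutions institution identifier pool size.
#' @param true_beta named coefficient vector: intercept,
#'   speciesRichness, then the nine policies (ln scale).
#' @param noise_sigma Gaussian noise on the ln response.
#' @param contamination_rate fraction of regression rows given gross
#'   response outliers (+4 on the ln scale).
#' @param n_occurrences occurrence records.
#' @param n_countries countries for occurrence records.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    seed = 1,
    n_orders = 20, species_per_order = 25,
    synonym_rate = 0.15, family_only_rate = 0.05,
    n_journals = 30, duplicate_journal_rate = 0.1,
    missing_openalex_rate = 0.2,
    n_articles = 300, taxonomic_fraction = 0.5,
    planted_names_per_article = 2, abbreviation_rate = 0.3,
    decoy_rate = 0.3, keyword_collision_rate = 0,
    n_persons = 80, duplicate_id_rate = 0.15, name_collision_rate = 0.1,
    non_european_rate = 0.1, n_institutions = 30,
    true_beta = c(`(Intercept)` = 1.0, speciesRichness = 0.47,
                  taxonomicResearchNeeded = 0.54, cropWildRelatives = 0.05,
                  iasListConcern = -0.08, horizonInvasives = 0.06,
                  habitatsDir = 0.35, marineDir = -0.27, redlistFull = 0.10,
                  birdDir = 0.37, pollinators = 0.12),
    noise_sigma = 0.3, contamination_rate = 0,
    n_occurrences = 1500, n_countries = 10) {
  rates <- c(synonym_rate, family_only_rate, duplicate_journal_rate,
             missing_openalex_rate, taxonomic_fraction, abbreviation_rate,
             decoy_rate, keyword_collision_rate, duplicate_id_rate,
             name_collision_rate, non_european_rate, contamination_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            n_orders >= 1, species_per_order >= 1, n_journals >= 2,
            n_articles >= 1, n_persons >= 2, noise_sigma > 0,
            length(true_beta) == 11)
  structure(as.list(environment()), class = "generator_config")
}

# --- pronounceable synthetic words -----------------------------------------
# Syllable-built names: no real taxon, person or place names, so fixtures
# can never make accidental semantic claims.

.syllables <- c("ba", "be", "bi", "bo", "bu", "ca", "ce", "ci", "co", "cu",
                "da", "de", "di", "do", "du", "fa", "fe", "fi", "fo", "fu",
                "ga", "ge", "gi", "go", "gu", "la", "le", "li", "lo", "lu",
                "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu",
                "pa", "pe", "pi", "po", "pu", "ra", "re", "ri", "ro", "ru",
                "sa", "se", "si", "so", "su", "ta", "te", "ti", "to", "tu",
                "va", "ve", "vi", "vo", "vu", "za", "ze", "zi", "zo", "zu")

syn_word <- function(n_syl = 3) {
  paste0(sample(.syllables, n_syl, replace = TRUE), collapse = "")
}

syn_words <- function(n, n_syl = 3, capitalise = FALSE, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    w <- syn_word(n_syl)
    if (capitalise) w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, 100))
    if (!w %in% out && !w %in% avoid) out <- c(out, w)
  }
  out
}

#' Generate a synthetic taxonomic backbone
#'
#' Builds `n_orders` orders of exactly `species_per_order` accepted
#' species each (so per-order richness is known by construction), plus
#' a fraction of synonym rows pointing at accepted rows, plus a
#' fraction of accepted species with family but no order rank. Orders
#' are distributed over three synthetic kingdoms with one phylum and
#' class each and three families per order.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, `backbone.tsv` is written
#'   there.
#' @return list with `taxa` (tibble in backbone TSV column order) and
#'   `path` (or `NULL`).
#' @export
generate_backbone <- function(config, dir = NULL) {
  taxa <- withr::with_seed(config$seed + 101L, {
    kingdoms <- c("Zoomorpha", "Phytomorpha", "Mycomorpha")
    n_ord <- config$n_orders
    orders <- paste0(syn_words(n_ord, 3, capitalise = TRUE), "ales")
    kingdom_of <- kingdoms[(seq_len(n_ord) - 1L) %% 3L + 1L]
    genera <- syn_words(n_ord * 4, 3, capitalise = TRUE)
    rows <- list()
    tid <- 0L
    next_id <- function() { tid <<- tid + 1L; sprintf("T%05d", tid) }
    epithet_pool <- syn_words(ceiling(n_ord * (config$species_per_order * 1.5 + 10)), 3)
    ep_i <- 0L
    next_epithet <- function() { ep_i <<- ep_i + 1L; epithet_pool[ep_i] }

    for (o in seq_len(n_ord)) {
      fams <- paste0(syn_words(3, 2, capitalise = TRUE), "idae")
      ord_genera <- genera[(o - 1L) * 4L + 1:4]
      n_acc <- config$species_per_order
      for (s in seq_len(n_acc)) {
        g <- ord_genera[(s - 1L) %% 4L + 1L]
        nm <- paste(g, next_epithet())
        acc_id <- next_id()
        rows[[length(rows) + 1]] <- list(
          taxonID = acc_id, scientificName = nm, taxonRank = "species",
          taxonomicStatus = "accepted", acceptedTaxonID = "",
          genus = g, family = fams[(s - 1L) %% 3L + 1L],
          order = orders[o], class = paste0(kingdom_of[o], "ia"),
          phylum = paste0(kingdom_of[o], "phyta"), kingdom = kingdom_of[o]
        )
        if (runif(1) < config$synonym_rate) {
          syn_nm <- paste(g, next_epithet())
          rows[[length(rows) + 1]] <- list(
            taxonID = next_id(), scientificName = syn_nm,
            taxonRank = "species", taxonomicStatus = "synonym",
            acceptedTaxonID = acc_id, genus = g,
            family = fams[(s - 1L) %% 3L + 1L], order = orders[o],
            class = paste0(kingdom_of[o], "ia"),
            phylum = paste0(kingdom_of[o], "phyta"), kingdom = kingdom_of[o]
          )
        }
      }
      # genus-rank row per order, exercises non-species handling
      rows[[length(rows) + 1]] <- list(
        taxonID = next_id(), scientificName = ord_genera[1],
        taxonRank = "genus", taxonomicStatus = "accepted",
        acceptedTaxonID = "", genus = ord_genera[1],
        family = fams[1], order = orders[o],
        class = paste0(kingdom_of[o], "ia"),
        phylum = paste0(kingdom_of[o], "phyta"), kingdom = kingdom_of[o]
      )
    }
    # family-only species: accepted, no order rank in the backbone
    n_family_only <- round(config$family_only_rate * n_ord *
                             config$species_per_order)
    if (n_family_only > 0) {
      fo_genera <- syn_words(max(2, ceiling(n_family_only / 3)), 3,
                             capitalise = TRUE, avoid = genera)
      fo_families <- paste0(syn_words(max(2, ceiling(n_family_only / 5)), 2,
                                      capitalise = TRUE), "aceae")
      for (k in seq_len(n_family_only)) {
        g <- fo_genera[(k - 1L) %% length(fo_genera) + 1L]
        rows[[length(rows) + 1]] <- list(
          taxonID = next_id(), scientificName = paste(g, next_epithet()),
          taxonRank = "species", taxonomicStatus = "accepted",
          acceptedTaxonID = "", genus = g,
          family = fo_families[(k - 1L) %% length(fo_families) + 1L],
          order = "", class = "Zoomorphia", phylum = "Zoomorphaphyta",
          kingdom = "Zoomorpha"
        )
      }
    }
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  })
  path <- NULL
  if (!is.null(dir)) {
    path <- file.path(dir, "backbone.tsv")
    readr::write_tsv(taxa, path, progress = FALSE)
  }
  list(taxa = taxa, path = path)
}

# person pool: names, institutions, countries, home taxa, duplicate and
# collision structure. Internal to generate_corpus.
generate_persons <- function(config, backbone_index) {
  euro <- c("BE", "DE", "FR", "ES", "IT", "PL", "CZ", "PT", "SE", "EE")
  non_euro <- c("US", "BR", "CN", "JP", "AU")
  orders_all <- names(backbone_index$richness_by_order)
  fo <- backbone_index$taxa[backbone_index$taxa$taxonRank == "species" &
                              !nzchar(backbone_index$taxa$order), , drop = FALSE]

  firsts <- syn_words(config$n_persons * 2, 3, capitalise = TRUE)
  lasts <- syn_words(config$n_persons * 2, 3, capitalise = TRUE)
  insts <- sprintf("I%03d", seq_len(config$n_institutions))

  persons <- list()
  used_trunc <- character(0)
  pi <- 0L
  add_person <- function(first, last, country, institution, home_order,
                         home_family, dup_rule = NA_character_) {
    pi <<- pi + 1L
    p <- list(personId = sprintf("P%03d", pi),
              first = first, last = last,
              displayName = paste(first, last),
              country = country, institution = institution,
              homeOrder = home_order, homeFamily = home_family,
              dupRule = dup_rule)
    persons[[length(persons) + 1]] <<- p
    used_trunc <<- c(used_trunc, paste0(substr(first, 1, 1), tolower(last)))
    p
  }

  n_family_persons <- if (nrow(fo) > 0) max(1, round(config$family_only_rate *
                                                       config$n_persons)) else 0
  k <- 0L
  while (pi < config$n_persons) {
    k <- k + 1L
    first <- firsts[(k - 1L) %% length(firsts) + 1L]
    last <- lasts[(k - 1L) %% length(lasts) + 1L]
    if (paste0(substr(first, 1, 1), tolower(last)) %in% used_trunc) next
    is_euro <- runif(1) >= config$non_european_rate
    country <- if (is_euro) sample(euro, 1) else sample(non_euro, 1)
    family_focus <- is_euro && pi < n_family_persons
    home_order <- if (family_focus) "" else sample(orders_all, 1)
    home_family <- if (family_focus) sample(unique(fo$family), 1) else ""
    dup <- if (is_euro && runif(1) < config$duplicate_id_rate) {
      if (runif(1) < 0.5) "rule1" else "rule2"
    } else NA_character_
    add_person(first, last, country, institution = sample(insts, 1),
               home_order, home_family, dup)
  }
  # planted truncated-name collisions: same initial + last name, distinct
  # first names, institutions and home orders -> must never merge
  n_coll <- round(config$name_collision_rate * config$n_persons)
  for (j in seq_len(n_coll)) {
    base <- persons[[j]]
    alt_first <- syn_words(1, 3, capitalise = TRUE, avoid = base$first)
    # force the same initial as the base person's first name
    alt_first <- paste0(substr(base$first, 1, 1), substr(alt_first, 2, 100))
    if (identical(alt_first, base$first)) alt_first <- paste0(alt_first, "ro")
    alt_inst <- setdiff(insts, base$institution)
    alt_orders <- setdiff(orders_all, base$homeOrder)
    add_person(alt_first, base$last, sample(euro, 1),
               sample(alt_inst, 1), sample(alt_orders, 1), "")
  }

  # author ids; duplicated persons get two
  aid <- 0L
  for (i in seq_along(persons)) {
    aid <- aid + 1L
    persons[[i]]$authorIds <- sprintf("A%04d", aid)
    persons[[i]]$variants <- persons[[i]]$displayName
    if (!is.na(persons[[i]]$dupRule)) {
      aid <- aid + 1L
      persons[[i]]$authorIds <- c(persons[[i]]$authorIds, sprintf("A%04d", aid))
      persons[[i]]$variants <- c(
        persons[[i]]$variants,
        if (persons[[i]]$dupRule == "rule1") {
          persons[[i]]$displayName        # same name, same institution
        } else {
          paste0(substr(persons[[i]]$first, 1, 1), ". ", persons[[i]]$last)
        }
      )
    }
  }
  persons
}

keyword_sentence <- function() {
  lang_kw <- default_keywords()
  lang <- sample(names(lang_kw), 1)
  kw <- sample(lang_kw[[lang]], 1)
  sprintf("This study presents a %s revision of the group.", kw)
}

#' Generate a synthetic journal table and article corpus with truth
#'
#' Journals include records lacking OpenAlex ids and duplicate listings
#' sharing a Wikidata id. Planted taxonomic articles pass every corpus
#' filter (usable journal, 2014-2023 date, at least one European
#' affiliation, Life Sciences domain, a keyword in title or abstract —
#' including abstract-only "nov." cases — across the configured
#' languages) and carry backbone binomials in the abstract, optionally
#' followed by an abbreviated "G. epithet" mention of the same genus
#' and by decoy binomials absent from the backbone. Non-taxonomic
#' articles variously fail the date, affiliation, domain or keyword
#' filter; a configurable fraction of the otherwise-passing ones get a
#' colliding keyword (the planted false-positive rate).
#'
#' Author identities follow [generator_config()]'s duplicate and
#' collision structure; every author id of a duplicated person leads at
#' least one taxonomic article planting species of that person's home
#' order (or home family for persons whose taxa lack order rank), so
#' the merge rules' preconditions hold by construction.
#'
#' @param config a [generator_config()].
#' @param backbone result of [generate_backbone()].
#' @param dir optional output directory (`journals.tsv`,
#'   `articles.jsonl`).
#' @return list with `journals` (tibble), `articles` (list of records)
#'   and `truth`: `articleLabels` (named logical), `plantedMentions`
#'   (named list of binomials), `collisionArticles` (ids),
#'   `personPartition` (tibble `authorId`, `personId`).
#' @export
generate_corpus <- function(config, backbone, dir = NULL) {
  index <- backbone_index_from_tibble(backbone$taxa)
  out <- withr::with_seed(config$seed + 202L, {
    journals <- generate_journals(config)
    usable <- journals$openalexId[nzchar(journals$openalexId)]
    persons <- generate_persons(config, index)

    euro_persons <- persons[vapply(persons, function(p)
      p$country %in% european_countries(), logical(1))]
    # (authorId, person index, display variant) units that must each lead
    # an article so ordersPublished covers the home taxa of both ids
    leads <- list()
    for (i in seq_along(euro_persons)) {
      p <- euro_persons[[i]]
      for (k in seq_along(p$authorIds)) {
        leads[[length(leads) + 1]] <- list(person = p, variant = k)
      }
    }

    sp <- index$taxa[index$taxa$taxonRank == "species" &
                       index$taxa$taxonomicStatus == "accepted", , drop = FALSE]
    n_tax <- round(config$taxonomic_fraction * config$n_articles)
    if (n_tax < length(leads)) {
      tc_log("generate_corpus: %d taxonomic articles < %d author-id units;%s",
             n_tax, length(leads), " some merge preconditions may not hold")
    }
    articles <- list()
    labels <- logical(0)
    planted <- list()
    collision_ids <- character(0)
    partition_rows <- list()
    seen_ids <- character(0)

    all_author_pool <- persons
    pick_authorship <- function(p, variant_idx) {
      list(authorId = p$authorIds[variant_idx],
           displayName = p$variants[variant_idx],
           institutionIds = list(p$institution),
           institutionNames = list(paste("Institute", p$institution)),
           countryCodes = list(p$country))
    }

    for (i in seq_len(config$n_articles)) {
      aid <- sprintf("W%05d", i)
      taxonomic <- i <= n_tax
      lead <- leads[[(i - 1L) %% length(leads) + 1L]]
      p <- lead$person

      authorships <- list(pick_authorship(p, lead$variant))
      n_co <- sample(0:2, 1)
      for (j in seq_len(n_co)) {
        q <- all_author_pool[[sample(length(all_author_pool), 1)]]
        if (q$personId == p$personId) next
        authorships[[length(authorships) + 1]] <-
          pick_authorship(q, sample(length(q$authorIds), 1))
      }

      if (taxonomic) {
        pool <- if (nzchar(p$homeOrder)) {
          sp[sp$order == p$homeOrder, , drop = FALSE]
        } else {
          sp[sp$family == p$homeFamily, , drop = FALSE]
        }
        n_names <- min(nrow(pool), 1 + rpois(1, config$planted_names_per_article - 1))
        chosen <- pool[sample(nrow(pool), n_names), , drop = FALSE]
        sentences <- sprintf("Populations of %s were examined in detail.",
                             chosen$scientificName)
        mentions <- chosen$scientificName

        if (runif(1) < config$abbreviation_rate) {
          g <- chosen$genus[1]
          others <- sp[sp$genus == g &
                         !(sp$scientificName %in% chosen$scientificName), ,
                       drop = FALSE]
          ambiguous <- any(substr(setdiff(chosen$genus, g), 1, 1) ==
                             substr(g, 1, 1))
          if (nrow(others) > 0 && !ambiguous) {
            pick <- others[sample(nrow(others), 1), , drop = FALSE]
            epithet <- sub("^[^ ]+ ", "", pick$scientificName)
            sentences <- c(sentences,
                           sprintf("Records of %s. %s are also discussed.",
                                   substr(g, 1, 1), epithet))
            mentions <- c(mentions, pick$scientificName)
          }
        }
        if (runif(1) < config$decoy_rate) {
          decoy <- paste(syn_words(1, 4, capitalise = TRUE),
                         syn_words(1, 4))
          if (is.null(match_binomial(index, decoy))) {
            sentences <- c(sentences,
                           sprintf("The habitat resembles that of %s.", decoy))
          }
        }
        kw_abstract_only <- runif(1) < 0.15
        title <- if (kw_abstract_only) {
          "Systematic notes on a remarkable lineage"
        } else {
          "A taxonomic revision with a checklist of species"
        }
        abstract <- paste(
          c(if (kw_abstract_only) "A distinctive form is described as sp. nov."
            else keyword_sentence(),
            sentences),
          collapse = " ")
        art <- list(
          articleId = aid,
          journalId = sample(usable, 1),
          title = title, abstract = abstract,
          language = "en",
          publicationDate = sprintf("20%02d-0%d-1%d", sample(14:23, 1),
                                    sample(1:9, 1), sample(0:9, 1)),
          conceptIds = if (runif(1) < 0.2) list("C58642233") else list(),
          domainId = "D1",
          authorships = authorships
        )
        labels[aid] <- TRUE
        planted[[aid]] <- mentions
        for (au in authorships) {
          if (unlist(au$countryCodes) %in% european_countries() &&
              !au$authorId %in% seen_ids) {
            seen_ids <- c(seen_ids, au$authorId)
            owner <- Filter(function(q) au$authorId %in% q$authorIds, persons)[[1]]
            partition_rows[[length(partition_rows) + 1]] <-
              tibble::tibble(authorId = au$authorId, personId = owner$personId)
          }
        }
      } else {
        failure <- sample(c("keyword", "keyword", "date", "affiliation",
                            "domain", "journal"), 1)
        collides <- failure == "keyword" &&
          runif(1) < config$keyword_collision_rate
        title <- "Observations on regional field populations"
        abstract <- paste(
          "Seasonal abundance patterns were recorded across sites.",
          if (collides) keyword_sentence() else
            "Habitat structure explained most variation."
        )
        art <- list(
          articleId = aid,
          journalId = if (failure == "journal") "S_UNUSABLE" else sample(usable, 1),
          title = title, abstract = abstract,
          language = "en",
          publicationDate = if (failure == "date") {
            sample(c("2012-06-15", "2013-12-31", "2024-01-01"), 1)
          } else {
            sprintf("20%02d-0%d-1%d", sample(14:23, 1), sample(1:9, 1),
                    sample(0:9, 1))
          },
          conceptIds = list(),
          domainId = if (failure == "domain") "D2" else "D1",
          authorships = if (failure == "affiliation") {
            ne <- Filter(function(q) !q$country %in% european_countries(),
                         persons)
            if (length(ne) == 0) authorships else
              list(pick_authorship(ne[[sample(length(ne), 1)]], 1))
          } else {
            authorships
          }
        )
        labels[aid] <- FALSE
        if (collides) {
          collision_ids <- c(collision_ids, aid)
          # collision articles enter the corpus; keep the partition truth
          # covering their authors too
          for (au in art$authorships) {
            if (unlist(au$countryCodes) %in% european_countries() &&
                !au$authorId %in% seen_ids) {
              seen_ids <- c(seen_ids, au$authorId)
              owner <- Filter(function(q) au$authorId %in% q$authorIds,
                              persons)[[1]]
              partition_rows[[length(partition_rows) + 1]] <-
                tibble::tibble(authorId = au$authorId, personId = owner$personId)
            }
          }
        }
      }
      articles[[length(articles) + 1]] <- art
    }
    list(journals = journals, articles = articles,
         truth = list(
           articleLabels = labels,
           plantedMentions = planted,
           collisionArticles = collision_ids,
           personPartition = dplyr::bind_rows(partition_rows)
         ))
  })
  if (!is.null(dir)) {
    readr::write_tsv(out$journals, file.path(dir, "journals.tsv"),
                     progress = FALSE)
    write_jsonl(out$articles, file.path(dir, "articles.jsonl"))
  }
  out
}

generate_journals <- function(config) {
  n <- config$n_journals
  titles <- paste("Journal of", syn_words(n, 4, capitalise = TRUE), "Studies")
  rows <- tibble::tibble(
    displayName = titles,
    wikidataId = sprintf("Q9%05d", seq_len(n)),
    openalexId = ifelse(runif(n) < config$missing_openalex_rate, "",
                        sprintf("S4%05d", seq_len(n))),
    issnL = sprintf("%04d-%04d", seq_len(n), rev(seq_len(n))),
    issn = "",
    ipniPubId = ifelse(runif(n) < 0.5, sprintf("ipni-%03d", seq_len(n)), ""),
    zoobankPubId = "",
    dissolved = ifelse(runif(n) < 0.2, "true", "false"),
    dissolvedYear = "",
    discoveryMethods = sample(c("wikidata_subject", "ipni_or_zoobank_id",
                                "openalex_concept"), n, replace = TRUE)
  )
  n_dup <- round(config$duplicate_journal_rate * n)
  if (n_dup > 0) {
    dup <- rows[seq_len(n_dup), , drop = FALSE]
    dup$openalexId <- ""           # second listing found elsewhere, no OA id
    dup$ipniPubId <- ""
    dup$discoveryMethods <- "wikidata_subject"
    rows <- dplyr::bind_rows(rows, dup)
  }
  rows
}

# index a backbone tibble without the TSV round trip (generator internal;
# load_backbone remains the contract for files on disk)
backbone_index_from_tibble <- function(taxa) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  readr::write_tsv(taxa, tmp, progress = FALSE)
  suppressWarnings(load_backbone(tmp))
}

#' Generate order-level regression data with known coefficients
#'
#' Draws per-order species richness and policy counts, forms the ln(x+1)
#' design, sets `ln(authors+1) = X beta + eps` with Gaussian noise, adds
#' gross positive outliers to a `contamination_rate` fraction of rows,
#' and back-transforms the response to integer author counts. Richness
#' spans roughly 1 to 10,000 species per order; each policy touches an
#' order with probability one half, with ln counts uniform on (0, 7).
#'
#' @param config a [generator_config()].
#' @param dir optional directory (`matrix.csv`).
#' @return list with `matrix` (tibble: `order`, `speciesRichness`, nine
#'   policy counts, `authorCount`), `trueBeta`, `contaminatedRows`
#'   (indices), `path`.
#' @export
generate_regression_data <- function(config, dir = NULL) {
  res <- withr::with_seed(config$seed + 303L, {
    n <- config$n_orders
    ln_rich <- runif(n, 0.7, 9.2)
    richness <- pmax(1, round(expm1(ln_rich)))
    pols <- sapply(policy_ids(), function(pid) {
      present <- runif(n) < 0.5
      ifelse(present, round(expm1(runif(n, 0, 7))), 0)
    })
    X <- cbind(`(Intercept)` = 1,
               speciesRichness = log1p(richness),
               log1p(pols))
    stopifnot(identical(colnames(X), names(config$true_beta)))
    y_ln <- drop(X %*% config$true_beta) + rnorm(n, 0, config$noise_sigma)
    contaminated <- integer(0)
    if (config$contamination_rate > 0) {
      contaminated <- sample(n, round(config$contamination_rate * n))
      y_ln[contaminated] <- y_ln[contaminated] + 4
    }
    authors <- pmax(0, round(expm1(y_ln)))
    mat <- tibble::tibble(order = sprintf("order_%03d", seq_len(n)),
                          speciesRichness = as.integer(richness))
    for (pid in policy_ids()) mat[[pid]] <- as.integer(pols[, pid])
    mat$authorCount <- as.integer(authors)
    list(matrix = mat, trueBeta = config$true_beta,
         contaminatedRows = contaminated)
  })
  res$path <- NULL
  if (!is.null(dir)) {
    res$path <- file.path(dir, "matrix.csv")
    readr::write_csv(res$matrix, res$path, progress = FALSE)
  }
  res
}

#' Generate synthetic policy species lists
#'
#' Draws, for each of the nine policies, a sample of backbone species
#' names (accepted and synonym rows both eligible) plus a stated number
#' of unresolvable names absent from the backbone. Ground truth records
#' the expected per-order counts under synonym remapping.
#'
#' @param config a [generator_config()].
#' @param backbone result of [generate_backbone()].
#' @param dir optional directory; one `policy_<id>.tsv` per policy.
#' @param species_per_policy sample size per list.
#' @param unresolved_per_policy planted backbone-miss names per list.
#' @return list with `paths` (named), `lists` (named list of name
#'   vectors) and `truth` (`expectedUnresolved` per policy).
#' @export
generate_policy_lists <- function(config, backbone, dir,
                                  species_per_policy = 30,
                                  unresolved_per_policy = 2) {
  withr::with_seed(config$seed + 404L, {
    # only species with an order rank: the planted unresolvable names are
    # then exactly the backbone misses
    sp <- backbone$taxa[backbone$taxa$taxonRank == "species" &
                          nzchar(backbone$taxa$order), , drop = FALSE]
    paths <- character(0)
    lists <- list()
    for (pid in policy_ids()) {
      k <- min(species_per_policy, nrow(sp))
      nms <- sp$scientificName[sample(nrow(sp), k)]
      fake <- paste(syn_words(unresolved_per_policy, 4, capitalise = TRUE),
                    syn_words(unresolved_per_policy, 4))
      all_nms <- c(nms, fake)
      tbl <- tibble::tibble(scientificName = all_nms,
                            category = rep("", length(all_nms)))
      p <- file.path(dir, paste0("policy_", pid, ".tsv"))
      readr::write_tsv(tbl, p, progress = FALSE)
      paths[pid] <- p
      lists[[pid]] <- all_nms
    }
    list(paths = paths, lists = lists,
         truth = list(expectedUnresolved = unresolved_per_policy))
  })
}

#' Generate synthetic occurrence records with known agent counts
#'
#' Records are spread over countries and years 2011-2025 with per-country
#' agent pools; a fraction carry a non-PRESENT status or the
#' COUNTRY_COORDINATE_MISMATCH flag. Ground-truth distinct-agent counts
#' are tracked during emission, over exactly the records that survive
#' the stated filters.
#'
#' @param config a [generator_config()].
#' @param dir optional directory (`occurrences.tsv`).
#' @param flagged_rate probability of the mismatch flag.
#' @param absent_rate probability of a non-PRESENT status.
#' @return list with `records` (tibble), `agentCounts` (tibble
#'   `countryCode`, `nRecords`, `nDistinctRecordedBy`,
#'   `nDistinctIdentifiedBy`, sorted ascending by record count) and
#'   `path`.
#' @export
generate_occurrences <- function(config, dir = NULL, flagged_rate = 0.1,
                                 absent_rate = 0.15) {
  res <- withr::with_seed(config$seed + 505L, {
    countries <- c("BE", "DE", "FR", "ES", "IT", "PL", "CZ", "PT", "SE",
                   "EE")[seq_len(config$n_countries)]
    pools <- lapply(stats::setNames(countries, countries), function(cc) {
      n_agents <- sample(5:25, 1)
      paste(syn_words(n_agents, 2, capitalise = TRUE),
            syn_words(n_agents, 3, capitalise = TRUE))
    })
    n <- config$n_occurrences
    cc <- sample(countries, n, replace = TRUE)
    year <- sample(2011:2025, n, replace = TRUE)
    status <- ifelse(runif(n) < absent_rate, "ABSENT", "PRESENT")
    issue <- ifelse(runif(n) < flagged_rate,
                    sample(c("COUNTRY_COORDINATE_MISMATCH",
                             "TAXON_MATCH_FUZZY;COUNTRY_COORDINATE_MISMATCH"),
                           n, replace = TRUE),
                    ifelse(runif(n) < 0.1, "TAXON_MATCH_FUZZY", ""))
    recorded <- vapply(seq_len(n), function(i)
      sample(pools[[cc[i]]], 1), character(1))
    identified <- ifelse(runif(n) < 0.4, "",
                         vapply(seq_len(n), function(i)
                           sample(pools[[cc[i]]], 1), character(1)))
    records <- tibble::tibble(countryCode = cc, year = as.integer(year),
                              occurrenceStatus = status, issue = issue,
                              recordedBy = recorded, identifiedBy = identified)
    surviving <- status == "PRESENT" &
      !vapply(strsplit(issue, ";", fixed = TRUE),
              function(f) "COUNTRY_COORDINATE_MISMATCH" %in% f, logical(1)) &
      year >= 2014 & year <= 2023
    sv <- records[surviving, , drop = FALSE]
    agent_counts <- dplyr::arrange(dplyr::summarise(
      dplyr::group_by(sv, .data$countryCode),
      nRecords = dplyr::n(),
      nDistinctRecordedBy = length(unique(.data$recordedBy[nzchar(.data$recordedBy)])),
      nDistinctIdentifiedBy = length(unique(.data$identifiedBy[nzchar(.data$identifiedBy)])),
      .groups = "drop"
    ), .data$nRecords, .data$countryCode)
    list(records = records, agentCounts = agent_counts)
  })
  res$path <- NULL
  if (!is.null(dir)) {
    res$path <- file.path(dir, "occurrences.tsv")
    readr::write_tsv(res$records, res$path, progress = FALSE)
  }
  res
}

#' Generate a country population table
#'
#' @param config a [generator_config()].
#' @param dir optional directory (`population.tsv`).
#' @return list with `population` (tibble `countryCode`, `population`)
#'   and `path`.
#' @export
generate_population <- function(config, dir = NULL) {
  res <- withr::with_seed(config$seed + 606L, {
    countries <- c("BE", "DE", "FR", "ES", "IT", "PL", "CZ", "PT", "SE",
                   "EE")[seq_len(config$n_countries)]
    tibble::tibble(countryCode = countries,
                   population = round(exp(runif(length(countries),
                                                log(1e6), log(8e7)))))
  })
  path <- NULL
  if (!is.null(dir)) {
    path <- file.path(dir, "population.tsv")
    readr::write_tsv(res, path, progress = FALSE)
  }
  list(population = res, path = path)
}

#' Generate every pipeline input into a directory
#'
#' Convenience wrapper calling each generator with the same
#' configuration, so a complete, mutually consistent fixture set
#' (backbone, journals, articles, policy lists, regression matrix,
#' occurrences, population) lands in `dir`.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return list with each generator's ground truth and the file paths.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  backbone <- generate_backbone(config, dir)
  corpus <- generate_corpus(config, backbone, dir)
  policies <- generate_policy_lists(config, backbone, dir)
  regression <- generate_regression_data(config, dir)
  occurrences <- generate_occurrences(config, dir)
  population <- generate_population(config, dir)
  list(backbone = backbone, corpus = corpus, policies = policies,
       regression = regression, occurrences = occurrences,
       population = population)
}
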