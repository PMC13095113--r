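test_that("journals sharing an id merge with unioned fields", {
  j <- journal_tbl(
    list(name = "Acta", wd = "Q1", oa = "", ipni = "ip1",
         method = "wikidata_subject"),
    list(name = "Acta", wd = "Q1", oa = "S9", method = "openalex_concept")
  )
  out <- dedupe_journals(j)
  expect_equal(nrow(out), 1)
  expect_equal(out$openalexId, "S9")
  expect_equal(out$ipniPubId, "ip1")
  expect_setequal(strsplit(out$discoveryMethods, ";")[[1]],
                  c("wikidata_subject", "openalex_concept"))
})

test_that("distinct journals pass through unchanged and dedupe is idempotent", {
  j <- journal_tbl(list(name = "A", wd = "Q1", oa = "S1"),
                   list(name = "B", wd = "Q2", oa = "S2"),
                   list(name = "C", wd = "Q3", oa = ""))
  expect_identical(dedupe_journals(j), j)
  j2 <- journal_tbl(list(name = "A", wd = "Q1", oa = "S1"),
                    list(name = "A2", wd = "Q1", oa = ""),
                    list(name = "B", wd = "Q2", oa = "S2"))
  once <- dedupe_journals(j2)
  expect_identical(dedupe_journals(once), once)
})

test_that("chained identifier sharing closes transitively", {
  j <- journal_tbl(list(name = "A", wd = "Q1", oa = "S1"),
                   list(name = "B", wd = "Q1", oa = "S2"),
                   list(name = "C", wd = "Q9", oa = "S2"))
  out <- dedupe_journals(j)
  expect_equal(nrow(out), 1)
  # oracle: exhaustive pairwise closure over shared-id relation
  shares <- function(a, b) {
    (nzchar(j$wikidataId[a]) && j$wikidataId[a] == j$wikidataId[b]) ||
      (nzchar(j$openalexId[a]) && j$openalexId[a] == j$openalexId[b])
  }
  adj <- outer(1:3, 1:3, Vectorize(shares))
  reach <- adj | diag(3)
  for (k in 1:3) reach <- reach | (reach[, k] %o% reach[k, ])
  expect_equal(length(unique(apply(reach, 1, paste, collapse = ""))), 1)
})

test_that("journals without an OpenAlex id are unusable", {
  j <- journal_tbl(list(name = "A", oa = "S1"), list(name = "B", oa = ""))
  expect_equal(select_usable_journals(j)$displayName, "A")
  expect_equal(nrow(select_usable_journals(j[0, ])), 0)
  withr::with_seed(5, {
    oa <- ifelse(runif(10) < 0.4, "", sprintf("S%d", 1:10))
  })
  j10 <- dplyr::bind_rows(lapply(oa, function(x) journal_tbl(list(oa = x))))
  expect_equal(nrow(select_usable_journals(j10)), sum(nzchar(oa)))
})

test_that("keyword decision covers title/abstract scope and concepts", {
  cfg <- default_keyword_config()
  a <- article_rec(title = "A new species of Carabus from Iberia")
  r <- is_taxonomic_article(a, cfg)
  expect_true(r$decision)
  expect_true("new species" %in% r$evidence)

  # "nov." is abstract-only: a title hit must not count
  b <- article_rec(title = "Thoughts on nov. things", abstract = "Plain text.")
  expect_false(is_taxonomic_article(b, cfg)$decision)
  b2 <- article_rec(title = "Plain", abstract = "Described as sp. nov. here.")
  expect_true(is_taxonomic_article(b2, cfg)$decision)

  expect_false(is_taxonomic_article(article_rec(), cfg)$decision)

  cc <- article_rec(title = "Plain", concepts = list("C58642233"))
  expect_true(is_taxonomic_article(cc, cfg)$decision)

  # multilingual, case-insensitive
  de <- article_rec(title = "Eine NEUE ART aus den Alpen")
  expect_true(is_taxonomic_article(de, cfg)$decision)
  ru <- article_rec(abstract = "Описан новый вид жуков")
  expect_true(is_taxonomic_article(ru, cfg)$decision)
})

test_that("article filters apply window, affiliation, domain and journal", {
  cfg <- default_keyword_config()
  usable <- journal_tbl(list(name = "A", oa = "S1"))
  ok <- article_rec(id = "ok", title = "A checklist of mosses")
  boundary_lo <- article_rec(id = "lo", title = "A checklist",
                             date = "2014-01-01")
  too_early <- article_rec(id = "early", title = "A checklist",
                           date = "2013-12-31")
  non_euro <- article_rec(id = "ne", title = "A checklist", countries = "US")
  wrong_domain <- article_rec(id = "dom", title = "A checklist",
                              domain = "D2")
  wrong_journal <- article_rec(id = "jr", title = "A checklist",
                               journal = "S_X")
  no_kw <- article_rec(id = "kw", title = "Field notes")
  arts <- list(ok, boundary_lo, too_early, non_euro, wrong_domain,
               wrong_journal, no_kw)
  corpus <- filter_articles(arts, usable, cfg)
  expect_setequal(vapply(corpus, `[[`, character(1), "articleId"),
                  c("ok", "lo"))
  counts <- attr(corpus, "filter_counts")
  expect_equal(sum(counts[2:7]) + counts[["corpus"]], counts[["input"]])

  expect_length(filter_articles(list(), usable, cfg), 0)
  bad_date <- article_rec(id = "bd", title = "A checklist",
                          date = "not-a-date")
  expect_warning(out <- filter_articles(list(bad_date), usable, cfg),
                 "unparseable")
  expect_length(out, 0)
})

test_that("the corpus equals the intersection of individual filter masks", {
  cfg <- generator_config(seed = 21, n_articles = 120)
  bb <- generate_backbone(cfg)
  sim <- generate_corpus(cfg, bb)
  usable <- select_usable_journals(dedupe_journals(sim$journals))
  kc <- default_keyword_config()
  corpus_ids <- vapply(filter_articles(sim$articles, usable, kc),
                       `[[`, character(1), "articleId")

  masks <- vapply(sim$articles, function(a) {
    d <- suppressWarnings(as.Date(a$publicationDate))
    c(journal = a$journalId %in% usable$openalexId,
      date = !is.na(d) && d >= as.Date(kc$window_start) &&
        d <= as.Date(kc$window_end),
      euro = any(unlist(lapply(a$authorships, function(au)
        unlist(au$countryCodes))) %in% kc$european_country_codes),
      domain = identical(a$domainId, kc$life_sciences_domain_id),
      kw = is_taxonomic_article(a, kc)$decision)
  }, logical(5))
  manual <- vapply(sim$articles, `[[`, character(1), "articleId")[
    apply(masks, 2, all)]
  expect_setequal(corpus_ids, manual)
})
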