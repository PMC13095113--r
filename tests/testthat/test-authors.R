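test_that("name keys strip separators and truncate to initial + last name", {
  k <- make_keys("Nils J. Broek")
  expect_equal(k$stripped, "NilsJBroek")
  expect_equal(k$truncated, "NBroek")
  expect_false(k$degenerate)

  # comma inversion and hyphen removal
  k2 <- make_keys("Vidal-Montes, Rosa")
  expect_equal(k2$stripped, "RosaVidalMontes")
  expect_equal(k2$truncated, "RVidalMontes")

  k3 <- make_keys("Linnaeus")
  expect_equal(k3$stripped, "Linnaeus")
  expect_equal(k3$truncated, "LLinnaeus")
  expect_true(k3$degenerate)

  expect_error(make_keys(""), "empty")
  expect_error(make_keys("   "), "empty")
})

test_that("extraction unions orders over an author's articles and drops non-Europeans", {
  idx <- tiny_backbone()
  a1 <- annotate_article_species(
    article_rec(id = "W1", abstract = "On Carabus solis populations",
                author_id = "A1", author_name = "Ann Author"), idx)
  a2 <- annotate_article_species(
    article_rec(id = "W2", abstract = "On Abies alba stands",
                author_id = "A1", author_name = "Ann Author"), idx)
  a3 <- annotate_article_species(
    article_rec(id = "W3", abstract = "On Abies alba again",
                author_id = "A2", author_name = "Bob Far",
                countries = "US"), idx)
  authors <- extract_authors(list(a1, a2, a3))
  expect_equal(nrow(authors), 1)
  expect_setequal(authors$ordersPublished[[1]], c("Carabales", "Pinales"))
  expect_setequal(authors$articleIds[[1]], c("W1", "W2"))
  expect_equal(nrow(extract_authors(list())), 0)
})

test_that("merge rules: stripped+institution, truncated+institution+orders", {
  # rule 2: initial variant, same institution, shared order
  a <- author_rec("A1", "John Smith", "I1", orders = "Coleoptera")
  b <- author_rec("A2", "J. Smith", "I1", orders = c("Coleoptera", "Diptera"))
  res <- merge_duplicates(dplyr::bind_rows(a, b))
  expect_equal(res$report$nAfter, 1)
  expect_equal(res$report$mergedPairs$rule, "truncated_institution_taxon")
  expect_setequal(res$authors$authorIds[[1]], c("A1", "A2"))

  # same stripped name but no shared institution: distinct people
  c1 <- author_rec("A3", "John Smith", "I1", orders = "Coleoptera")
  c2 <- author_rec("A4", "John Smith", "I2", orders = "Coleoptera")
  res2 <- merge_duplicates(dplyr::bind_rows(c1, c2))
  expect_equal(res2$report$nAfter, 2)

  # rule 1 needs no taxon overlap
  d1 <- author_rec("A5", "Mia Vox", "I3", orders = "Pinales")
  d2 <- author_rec("A6", "Mia Vox", "I3", orders = "Carabales")
  res3 <- merge_duplicates(dplyr::bind_rows(d1, d2))
  expect_equal(res3$report$mergedPairs$rule, "stripped_institution")

  # truncated match without taxon overlap: not the same person
  e1 <- author_rec("A7", "Mo Rel", "I4", orders = "Pinales")
  e2 <- author_rec("A8", "M. Rel", "I4", orders = "Carabales")
  expect_equal(merge_duplicates(dplyr::bind_rows(e1, e2))$report$nAfter, 2)

  # family fallback when either side lacks order-rank taxa
  f1 <- author_rec("A9", "Ana Lis", "I5", families = "Pinaceae")
  f2 <- author_rec("A10", "A. Lis", "I5", orders = "Pinales",
                   families = "Pinaceae")
  expect_equal(merge_duplicates(dplyr::bind_rows(f1, f2))$report$nAfter, 1)

  single <- author_rec("A11", "Solo Person", "I9")
  res4 <- merge_duplicates(single)
  expect_equal(res4$report$nBefore, 1)
  expect_equal(res4$report$nAfter, 1)
  expect_equal(nrow(res4$report$mergedPairs), 0)
})

test_that("merging is idempotent and never increases the record count", {
  withr::with_seed(42, {
    n <- 40
    recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      nm <- paste(sample(c("Ana", "A.", "Bo", "B.", "Cy", "C."), 1),
                  sample(c("Rix", "Sol", "Tam"), 1))
      author_rec(sprintf("A%02d", i), nm, sample(c("I1", "I2", "I3"), 1),
                 orders = sample(c("Ord1", "Ord2"),
                                 sample(1:2, 1)))
    }))
  })
  once <- merge_duplicates(recs)
  expect_lte(once$report$nAfter, once$report$nBefore)
  twice <- merge_duplicates(once$authors)
  expect_equal(twice$report$nAfter, once$report$nAfter)
  expect_equal(nrow(twice$report$mergedPairs), 0)
})

test_that("merge equals brute-force transitive closure on random instances", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- 60
      firsts <- c("Ana", "Bodo", "Cyra", "Dane")
      lasts <- c("Rix", "Soli", "Tamo", "Ulva", "Vero")
      recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        first <- sample(firsts, 1)
        if (runif(1) < 0.4) first <- paste0(substr(first, 1, 1), ".")
        author_rec(sprintf("A%02d", i), paste(first, sample(lasts, 1)),
                   sample(c("I1", "I2", "I3", "I4"), 1),
                   orders = sample(c("Ord1", "Ord2", "Ord3"),
                                   sample(0:2, 1)),
                   families = sample(c("FamA", "FamB"), 1))
      }))
    })
    got <- merge_duplicates(recs)

    # oracle: apply the pairwise rule to every pair, then close over
    # connectivity with matrix reachability
    link <- matrix(FALSE, nrow(recs), nrow(recs))
    for (i in seq_len(nrow(recs) - 1)) {
      for (j in (i + 1):nrow(recs)) {
        link[i, j] <- link[j, i] <-
          !is.na(taxcap:::author_match_rule(i, j, recs))
      }
    }
    reach <- link | diag(nrow(recs)) > 0
    for (k in seq_len(nrow(recs))) {
      reach <- reach | (reach[, k] %o% reach[k, ])
    }
    oracle_clusters <- unique(apply(reach, 1, paste, collapse = ""))
    expect_equal(got$report$nAfter, length(oracle_clusters))
  }
})

test_that("pairwise precision and recall against a truth partition", {
  perfect <- dplyr::bind_rows(author_rec("A1", "X Y", "I1"),
                              author_rec("A2", "X Y", "I1"))
  merged <- merge_duplicates(perfect)$authors
  truth <- tibble::tibble(authorId = c("A1", "A2"), personId = "P1")
  q <- merge_quality(merged, truth)
  expect_equal(q$precision, 1)
  expect_equal(q$recall, 1)

  # 10 true duplicate pairs; system finds 8, no spurious merges
  merged8 <- dplyr::bind_rows(
    lapply(1:8, function(i) {
      r <- author_rec(paste0("B", i), "N N", "I1")
      r$authorIds <- list(c(paste0("B", i), paste0("C", i)))
      r
    }),
    author_rec("B9", "N N", "I1"), author_rec("C9", "N N", "I1"),
    author_rec("B10", "N N", "I1"), author_rec("C10", "N N", "I1")
  )
  truth10 <- tibble::tibble(
    authorId = c(paste0("B", 1:10), paste0("C", 1:10)),
    personId = rep(paste0("P", 1:10), 2)
  )
  q2 <- merge_quality(merged8, truth10)
  expect_equal(q2$precision, 1)
  expect_equal(q2$recall, 0.8)

  # no merges at all: precision 1 by convention, recall 0
  none <- dplyr::bind_rows(author_rec("B9", "N N", "I1"),
                           author_rec("C9", "N N", "I2"))
  truth1 <- tibble::tibble(authorId = c("B9", "C9"), personId = "P1")
  expect_warning(q3 <- merge_quality(none, truth1), "convention")
  expect_equal(q3$precision, 1)
  expect_equal(q3$recall, 0)

  expect_error(
    merge_quality(none, tibble::tibble(authorId = "Z1", personId = "P")),
    "universe")
})

test_that("the duplicate-inflation bound is the product of its rates", {
  expect_equal(inflation_bound(9 / 200, 0.10), 0.45)
  expect_equal(inflation_bound(0, 0.7), 0)
  expect_equal(inflation_bound(1, 1), 100)
  expect_error(inflation_bound(-0.1, 0.5), "0, 1")
  expect_error(inflation_bound(0.5, 1.2), "0, 1")
})
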