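#' Pipeline configuration
#'
#' Paths to every input, the article-selection configuration, the
#' robust-fit configuration and a handful of behavioural flags. A YAML
#' file with the same field names can be loaded via
#' [read_pipeline_config()]. Optional stages (occurrences, population)
#' are skipped with an explicit notice when their inputs are absent.
#'
#' @param journals,articles,backbone input paths (TSV, JSONL, TSV).
#' @param policies named character vector, policy id to TSV path.
#' @param occurrences,population optional TSV paths.
#' @param keyword_config a `keyword_config`.
#' @param fit a [fit_config()].
#' @param remap_synonyms count synonym hits under the accepted taxon's
#'   order.
#' @param outlier_threshold standardised-residual threshold.
#' @param out_dir directory for intermediate artifacts; `NULL` disables
#'   materialisation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(journals, articles, backbone, policies,
                            occurrences = NULL, population = NULL,
                            keyword_config = default_keyword_config(),
                            fit = fit_config(), remap_synonyms = TRUE,
                            outlier_threshold = 3, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kw <- if (!is.null(raw$keyword_config)) {
    do.call(default_keyword_config, raw$keyword_config)
  } else {
    default_keyword_config()
  }
  fc <- if (!is.null(raw$fit)) do.call(fit_config, raw$fit) else fit_config()
  pipeline_config(
    journals = raw$journals, articles = raw$articles,
    backbone = raw$backbone, policies = unlist(raw$policies),
    occurrences = raw$occurrences, population = raw$population,
    keyword_config = kw, fit = fc,
    remap_synonyms = raw$remap_synonyms %||% TRUE,
    outlier_threshold = raw$outlier_threshold %||% 3,
    out_dir = raw$out_dir
  )
}

#' Run the full supply-demand pipeline
#'
#' Executes the stages in order — journal deduplication and selection,
#' article filtering, species-name annotation, author extraction and
#' disambiguation, demand-matrix construction, the robust log-log
#' regression with model comparison and diagnostics, and (when inputs
#' are present) the occurrence agent counts and the author-population
#' correlation. Intermediate artifacts (`corpus.jsonl`,
#' `annotated.jsonl`, `authors.jsonl`, `matrix.csv`, `report.json`) are
#' written to `out_dir` when set, so any stage can be re-examined in
#' isolation.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: per-stage counts, the merge report, the
#'   fits, diagnostics, model comparison, outlier table, per-order
#'   taxonomist ratios, and the optional geographic summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  index <- load_backbone(config$backbone)

  journals <- read_journals(config$journals)
  deduped <- dedupe_journals(journals)
  usable <- select_usable_journals(deduped)

  articles <- read_articles(config$articles)
  corpus <- filter_articles(articles, usable, config$keyword_config)
  filter_counts <- attr(corpus, "filter_counts")
  if (!is.null(out_dir)) write_articles(corpus, file.path(out_dir, "corpus.jsonl"))

  annotated <- annotate_corpus(corpus, index)
  if (!is.null(out_dir)) {
    write_articles(annotated, file.path(out_dir, "annotated.jsonl"))
  }

  authors <- extract_authors(annotated,
                             config$keyword_config$european_country_codes)
  merged <- merge_duplicates(authors)
  if (!is.null(out_dir)) {
    recs <- lapply(seq_len(nrow(merged$authors)), function(i)
      lapply(merged$authors[i, ], function(col) col[[1]]))
    write_jsonl(recs, file.path(out_dir, "authors.jsonl"))
  }

  lists <- load_policy_lists(config$policies)
  demand <- build_policy_matrix(lists, index,
                                authors_by_order(merged$authors),
                                remap_synonyms = config$remap_synonyms)
  if (!is.null(out_dir)) {
    readr::write_csv(demand, file.path(out_dir, "matrix.csv"),
                     progress = FALSE)
  }

  ds <- regression_dataset(demand)
  # zero-variance predictors (e.g. a policy hitting no order) carry no
  # information and would make the design rank deficient; drop with notice
  keep <- c(TRUE, apply(ds$X_full[, -1, drop = FALSE], 2,
                        function(col) stats::var(col) > 0))
  dropped <- colnames(ds$X_full)[!keep]
  if (length(dropped) > 0) {
    tc_log("run_pipeline: dropping constant predictor(s): %s",
           paste(dropped, collapse = ", "))
  }
  X_full <- ds$X_full[, keep, drop = FALSE]
  X_reduced <- X_full[, intersect(colnames(X_full),
                                  c("(Intercept)", "speciesRichness")),
                      drop = FALSE]
  full <- fit_huber_rlm(X_full, ds$y, config$fit)
  reduced <- fit_huber_rlm(X_reduced, ds$y, config$fit)
  comparison <- compare_models_f(full, reduced)
  diagnostics <- list(
    shapiro = shapiro_wilk(full$residuals),
    durbinWatson = durbin_watson(full$residuals),
    breuschPagan = breusch_pagan(full$residuals, full$X)
  )
  outliers <- flag_outliers(full, config$outlier_threshold,
                            row_labels = ds$rowLabels)
  ratios <- tibble::tibble(
    order = demand$order,
    taxonomistsPerSpecies = suppressWarnings(
      mapply(taxonomists_per_species, demand$authorCount,
             demand$speciesRichness))
  )

  geo <- NULL
  if (!is.null(config$occurrences) && file.exists(config$occurrences)) {
    occ <- read_occurrences(config$occurrences)
    geo <- count_distinct_agents(occ,
                                 as.integer(format(as.Date(config$keyword_config$window_start), "%Y")),
                                 as.integer(format(as.Date(config$keyword_config$window_end), "%Y")))
  } else {
    tc_log("run_pipeline: occurrence input absent; geo stage skipped")
  }

  population_cor <- NULL
  if (!is.null(config$population) && file.exists(config$population)) {
    pop <- readr::read_tsv(config$population,
                           col_types = readr::cols(countryCode = "c",
                                                   population = "d"),
                           progress = FALSE)
    author_countries <- table(unlist(merged$authors$countryCodes))
    shared <- intersect(names(author_countries), pop$countryCode)
    if (length(shared) >= 3) {
      popv <- stats::setNames(pop$population, pop$countryCode)[shared]
      cnt <- as.numeric(author_countries[shared])
      population_cor <- c(pearson_correlation(popv, cnt),
                          list(perCapita = per_capita(
                            stats::setNames(cnt, shared), popv)))
    }
  } else {
    tc_log("run_pipeline: population input absent; correlation skipped")
  }

  report <- list(
    journals = list(input = nrow(journals), deduped = nrow(deduped),
                    usable = nrow(usable)),
    articles = as.list(filter_counts),
    authors = list(before = merged$report$nBefore,
                   after = merged$report$nAfter,
                   mergedPairs = nrow(merged$report$mergedPairs)),
    unresolvedPolicyNames = lapply(attr(demand, "unresolved"), length),
    droppedPredictors = dropped,
    fit = list(coefficients = as.list(full$coefficients),
               standardErrors = as.list(full$standardErrors),
               pValues = as.list(full$pValues),
               scale = full$scale, converged = full$converged),
    reducedFit = list(coefficients = as.list(reduced$coefficients)),
    comparison = comparison,
    diagnostics = diagnostics,
    outliers = outliers,
    ratios = ratios,
    geo = geo,
    populationCorrelation = population_cor,
    skipped = c(if (is.null(geo)) "geo",
                if (is.null(population_cor)) "population_correlation")
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("taxcap run report\n")
  cat("  journals:", x$journals$input, "->", x$journals$usable, "usable\n")
  cat("  articles:", x$articles$input, "->", x$articles$corpus, "in corpus\n")
  cat("  authors:", x$authors$before, "->", x$authors$after,
      "after disambiguation\n")
  cat("  combined-vs-species-only F =", format(x$comparison$fStatistic),
      " p =", format(x$comparison$pValue), "\n")
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
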