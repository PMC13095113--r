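# taxcap

Assessing the supply of taxonomic expertise against the demand from
biodiversity policy, from bibliographic metadata — offline and
reproducible.

## What it does

Taxonomy underpins biodiversity policy (species protection directives,
invasive-species regulation, red-listing, pollinator monitoring), but
taxonomic capacity is unevenly distributed across taxa and countries —
the "taxonomic impediment". `taxcap` implements a pipeline that:

1. **builds a corpus of taxonomic articles** from journal and article
   records: journal deduplication by shared identifiers, a 2014–2023
   publication window, a European-affiliation requirement, a Life
   Sciences domain check, and a multilingual keyword/concept filter
   (*taxonomic, taxon, checklist, new species, …*, with "nov."
   matched in abstracts only);
2. **extracts species names**: candidate binomials shaped like
   *Genus species* are validated by exact lookup against a Darwin Core
   style taxonomic backbone, and abbreviated mentions ("*C. monilis*")
   are expanded against genera confirmed in the same article;
3. **disambiguates authors** with two rules over simplified name keys —
   same *stripped* name (separators removed) plus a shared
   institution, or same *truncated* name (first initial + last name)
   plus a shared institution plus overlapping taxonomic orders (family
   fallback when orders are missing) — closed transitively, with
   pairwise precision/recall against ground truth and a validation
   bound on residual duplicates;
4. **aggregates policy demand**: nine policy species lists (research
   needed, crop wild relatives, invasive-species lists, horizon scans,
   Habitats/Birds/Marine directives, full red list, pollinators)
   resolved against the backbone into an order × policy count matrix
   with an explicit unresolved-name ledger;
5. **relates supply to demand**: with y the number of authors per
   taxonomic order, S the order's accepted-species richness and P_j
   the order's count in policy list j, it fits the robust log-log model

   ln(y+1) = β₀ + β₁ ln(S+1) + Σⱼ βⱼ ln(Pⱼ+1) + ε

   by Huber-T M-estimation (IRLS, MAD scale, c = 1.345), compares the
   combined model against the species-only model with an F-test on
   weighted residual sums of squares, and runs Shapiro–Wilk,
   Durbin–Watson and Breusch–Pagan diagnostics with |standardised
   residual| > 3 outlier flagging;
6. **counts occurrence agents**: distinct `recordedBy`/`identifiedBy`
   strings per country under the stated status/issue/year filters, and
   per-capita rates against population.

Live harvesting of scholarly/biodiversity APIs is deliberately out of
scope: inputs are file snapshots (TSV, JSON lines), and a
**synthetic-data generator** (`simulate_inputs()`) emulates all of
them with known ground truth — planted article labels, species
mentions, duplicate-author structure, true regression coefficients,
expected agent counts — so the whole pipeline is testable end to end
without network access.

## Worked example

```r
library(taxcap)
cfg <- generator_config(seed = 7)
dir <- file.path(tempdir(), "taxcap-demo")
sim <- simulate_inputs(cfg, dir)

config <- pipeline_config(
  journals    = file.path(dir, "journals.tsv"),
  articles    = file.path(dir, "articles.jsonl"),
  backbone    = file.path(dir, "backbone.tsv"),
  policies    = sim$policies$paths,
  occurrences = file.path(dir, "occurrences.tsv"),
  population  = file.path(dir, "population.tsv"),
  out_dir     = file.path(dir, "out")
)
report <- run_pipeline(config)
report
```

prints

```
[taxcap] dedupe_journals: 33 -> 30 records
[taxcap] select_usable_journals: 26 retained, 4 lacked an OpenAlex ID
[taxcap] filter_articles: 300 -> 150 (removed_unparseable_date=0, removed_journal=34,
         removed_date=22, removed_affiliation=18, removed_domain=29, removed_keyword=47)
[taxcap] merge_duplicates: 95 -> 80 records (15 linked pairs)
[taxcap] run_pipeline: dropping constant predictor(s): speciesRichness
taxcap run report
  journals: 33 -> 26 usable
  articles: 300 -> 150 in corpus
  authors: 95 -> 80 after disambiguation
  combined-vs-species-only F = 2.521041  p = 0.08298197
```

Reading this: of 33 generated journal records, 3 were duplicate
listings and 4 lacked the identifier needed for article retrieval; the
filters cut 300 articles to the 150 planted taxonomic ones (the
per-filter removals always sum back to the input count); 95 author
identifiers collapse to 80 persons (all 15 links correct against the
generator's ground truth). The species-richness predictor is dropped
here with a notice because the synthetic backbone gives every order
identical richness (zero variance); the F-test then compares the
policy predictors against the intercept-only baseline. The report also
carries coefficients with standard errors, diagnostics, flagged
outlier orders, taxonomist-per-species ratios (e.g. `Benepeales
0.16`), per-country agent summaries, and the author–population
correlation — and is written alongside all intermediate artifacts
(`corpus.jsonl`, `annotated.jsonl`, `authors.jsonl`, `matrix.csv`,
`report.json`) under `out_dir`.

See `vignettes/taxonomic-capacity.Rmd` for the full account of the
models, rules, parameters and design decisions.

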