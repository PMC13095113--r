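---
title: "Measuring taxonomic capacity against biodiversity policy demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring taxonomic capacity against biodiversity policy demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxcap)
options(taxcap.verbose = FALSE)
```

## The problem

Biodiversity policy — species protection directives, invasive-species
regulation, red-listing, pollinator initiatives — depends on taxonomic
expertise, yet the supply of that expertise is unevenly spread across
taxa and countries. `taxcap` implements a bibliometric pipeline that
quantifies the *supply* of taxonomists from publication metadata (who
publishes taxonomic work, on which taxonomic orders, from which
countries), quantifies the *demand* expressed by policy species lists,
and relates the two with a robust regression at the level of taxonomic
orders.

The pipeline is built to run entirely offline. Live harvesting of
scholarly and biodiversity databases is out of scope; instead the
package reads file-based snapshots in simple open formats (TSV, JSON
lines) and ships a synthetic-data generator that emulates all of them
with known ground truth, so every stage is testable end to end.

## Pipeline stages and their rules

**Journal selection.** Journal records discovered through several
methods are deduplicated by shared identifier: records sharing a
Wikidata identifier or an OpenAlex identifier are merged (transitive
closure via union-find), with identifier fields unioned and conflicts
logged. The written description of the deduplication ("the same
Wikidata ID and OpenAlex ID") is ambiguous between *either shared* and
*both shared*; we merge on *either*, the safer superset, and log every
merge. Only journals with an OpenAlex identifier are usable for article
retrieval; dissolved journals are retained because the date window
naturally excludes their articles.

**Article selection.** An article enters the corpus when it appears in
a usable journal, is published inside the inclusive window (default
2014-01-01 to 2023-12-31), has at least one authorship with an
institution in a European country (an explicit, editable ISO alpha-2
list covering the European Political Community, the Vatican, and
European dependencies), belongs to the Life Sciences domain, and passes
the keyword/concept test. Keyword matching is case-insensitive,
contiguous-substring matching on whitespace-normalised text: phrases
such as *taxonomic, taxon, checklist, new species, novel species, new
genus, new genera* and translations in eleven further languages are
sought in title and abstract, while the nomenclatural marker "nov." is
sought in the abstract only (substring matching deliberately catches
"sp. nov." and "gen. nov."). Concept tags count as evidence on their
own. Case-insensitivity is a documented choice; the source of the
keyword list prints examples only, so the shipped multilingual lists
are configuration data, fully overridable.

**Species-name extraction.** Candidate binomials are word pairs shaped
like "Genus species": a capitalised word (initial capital plus at least
two lowercase letters) followed by an all-lowercase word. We require at
least three lowercase letters in the epithet — with only two, ordinary
sentence fragments such as "Here we" qualify — and allow an internal
hyphen and Unicode letters (diacritics). Candidates are validated by
exact, case-sensitive lookup against a Darwin Core style taxonomic
backbone; there is deliberately no fuzzy matching, and ordinary
capitalised phrases ("New species") are left to the backbone gate to
reject. After full binomials are confirmed, abbreviated mentions like
"C. monilis" are expanded against the genera confirmed *in the same
article*: an initial matching two confirmed genera is ambiguous and
skipped rather than guessed. Synonym names are matchable (a mention of
a synonym is still a backbone hit) but only accepted species count
toward per-order richness.

**Author disambiguation.** Authors are collected per author identifier
from the corpus, keeping those with at least one European affiliation.
Each gets two name keys: the *stripped* name (spaces, periods, hyphens
removed) and the *truncated* name (first initial + last name, same
removals). Records are linked when they have the same stripped name and
a shared institution (rule 1), or the same truncated name, a shared
institution, and intersecting published orders (rule 2) — intersecting
families when either record has no order-rank taxa, mirroring the
family fallback for the roughly 5% of authors whose taxa lack an order
rank. "Shared institution" means intersecting identifier sets, with
name-string equality only when both records lack identifiers; "same
taxonomic orders" means non-empty intersection, since set equality
would almost never hold for multi-order authors. Links are closed
transitively and components merged. Key comparison is case-insensitive
with diacritics preserved: ASCII folding would conflate distinct
Eastern-European names. Candidate pairs are generated within buckets of
equal truncated name, which both rules require in practice; a second
application of the merge to generator-style data links nothing new.
The merge is evaluated as pairwise precision/recall against a
ground-truth partition, and `inflation_bound()` implements the
validation arithmetic that bounds residual double counting: the missed
duplicate-pair rate in a manually checked sample times the share of
authors sharing a truncated name.

**Demand matrix.** Nine policy instruments are represented as species
lists: `taxonomicResearchNeeded`, `cropWildRelatives`, `iasListConcern`,
`horizonInvasives`, `habitatsDir`, `marineDir`, `redlistFull`,
`birdDir`, `pollinators`. Each name is resolved against the backbone;
by default synonym hits are remapped to the accepted taxon's order
(configurable, because policy lists rarely carry persistent
identifiers and either convention is defensible). Names that fail to
resolve — or resolve to a record with no order — are kept in a visible
unresolved ledger, so for every policy *resolved + unresolved = list
size* exactly. Percentage summaries round half-up to one decimal, the
convention of printed policy statistics.

**Supply-demand regression.** Counts are transformed with ln(x + 1) —
response (authors per order) and predictors (species richness, nine
policy counts) alike — and fitted with a robust linear model using
Huber's T norm. The IRLS loop re-estimates scale each iteration by the
MAD of residuals about their median with the 1/0.6745 consistency
constant, weights observations by `min(1, c / |r/sigma|)`, and stops
when the largest coefficient change falls below 1e-8 (default cap 50
iterations). The tuning constant defaults to 1.345 (95% efficiency
under Gaussian errors), the conventional default. Standard errors use
the standard Huber sandwich
`sigma^2 [sum psi(u)^2/(n-p)] / [mean psi'(u)]^2 (X'X)^{-1}` with
asymptotic-normal p-values, reported unadjusted. The combined model
(richness + nine policies) is compared with the species-only model by
an F-test on weighted residual sums of squares, applying the full
model's final IRLS weights to both fits — a construction pinned by its
OLS limit: with all weights one it reproduces the textbook nested-model
F exactly, and identical models give F = 0 exactly. Diagnostics:
Shapiro-Wilk on residuals (delegated to the reference routine in
`stats`), the Durbin-Watson statistic, and the Breusch-Pagan test in
its `n R^2` Lagrange-multiplier (studentised) form. Rows with
|standardised residual| above 3 (residual over robust scale) are
flagged as outlier orders. Per-order taxonomist-per-species ratios are
reported to three decimals, and author counts per country are related
to population by Pearson correlation with the usual t-transform
p-value.

**Occurrence agents.** As a complementary supply signal, distinct
`recordedBy` and `identifiedBy` strings are counted per country from
occurrence records, keeping status "PRESENT" (case-insensitive),
dropping records flagged `COUNTRY_COORDINATE_MISMATCH`, and using the
inclusive 2014-2023 window. Strings are compared verbatim apart from
outer whitespace: they are uncontrolled text that may denote a person,
an organisation or an expedition, and no disaggregation is attempted.

## The synthetic-data generator

`generator_config()` fixes the study conditions; all generators draw
from one seed and regenerate byte-identical files. The generator
emulates:

* a backbone with exactly `species_per_order` accepted species per
  order (so richness is known by construction), synonym rows pointing
  at accepted rows, and a fraction of accepted species with family but
  no order rank;
* journals with missing OpenAlex identifiers and duplicate listings
  sharing a Wikidata identifier;
* articles in which every planted taxonomic article passes every
  filter and carries backbone binomials (with abbreviated follow-up
  mentions and non-backbone decoy binomials), while non-taxonomic
  articles fail exactly one filter — a configurable fraction get a
  colliding keyword, which is the corpus filter's planted
  false-positive rate;
* authorship structure in which a fraction of persons appear under two
  identifiers with name variants satisfying rule 1 or rule 2
  preconditions, and planted truncated-name collisions (distinct
  persons, different institutions and orders) that must never merge;
* order-level regression data with `ln(authors + 1) = X beta + eps`:
  120 orders by default, Gaussian noise sigma 0.3, true coefficients
  mirroring the magnitudes reported for the real European harvest
  (richness 0.47, taxonomic-research-needed 0.54, Habitats 0.35, Birds
  0.37, marine -0.27, the rest small), ln-richness uniform on
  (0.7, 9.2) — one to roughly ten thousand species per order — and
  each policy touching an order with probability one half with ln
  counts uniform on (0, 7). Optional contamination adds +4 (ln scale)
  to a stated fraction of responses;
* occurrence records with per-country agent pools and planted
  status/flag/year violations, with ground-truth distinct counts
  tracked over exactly the surviving records.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: real abstracts (noisy OCR,
author citations inside names, genus-only mentions), real name-variant
distributions (transliteration, marriage-related changes, shared exact
names at one institution), citation structure, and realistic journal
metadata. The generator demonstrates correctness of the rules, not
robustness to messiness the rules do not model.

## Numerical and design choices

* Whitespace is normalised before any text matching; backbone names
  are matched case-sensitively, keywords case-insensitively.
* The regression intercept is always included; predictors are never
  standardised (coefficients are on the ln scale). Standardised
  relative importance, if wanted, is a reporting transform, not a
  fitting choice.
* A zero residual scale (exactly interpolating fit) short-circuits the
  IRLS with unit weights; outlier flagging then errors explicitly
  rather than dividing by zero.
* In `run_pipeline()`, predictors with zero variance across orders
  (a policy hitting no order, or a backbone with uniform richness, as
  the synthetic backbone deliberately has) are dropped with a notice
  before fitting; they carry no information and would make the design
  rank deficient.
* The F statistic is clamped at zero (under the full model's weights a
  reduced model can in principle fit fractionally better).
* Rounding of printed percentages is half-up at one decimal, matching
  how policy summaries are typically printed; base `round()`
  half-to-even would differ on exact halves.

Problem sizes used by the test-suite simulations were chosen to make
sampling error negligible relative to the tested tolerances: 100
replicate fits for coefficient recovery and contamination comparisons
(n = 120 orders each), 1,000 replicates for the Breusch-Pagan size
check, and 10,000 residuals for the Durbin-Watson null behaviour.

## Worked example

```{r example, eval = FALSE}
library(taxcap)
cfg <- generator_config(seed = 7)
dir <- file.path(tempdir(), "taxcap-demo")
sim <- simulate_inputs(cfg, dir)

config <- pipeline_config(
  journals = file.path(dir, "journals.tsv"),
  articles = file.path(dir, "articles.jsonl"),
  backbone = file.path(dir, "backbone.tsv"),
  policies = sim$policies$paths,
  occurrences = file.path(dir, "occurrences.tsv"),
  population = file.path(dir, "population.tsv"),
  out_dir = file.path(dir, "out")
)
report <- run_pipeline(config)
report
```

The run report carries per-stage counts (journals deduplicated and
usable; per-filter article removals that always reconcile with the
corpus size; authors before and after disambiguation), the robust fit
with standard errors, the model comparison, diagnostics, flagged
outlier orders, per-order taxonomist-per-species ratios, per-country
agent summaries, and the author-population correlation.

## Known limitations

* Coefficients estimated from a real European harvest are not
  reproducible offline by construction; the package reproduces the
  *method* and its validation arithmetic, not live database state.
* Exact backbone matching misses misspelled or re-combined names; that
  is the documented design (validate-by-backbone), not an oversight.
* Agent strings conflate people, teams and institutions; counts are an
  upper-bound style indicator.
* Rule-based author merging cannot separate two people with identical
  names at the same institution working on the same orders.
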