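#' Default article-selection configuration
#'
#' Configuration driving the taxonomic-article filter: multilingual
#' keyword lists matched in title and abstract, abstract-only keywords
#' (nomenclatural "nov."), taxonomy concept identifiers, the Life
#' Sciences domain identifier, the 2014-2023 publication window, and the
#' set of European ISO 3166-1 alpha-2 country codes (European Political
#' Community members plus the Vatican and European dependencies).
#'
#' The English list carries the seed phrases (taxonomic, taxon,
#' checklist, new/novel species, new genus/genera); other languages hold
#' standard translations. The lists are ordinary character vectors and
#' fully overridable: pass edited copies, or load a YAML file with
#' [read_keyword_config()].
#'
#' @param keywords_by_language named list, language code to phrase vector.
#' @param abstract_only_keywords phrases only matched against abstracts.
#' @param taxonomic_concept_ids concept identifiers counting as taxonomic.
#' @param life_sciences_domain_id the required article domain identifier.
#' @param window_start,window_end inclusive publication-date window.
#' @param european_country_codes ISO alpha-2 codes defining "European".
#' @return a `keyword_config` list.
#' @export
default_keyword_config <- function(
    keywords_by_language = default_keywords(),
    abstract_only_keywords = c("nov."),
    taxonomic_concept_ids = c("C58642233", "C71640776"),
    life_sciences_domain_id = "D1",
    window_start = "2014-01-01",
    window_end = "2023-12-31",
    european_country_codes = european_countries()) {
  stopifnot(as.Date(window_start) <= as.Date(window_end),
            length(european_country_codes) > 0)
  structure(
    list(keywords_by_language = keywords_by_language,
         abstract_only_keywords = abstract_only_keywords,
         taxonomic_concept_ids = taxonomic_concept_ids,
         life_sciences_domain_id = life_sciences_domain_id,
         window_start = window_start,
         window_end = window_end,
         european_country_codes = european_country_codes),
    class = "keyword_config"
  )
}

#' @rdname default_keyword_config
#' @export
default_keywords <- function() {
  list(
    en = c("taxonomic", "taxon", "checklist", "new species", "novel species",
           "new genus", "new genera"),
    bg = c("нов вид", "нов род", "таксономичен"),
    cs = c("nový druh", "nový rod", "taxonomický"),
    fr = c("nouvelle espèce", "nouveau genre", "taxonomique", "taxinomique"),
    de = c("neue Art", "neue Gattung", "taxonomisch"),
    hu = c("új faj", "új nemzetség", "taxonómiai"),
    it = c("nuova specie", "nuovo genere", "tassonomico"),
    pl = c("nowy gatunek", "nowy rodzaj", "taksonomiczny"),
    pt = c("nova espécie", "novo gênero", "novo género", "taxonômico", "taxonómico"),
    ro = c("specie nouă", "gen nou", "taxonomie"),
    ru = c("новый вид", "новый род", "таксономический"),
    es = c("nueva especie", "nuevo género", "taxonómico")
  )
}

#' @rdname default_keyword_config
#' @export
european_countries <- function() {
  c(
    # European Political Community members
    "AL", "AD", "AM", "AT", "AZ", "BE", "BA", "BG", "HR", "CY", "CZ",
    "DK", "EE", "FI", "FR", "GE", "DE", "GR", "HU", "IS", "IE", "IT",
    "XK", "LV", "LI", "LT", "LU", "MT", "MD", "MC", "ME", "NL", "MK",
    "NO", "PL", "PT", "RO", "SM", "RS", "SK", "SI", "ES", "SE", "CH",
    "TR", "UA", "GB",
    # Vatican City and European dependencies/territories
    "VA", "FO", "GI", "GG", "IM", "JE", "AX", "SJ"
  )
}

#' Read or write a keyword configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `keyword_config`.
#' @return `read_keyword_config()` returns a `keyword_config`;
#'   `write_keyword_config()` returns `path` invisibly.
#' @export
read_keyword_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- default_keyword_config()
  for (nm in names(raw)) defaults[[nm]] <- raw[[nm]]
  do.call(default_keyword_config, defaults[names(formals(default_keyword_config))])
}

#' @rdname read_keyword_config
#' @export
write_keyword_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
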