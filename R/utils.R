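#' @importFrom rlang %||%
#' @importFrom stats mad median pchisq pf pnorm rnorm runif rpois sd
#' @importFrom utils combn
NULL

# Collapse internal whitespace runs (incl. non-breaking spaces) to single
# spaces and trim the ends. All text matching in the package happens on
# this normalised form.
normalize_ws <- function(x) {
  x <- gsub("[\\s ]+", " ", x, perl = TRUE)
  trimws(x)
}

tc_log <- function(...) {
  if (isTRUE(getOption("taxcap.verbose", TRUE))) {
    message("[taxcap] ", sprintf(...))
  }
}

# --- minimal union-find over 1..n ------------------------------------------
# Functional style: `parent` is an integer vector; uf_find follows links,
# uf_union links roots. No rank/path-compression: instance sizes here are
# thousands at most and determinism matters more than asymptotics.

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

# --- JSON lines -------------------------------------------------------------

#' Read and write JSON-lines files
#'
#' One JSON object per line, UTF-8. Used for article and author records.
#' Atomic arrays are simplified to vectors on read; objects are kept as
#' named lists (no data-frame simplification), so nested structures such
#' as authorships round-trip as lists of lists.
#'
#' @param path file path.
#' @param records list of records (named lists, possibly nested; data
#'   frames are serialised as arrays of objects).
#' @return `read_jsonl()` returns a list of records; `write_jsonl()`
#'   returns `path` invisibly.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON,
         simplifyVector = TRUE, simplifyDataFrame = FALSE,
         simplifyMatrix = FALSE)
}

#' @rdname read_jsonl
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# Character vector helper: jsonlite deserialises an empty array as list().
as_chr <- function(x) {
  if (is.null(x) || length(x) == 0) character(0) else unlist(x, use.names = FALSE)
}
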