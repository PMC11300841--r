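# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so seeded package
#' operations never perturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 0-based half-open slice of a string: slice0("abcd", 1, 3) == "bc"
slice0 <- function(text, start, end) {
  substr(text, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mirdex <- function(...) stop(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Construct a namespaced concept identifier
#'
#' Concept identifiers are plain strings of the form `"NAMESPACE:accession"`,
#' e.g. `"MIRBASE:MIMAT0000063"` or `"MESH:D004827"`. Namespace-specific
#' accession syntax is validated: miRBase mature accessions match `MIMAT\\d+`,
#' precursor accessions `MI\\d+`, and MeSH descriptors are `D`- or
#' `C`-prefixed.
#'
#' @param namespace one of `"MIRBASE"`, `"MESH"`, `"UMLS"`, `"MONDO"`.
#' @param accession non-empty accession string.
#' @return a single string `"NAMESPACE:accession"`.
#' @examples
#' concept_id("MESH", "D004827")
#' @export
concept_id <- function(namespace, accession) {
  namespace <- match.arg(namespace, c("MIRBASE", "MESH", "UMLS", "MONDO"))
  if (!is_string(accession) || !nzchar(accession)) {
    stop_mirdex("concept accession must be a non-empty string")
  }
  ok <- switch(namespace,
    MIRBASE = grepl("^(MIMAT[0-9]+|MI[0-9]+)$", accession),
    MESH    = grepl("^[DC][0-9]+$", accession),
    UMLS    = grepl("^C[0-9]+$", accession),
    MONDO   = grepl("^MONDO:[0-9]+$|^[0-9]{7}$", accession)
  )
  if (!ok) {
    stop_mirdex("accession '%s' is not valid for namespace %s",
                accession, namespace)
  }
  paste0(namespace, ":", accession)
}

concept_namespace <- function(id) sub(":.*$", "", id)
concept_accession <- function(id) sub("^[^:]+:", "", id)
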