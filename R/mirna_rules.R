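# Rule-based miRNA mention detection and miRBase normalization.
#
# The mention grammar requires a family keyword (miR / mir / miRNA /
# microRNA / let / lin) followed by a number, so bare gene-like symbols
# ("GFAP", "Stat3", "BRCA1") and generic plurals ("miRNAs", "microRNA"
# without a number) never match. Recognized structure:
#
#   [species-]FAMILY[-]NUMBER[letter][-paralog][-5p|-3p][/alt[/alt...]]
#
# e.g. "hsa-miR-501-3p", "let-7b", "microRNA-21-5p", "miR-121-2",
# "miR-200b/c" (an enumeration, split into one mention per alternative).

.mirna_family_re <-
  "(microRNA|MicroRNA|Micro-RNA|MiRNA|miRNA|MiR|miR|mir|Let|let|Lin|lin)"

.mirna_core_re <- paste0(
  "(?:([a-z]{3})-)?",            # 1 species prefix
  .mirna_family_re,              # 2 family keyword
  "[- ]?",
  "([0-9]+)",                    # 3 number
  "([a-z]{1,2})?",               # 4 letter suffix
  "(?:-([0-9]+)(?![0-9]*p))?",   # 5 paralog index (never the arm digits)
  "(?:-(5p|3p))?"                # 6 arm
)

.mirna_mention_re <- paste0(
  "(?<![A-Za-z0-9])", .mirna_core_re,
  "((?:/[A-Za-z0-9]+)*)",        # 7 enumeration tail, e.g. "/c" or "/16"
  "(?![A-Za-z0-9])"
)

#' Detect miRNA mentions in a sentence
#'
#' Applies the rule grammar above and returns non-overlapping mentions of
#' class `"mirna"`. Enumerations such as `"miR-200b/c"` yield one mention per
#' alternative: the first covers the full stem (`"miR-200b"`), each further
#' alternative covers its own token (`"c"`) and carries the expanded name
#' (`"miR-200c"`) in the mention attribute `"resolved_name"`, which the
#' normalizer consults.
#'
#' @param sentence_text a single string.
#' @return list of [mention()] objects ordered by start offset (possibly
#'   empty).
#' @examples
#' detect_mirna_mentions("Overexpression of let-7b inhibited activation.")
#' @export
detect_mirna_mentions <- function(sentence_text) {
  stopifnot(is_string(sentence_text))
  if (!nzchar(sentence_text)) return(list())
  m <- gregexpr(.mirna_mention_re, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  out <- list()
  for (i in seq_along(m)) {
    s1 <- m[i]                                # 1-based start
    len <- attr(m, "match.length")[i]
    surface <- substr(sentence_text, s1, s1 + len - 1L)
    tail_m <- regexpr("(?:/[A-Za-z0-9]+)+$", surface, perl = TRUE)
    if (tail_m == -1L) {
      out[[length(out) + 1L]] <-
        mention(s1 - 1L, s1 - 1L + len, surface, "mirna")
      next
    }
    stem <- substr(surface, 1L, tail_m - 1L)
    stem_m <- mention(s1 - 1L, s1 - 1L + nchar(stem), stem, "mirna")
    out[[length(out) + 1L]] <- stem_m
    parts <- parse_mirna_name(stem)
    alts <- strsplit(substr(surface, tail_m + 1L, nchar(surface)), "/")[[1]]
    cursor <- s1 - 1L + nchar(stem)           # 0-based, at "/"
    for (alt in alts) {
      a0 <- cursor + 1L                       # skip "/"
      a1 <- a0 + nchar(alt)
      cursor <- a1
      resolved <- expand_enumeration_alt(parts, alt)
      if (is.null(resolved)) next             # unparseable alternative
      alt_m <- mention(a0, a1, alt, "mirna")
      attr(alt_m, "resolved_name") <- resolved
      out[[length(out) + 1L]] <- alt_m
    }
  }
  out
}

# "miR-200b" + "c" -> "miR-200c"; "miR-15a" + "16" -> "miR-16"
expand_enumeration_alt <- function(stem_parts, alt) {
  if (is.null(stem_parts)) return(NULL)
  p <- stem_parts
  if (grepl("^[a-z]{1,2}$", alt)) {
    p$letter_suffix <- alt
  } else if (grepl("^[0-9]+[a-z]{0,2}$", alt)) {
    p$number <- as.integer(sub("[a-z]*$", "", alt))
    suf <- sub("^[0-9]+", "", alt)
    p$letter_suffix <- if (nzchar(suf)) suf else NA_character_
  } else {
    return(NULL)
  }
  p$paralog_index <- NA_integer_
  serialize_mirna_name(p)
}

#' Parse a miRNA surface form into its name parts
#'
#' @param surface a string matched by the mention grammar.
#' @return a list of class `mirna_name_parts` with elements
#'   `species_prefix`, `family` (`"miR"`, `"let"` or `"lin"`; all
#'   miR/miRNA/microRNA spellings collapse to `"miR"`), `number`,
#'   `letter_suffix`, `paralog_index`, `arm` (`"5p"`, `"3p"` or
#'   `"unspecified"`) and `precursor_flag` (`TRUE` for the lowercase
#'   `"mir-"` precursor spelling) — or `NULL` if the surface does not match
#'   the grammar.
#' @examples
#' parse_mirna_name("hsa-miR-501-3p")
#' @export
parse_mirna_name <- function(surface) {
  if (!is_string(surface)) return(NULL)
  re <- paste0("^", .mirna_core_re, "$")
  m <- regexec(re, surface, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  g <- regmatches(surface, list(m))[[1]]  # full match + 6 groups
  fam_raw <- g[3]
  family <- if (tolower(substr(fam_raw, 1, 3)) %in% c("let")) "let"
            else if (tolower(substr(fam_raw, 1, 3)) %in% c("lin")) "lin"
            else "miR"
  structure(list(
    species_prefix = if (nzchar(g[2])) g[2] else NA_character_,
    family = family,
    number = as.integer(g[4]),
    letter_suffix = if (nzchar(g[5])) g[5] else NA_character_,
    paralog_index = if (nzchar(g[6])) as.integer(g[6]) else NA_integer_,
    arm = if (nzchar(g[7])) g[7] else "unspecified",
    precursor_flag = identical(fam_raw, "mir")
  ), class = "mirna_name_parts")
}

#' Serialize miRNA name parts to the canonical name
#'
#' Inverse of [parse_mirna_name()] on canonical names:
#' `serialize_mirna_name(parse_mirna_name(x)) == x` whenever `x` is a
#' canonical miRBase-style name such as `"hsa-miR-501-3p"`.
#'
#' @param parts a `mirna_name_parts` list.
#' @return canonical name string.
#' @export
serialize_mirna_name <- function(parts) {
  fam <- if (parts$family == "miR") {
    if (isTRUE(parts$precursor_flag)) "mir" else "miR"
  } else parts$family
  paste0(
    if (!is.na(parts$species_prefix)) paste0(parts$species_prefix, "-") else "",
    fam, "-", parts$number,
    if (!is.na(parts$letter_suffix)) parts$letter_suffix else "",
    if (!is.na(parts$paralog_index)) paste0("-", parts$paralog_index) else "",
    if (parts$arm != "unspecified") paste0("-", parts$arm) else ""
  )
}

#' Load a miRBase-style name/accession lexicon
#'
#' @param path TSV with header columns `canonical_name`, `accession`,
#'   `type` (`mature` or `precursor`). Mature accessions are `MIMAT`-,
#'   precursor accessions `MI`-prefixed. Name lookups are case-insensitive;
#'   accessions keep their case. Duplicate names mapping to conflicting
#'   accessions raise an error.
#' @return an object of class `mirbase_lexicon`.
#' @export
load_mirbase_lexicon <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  need <- c("canonical_name", "accession", "type")
  if (!all(need %in% names(df))) {
    stop_mirdex("lexicon TSV needs columns: %s", paste(need, collapse = ", "))
  }
  mirbase_lexicon(df)
}

#' Build a miRBase lexicon from a data frame
#'
#' @param df data frame with `canonical_name`, `accession`, `type` columns.
#' @return `mirbase_lexicon` object with case-folded name keys.
#' @export
mirbase_lexicon <- function(df) {
  if (!all(df$type %in% c("mature", "precursor"))) {
    stop_mirdex("lexicon type column must be 'mature' or 'precursor'")
  }
  bad <- !ifelse(df$type == "mature",
                 grepl("^MIMAT[0-9]+$", df$accession),
                 grepl("^MI[0-9]+$", df$accession))
  if (any(bad)) {
    stop_mirdex("accession '%s' invalid for type '%s'",
                df$accession[bad][1], df$type[bad][1])
  }
  key <- tolower(df$canonical_name)
  for (k in unique(key[duplicated(key)])) {
    accs <- unique(df$accession[key == k])
    if (length(accs) > 1L) {
      stop_mirdex("conflicting accessions for name '%s': %s",
                  df$canonical_name[key == k][1],
                  paste(accs, collapse = ", "))
    }
  }
  keep <- !duplicated(key)
  structure(list(
    mature = stats::setNames(df$accession[df$type == "mature" & keep],
                             key[df$type == "mature" & keep]),
    precursor = stats::setNames(df$accession[df$type == "precursor" & keep],
                                key[df$type == "precursor" & keep]),
    table = df[keep, c("canonical_name", "accession", "type")]
  ), class = "mirbase_lexicon")
}

#' @export
print.mirbase_lexicon <- function(x, ...) {
  cat(sprintf("<mirbase_lexicon: %d mature, %d precursor name(s)>\n",
              length(x$mature), length(x$precursor)))
  invisible(x)
}

#' Normalize parsed miRNA name parts to miRBase accessions
#'
#' Pure rule-based linking. The species prefix defaults to
#' `species_context` when the mention has none. A lowercase `"mir-"`
#' spelling is first looked up among precursors (`MI` accession) and falls
#' through to the mature table. Mentions without an arm suffix resolve to the
#' armless mature name when the lexicon has one; otherwise to the `-5p`
#' mature by default (`arm_policy = "5p"`), or to every available arm with
#' `arm_policy = "both"`. Unknown names yield an empty vector, never a
#' guess.
#'
#' @param parts `mirna_name_parts` (from [parse_mirna_name()]) or a surface
#'   string, parsed on the fly.
#' @param lexicon a `mirbase_lexicon`.
#' @param species_context default species prefix (default `"hsa"`, human).
#' @param arm_policy `"5p"` (default) or `"both"`.
#' @return character vector of `"MIRBASE:<accession>"` concept ids.
#' @examples
#' lex <- generate_lexicons()$mirbase
#' normalize_to_mirbase("let-7b", lex)
#' @export
normalize_to_mirbase <- function(parts, lexicon, species_context = "hsa",
                                 arm_policy = c("5p", "both")) {
  arm_policy <- match.arg(arm_policy)
  if (is.character(parts)) parts <- parse_mirna_name(parts)
  if (is.null(parts)) return(character())
  if (is.na(parts$species_prefix)) parts$species_prefix <- species_context
  stem <- local({
    p <- parts; p$arm <- "unspecified"; p$precursor_flag <- FALSE
    serialize_mirna_name(p)
  })
  hit <- function(tab, name) {
    acc <- unname(tab[tolower(name)])
    if (length(acc) == 0L || is.na(acc)) NULL else acc
  }
  if (isTRUE(parts$precursor_flag)) {
    pre_name <- sub("-miR-", "-mir-", stem, fixed = TRUE)
    acc <- hit(lexicon$precursor, pre_name)
    if (!is.null(acc)) return(concept_id("MIRBASE", acc))
  }
  if (parts$arm != "unspecified") {
    acc <- hit(lexicon$mature, paste0(stem, "-", parts$arm))
    return(if (is.null(acc)) character() else concept_id("MIRBASE", acc))
  }
  acc <- hit(lexicon$mature, stem)
  if (!is.null(acc)) return(concept_id("MIRBASE", acc))
  acc5 <- hit(lexicon$mature, paste0(stem, "-5p"))
  acc3 <- hit(lexicon$mature, paste0(stem, "-3p"))
  if (arm_policy == "both") {
    accs <- c(acc5, acc3)
    return(if (is.null(accs)) character()
           else vapply(accs, concept_id, character(1),
                       namespace = "MIRBASE", USE.NAMES = FALSE))
  }
  if (!is.null(acc5)) return(concept_id("MIRBASE", acc5))
  if (!is.null(acc3)) return(concept_id("MIRBASE", acc3))
  character()
}

#' Detect and normalize miRNA mentions in one step
#'
#' Convenience wrapper: [detect_mirna_mentions()] followed by
#' [normalize_to_mirbase()] on each mention (honoring enumeration
#' expansions), filling the mention `ids` field.
#'
#' @inheritParams detect_mirna_mentions
#' @inheritParams normalize_to_mirbase
#' @return list of mentions with `ids` populated (empty for unmapped names).
#' @export
annotate_mirna <- function(sentence_text, lexicon, species_context = "hsa",
                           arm_policy = c("5p", "both")) {
  arm_policy <- match.arg(arm_policy)
  lapply(detect_mirna_mentions(sentence_text), function(m) {
    name <- attr(m, "resolved_name") %||% m$surface
    m$ids <- normalize_to_mirbase(name, lexicon, species_context, arm_policy)
    m
  })
}
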