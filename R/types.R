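# Core document model: documents, sentences, typed entity mentions.
# All character offsets everywhere in the package are 0-based and half-open;
# mention offsets are relative to their sentence.

#' Create an entity mention
#'
#' A typed text span inside a sentence. Offsets are 0-based, half-open and
#' sentence-relative; `surface` must equal the corresponding slice of the
#' sentence text (checked by [sentence()] and by every corpus reader).
#'
#' @param start,end integer character offsets, `0 <= start < end`.
#' @param surface the mention text.
#' @param entity_class `"mirna"` or `"disease"`.
#' @param ids character vector of normalized concept ids
#'   (see [concept_id()]); empty when the mention is unlinked.
#' @return an object of class `mdx_mention`.
#' @examples
#' mention(0, 6, "miR-21", "mirna")
#' @export
mention <- function(start, end, surface, entity_class,
                    ids = character()) {
  entity_class <- match.arg(entity_class, c("mirna", "disease"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop_mirdex("mention offsets must satisfy 0 <= start < end (got %s, %s)",
                start, end)
  }
  structure(
    list(start = start, end = end, surface = surface,
         entity_class = entity_class, ids = as.character(ids)),
    class = "mdx_mention"
  )
}

#' Create a sentence
#'
#' @param text sentence text.
#' @param start 0-based offset of the sentence within its document.
#' @param mentions list of [mention()] objects; offsets are validated against
#'   `text` and mentions of the same class must not overlap.
#' @return an object of class `mdx_sentence`.
#' @export
sentence <- function(text, start = 0L, mentions = list()) {
  stopifnot(is_string(text))
  s <- structure(
    list(text = text, start = as.integer(start), mentions = mentions),
    class = "mdx_sentence"
  )
  validate_sentence(s)
  s
}

validate_sentence <- function(s) {
  n <- nchar(s$text)
  for (m in s$mentions) {
    if (m$end > n) {
      stop_mirdex("mention [%d,%d) exceeds sentence length %d",
                  m$start, m$end, n)
    }
    slice <- slice0(s$text, m$start, m$end)
    if (!identical(slice, m$surface)) {
      stop_mirdex(
        "mention surface '%s' does not match sentence slice '%s' at [%d,%d)",
        m$surface, slice, m$start, m$end)
    }
  }
  for (cls in c("mirna", "disease")) {
    ms <- Filter(function(m) m$entity_class == cls, s$mentions)
    if (length(ms) > 1L) {
      ord <- order(vapply(ms, `[[`, integer(1), "start"))
      ms <- ms[ord]
      for (i in seq_len(length(ms) - 1L)) {
        if (ms[[i + 1L]]$start < ms[[i]]$end) {
          stop_mirdex("overlapping %s mentions at [%d,%d) and [%d,%d)",
                      cls, ms[[i]]$start, ms[[i]]$end,
                      ms[[i + 1L]]$start, ms[[i + 1L]]$end)
        }
      }
    }
  }
  invisible(s)
}

#' Create a document
#'
#' @param doc_id non-empty identifier (typically a PMID or PMC id).
#' @param text full document text.
#' @param sentences list of [sentence()] objects; spans must be ordered,
#'   non-overlapping and lie within `text`. When `NULL`, the text is
#'   segmented with [split_sentences()].
#' @param source one of `"pubmed_abstract"`, `"pmc_fulltext"`, `"other"`.
#' @return an object of class `mdx_document`.
#' @examples
#' document("123", "miR-21 is upregulated in glioma. It is a biomarker.")
#' @export
document <- function(doc_id, text, sentences = NULL,
                     source = c("other", "pubmed_abstract", "pmc_fulltext")) {
  source <- match.arg(source)
  if (!is_string(doc_id) || !nzchar(doc_id)) {
    stop_mirdex("doc_id must be a non-empty string")
  }
  if (is.null(sentences)) sentences <- split_sentences(text)
  d <- structure(
    list(doc_id = doc_id, source = source, text = text,
         sentences = sentences),
    class = "mdx_document"
  )
  validate_document(d)
  d
}

validate_document <- function(d) {
  prev_end <- 0L
  for (s in d$sentences) {
    validate_sentence(s)
    s_end <- s$start + nchar(s$text)
    if (s$start < prev_end || s_end > nchar(d$text)) {
      stop_mirdex("sentence span [%d,%d) out of order or out of bounds",
                  s$start, s_end)
    }
    if (!identical(slice0(d$text, s$start, s_end), s$text)) {
      stop_mirdex("sentence text does not match document slice at offset %d",
                  s$start)
    }
    prev_end <- s_end
  }
  invisible(d)
}

#' @export
print.mdx_document <- function(x, ...) {
  cat(sprintf("<document %s (%s): %d sentence(s), %d char>\n",
              x$doc_id, x$source, length(x$sentences), nchar(x$text)))
  invisible(x)
}

#' @export
print.mdx_mention <- function(x, ...) {
  ids <- if (length(x$ids)) paste(x$ids, collapse = ",") else "-"
  cat(sprintf("<%s [%d,%d) '%s' %s>\n",
              x$entity_class, x$start, x$end, x$surface, ids))
  invisible(x)
}

# mentions of one class in a sentence, ordered by start
mentions_of <- function(s, cls) {
  ms <- Filter(function(m) m$entity_class == cls, s$mentions)
  if (length(ms) > 1L) ms <- ms[order(vapply(ms, `[[`, integer(1), "start"))]
  ms
}
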