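# Rule-based sentence segmentation.
#
# Boundary rule: a run of [.?!] followed by whitespace ends a sentence unless
# the token immediately before it is a known abbreviation, or the next
# non-space character does not start a new sentence (uppercase letter, digit
# or opening bracket/quote). Decimal points never qualify because they are
# not followed by whitespace.

.abbrev_blacklist <- c(
  "Fig", "Figs", "Eq", "Eqs", "Ref", "Refs", "Tab", "No", "no",
  "al", "e.g", "i.e", "cf", "ca", "vs", "etc", "approx",
  "Dr", "Prof", "St", "Mr", "Mrs", "Ms",
  "sp", "spp", "subsp", "var", "str"
)

#' Split text into sentences
#'
#' Rule-based splitter used by [read_documents()] and [document()]. The rule
#' set (sentence-final punctuation plus an abbreviation blacklist including
#' `"Fig."`, `"et al."` and species-style abbreviations) is deliberately
#' simple and pluggable: any function `text -> list of` [sentence()] can be
#' passed wherever a splitter is accepted.
#'
#' @param text a single string.
#' @return list of [sentence()] objects with document-relative `start`
#'   offsets (0-based).
#' @examples
#' length(split_sentences("miR-21 rises in glioma. See Fig. 2 for details."))
#' @export
split_sentences <- function(text) {
  stopifnot(is_string(text))
  if (!nzchar(trimws(text))) return(list())
  n <- nchar(text)
  # candidate boundaries: sentence punctuation followed by whitespace
  m <- gregexpr("[.?!]+(?=[ \t\r\n])", text, perl = TRUE)[[1]]
  ends <- integer()  # 0-based half-open end of each sentence (incl. punct)
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      punct_start <- m[i]                       # 1-based
      punct_len <- attr(m, "match.length")[i]
      before <- substr(text, 1L, punct_start - 1L)
      word <- regmatches(before,
                         regexpr("[A-Za-z.]+$", before, perl = TRUE))
      if (length(word) == 1L && word %in% .abbrev_blacklist) next
      # single capital letter before "." is an initial ("J. Smith")
      if (length(word) == 1L && grepl("^[A-Z]$", word)) next
      rest <- substr(text, punct_start + punct_len, n)
      nxt <- regmatches(rest, regexpr("[^ \t\r\n]", rest, perl = TRUE))
      nxt_word <- regmatches(rest,
                             regexpr("[^ \t\r\n]+", rest, perl = TRUE))
      # a new sentence starts with a capital, digit, bracket/quote, or a
      # lowercase miRNA-style token ("miR-21 was ...", "let-7b levels ...")
      mirna_start <- length(nxt_word) == 1L &&
        grepl("^(?:[a-z]{3}-)?(?:miR|mir|let|lin|miRNA|microRNA)[- ]?[0-9]",
              nxt_word, perl = TRUE)
      if (length(nxt) == 1L && !grepl("[A-Z0-9([\"']", nxt) &&
          !mirna_start) next
      ends <- c(ends, punct_start + punct_len - 1L)  # 0-based end
    }
  }
  if (grepl("[^ \t\r\n]", substr(text,
                                 if (length(ends)) max(ends) + 1L else 1L,
                                 n))) {
    # trailing material forms the final sentence
    last_char <- max(gregexpr("[^ \t\r\n]", text)[[1]])
    ends <- c(ends, last_char)
  }
  out <- list()
  cursor <- 0L
  for (e in ends) {
    seg <- slice0(text, cursor, e)
    lead <- nchar(seg) - nchar(sub("^[ \t\r\n]+", "", seg))
    start <- cursor + lead
    out[[length(out) + 1L]] <- sentence(slice0(text, start, e), start = start)
    cursor <- e
  }
  out
}
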