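# Model-based NER over IOB labels, plus the dictionary MeSH disease linker.
#
# IOB conventions: "O" outside, "B-<class>" first token of an entity,
# "I-<class>" continuation. Decoding is total: an "I-" with no legal
# predecessor is repaired to "B-" (the repair is also applied to model
# predictions so emitted sequences are always legal).

#' Construct a tagged sentence
#'
#' Parallel token/label vectors with per-token character spans. When `text`
#' is not supplied it is reconstructed by joining tokens with single spaces
#' (the convention used for IOB files, which carry no character offsets).
#'
#' @param tokens character vector.
#' @param labels parallel IOB label vector.
#' @param text original sentence text, or `NULL` to reconstruct.
#' @param spans `n x 2` matrix of 0-based half-open token offsets, or `NULL`.
#' @return object of class `mdx_tagged`.
#' @export
tagged_sentence <- function(tokens, labels, text = NULL, spans = NULL) {
  if (length(tokens) != length(labels)) {
    stop_mirdex("tokens and labels must have equal length")
  }
  if (is.null(text)) {
    text <- paste(tokens, collapse = " ")
    if (is.null(spans)) {
      ends <- cumsum(nchar(tokens) + 1L) - 1L
      spans <- cbind(ends - nchar(tokens), ends)
    }
  }
  structure(list(tokens = tokens, labels = labels, text = text,
                 char_spans = spans),
            class = "mdx_tagged")
}

#' @export
print.mdx_tagged <- function(x, ...) {
  cat(paste(x$tokens, x$labels, sep = "/", collapse = " "), "\n")
  invisible(x)
}

#' Encode sentence mentions as IOB token labels
#'
#' The first token overlapping a mention receives `B-<class>`, subsequent
#' overlapping tokens `I-<class>`, all others `O`. Two adjacent same-class
#' mentions produce `B-x B-x`, never an `I-` bridge. A mention whose
#' boundaries fall inside a token is aligned to the covering tokens with a
#' warning (never dropped silently).
#'
#' @param s a [sentence()] object.
#' @param mentions mentions to encode (default: the sentence's own).
#' @param tokenizer tokenization function returning `tokens` and `spans`
#'   (default [word_tokenize()]).
#' @return a [tagged_sentence()].
#' @export
iob_encode <- function(s, mentions = s$mentions, tokenizer = word_tokenize) {
  tk <- tokenizer(s$text)
  labels <- rep("O", length(tk$tokens))
  for (m in mentions) {
    overlap <- which(tk$spans[, 1] < m$end & tk$spans[, 2] > m$start)
    if (!length(overlap)) {
      warning(sprintf("mention '%s' [%d,%d) covers no token", m$surface,
                      m$start, m$end), call. = FALSE)
      next
    }
    if (tk$spans[overlap[1], 1] != m$start ||
        tk$spans[overlap[length(overlap)], 2] != m$end) {
      warning(sprintf(
        "mention '%s' [%d,%d) not aligned to token boundaries; widened",
        m$surface, m$start, m$end), call. = FALSE)
    }
    labels[overlap[1]] <- paste0("B-", m$entity_class)
    if (length(overlap) > 1L) {
      labels[overlap[-1]] <- paste0("I-", m$entity_class)
    }
  }
  tagged_sentence(tk$tokens, labels, text = s$text, spans = tk$spans)
}

# promote illegal "I-x" (after O, start, or a different class) to "B-x"
repair_iob <- function(labels) {
  prev <- "O"
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (startsWith(lab, "I-")) {
      cls <- substring(lab, 3L)
      if (!(prev %in% paste0(c("B-", "I-"), cls))) {
        labels[i] <- paste0("B-", cls)
      }
    }
    prev <- labels[i]
  }
  labels
}

#' Decode IOB labels back to entity mentions
#'
#' Total (never fails): illegal `I-` labels are repaired to `B-` first, then
#' maximal `B-x I-x*` runs become mentions spanning from the first to the
#' last token of the run. On legal input this is the exact inverse of
#' [iob_encode()].
#'
#' @param tagged a [tagged_sentence()].
#' @return list of [mention()] objects.
#' @export
iob_decode <- function(tagged) {
  labels <- repair_iob(tagged$labels)
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (startsWith(labels[i], "B-")) {
      cls <- substring(labels[i], 3L)
      j <- i
      while (j < n && identical(labels[j + 1L], paste0("I-", cls))) {
        j <- j + 1L
      }
      s0 <- tagged$char_spans[i, 1]
      e0 <- tagged$char_spans[j, 2]
      out[[length(out) + 1L]] <-
        mention(s0, e0, slice0(tagged$text, s0, e0), cls)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Align token-level IOB labels to a subtoken sequence
#'
#' The first subtoken of every token carries the token's label; continuation
#' subtokens carry the ignore mark `"IGNORE"` and are excluded from the
#' training loss and from decoding.
#'
#' @param tagged a [tagged_sentence()].
#' @param sub_map list (one element per token) of subtoken character
#'   vectors, e.g. from [subtoken_map()].
#' @return list with `subtokens`, `labels` (including `"IGNORE"`),
#'   `token_index` (integer map back to tokens) and `is_first` (logical).
#' @export
align_to_subtokens <- function(tagged, sub_map) {
  if (length(sub_map) != length(tagged$tokens)) {
    stop_mirdex("subtoken map length (%d) != token count (%d)",
                length(sub_map), length(tagged$tokens))
  }
  lens <- lengths(sub_map)
  if (any(lens == 0L)) {
    stop_mirdex("token '%s' produced zero subtokens",
                tagged$tokens[which(lens == 0L)[1]])
  }
  labels <- unlist(mapply(function(lab, k) c(lab, rep("IGNORE", k - 1L)),
                          tagged$labels, lens, SIMPLIFY = FALSE),
                   use.names = FALSE)
  list(subtokens = unlist(sub_map, use.names = FALSE),
       labels = labels,
       token_index = rep(seq_along(sub_map), lens),
       is_first = !duplicated(rep(seq_along(sub_map), lens)))
}

#' Project subtoken-level labels back to tokens
#'
#' Inverse of [align_to_subtokens()] after prediction: the label of each
#' token is the label at its first subtoken.
#'
#' @param sub_labels subtoken-level label vector.
#' @param alignment the list returned by [align_to_subtokens()].
#' @return per-token label vector of the original token count.
#' @export
project_to_tokens <- function(sub_labels, alignment) {
  sub_labels[alignment$is_first]
}

# ---- trainable tagger -------------------------------------------------

prepare_tagging_instance <- function(tagged, label_set, config) {
  al <- align_to_subtokens(tagged, subtoken_map(tagged$tokens))
  ids <- subtoken_ids(al$subtokens, config$vocab_size)
  y <- match(al$labels, label_set)     # NA for IGNORE
  truncated <- length(ids) > config$max_length
  if (truncated) {
    keep <- seq_len(config$max_length)
    ids <- ids[keep]; y <- y[keep]
    al$is_first <- al$is_first[keep]
  }
  list(ids = ids, y = y, alignment = al, truncated = truncated)
}

#' Train an IOB sequence tagger
#'
#' Fine-tunes the small encoder with a single linear layer per-subtoken
#' softmax head. Loss is cross-entropy over labeled (non-`IGNORE`) subtoken
#' positions only, so training is invariant to the labels at ignored
#' positions. Fully deterministic for a fixed `config$seed`; with
#' `epochs = 0` the randomly initialized tagger is returned untrained.
#'
#' @param train_sentences list of [tagged_sentence()] objects (non-empty).
#' @param val_sentences optional validation sentences; labels must be a
#'   subset of the training label set.
#' @param config an [tiny_encoder_config()] list.
#' @return object of class `mdx_tagger` exposing [predict_tags()].
#' @export
train_tagger <- function(train_sentences, val_sentences = NULL,
                         config = tiny_encoder_config()) {
  if (!length(train_sentences)) stop_mirdex("empty training set")
  label_set <- sort(unique(unlist(lapply(train_sentences, `[[`, "labels"))))
  label_set <- c("O", setdiff(label_set, "O"))
  if (!is.null(val_sentences)) {
    val_labs <- unique(unlist(lapply(val_sentences, `[[`, "labels")))
    extra <- setdiff(val_labs, label_set)
    if (length(extra)) {
      stop_mirdex("validation label(s) absent from training set: %s",
                  paste(extra, collapse = ", "))
    }
  }
  L <- length(label_set)
  with_seed(config$seed, {
    enc <- encoder_init(config)
    head <- list(
      Wt = matrix(stats::rnorm(L * config$out_dim, sd = 0.2), L,
                  config$out_dim),
      bt = numeric(L)
    )
    prep <- lapply(train_sentences, prepare_tagging_instance,
                   label_set = label_set, config = config)
    opt_enc <- adam_init(enc$params)
    opt_head <- adam_init(head)
    n <- length(prep)
    bs <- max(1L, config$batch_size)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      for (b0 in seq(1L, n, by = bs)) {
        batch <- perm[b0:min(b0 + bs - 1L, n)]
        g_enc <- zero_grads(enc$params)
        g_head <- zero_grads(head)
        n_lab <- sum(vapply(prep[batch],
                            function(p) sum(!is.na(p$y)), integer(1)))
        if (n_lab == 0L) next
        for (k in batch) {
          p <- prep[[k]]
          fw <- encoder_forward(enc, p$ids)
          logits <- sweep(fw$Z %*% t(head$Wt), 2L, head$bt, `+`)
          P <- softmax(logits)
          mask <- !is.na(p$y)
          dlog <- P
          dlog[cbind(which(mask), p$y[mask])] <-
            dlog[cbind(which(mask), p$y[mask])] - 1
          dlog[!mask, ] <- 0
          dlog <- dlog / n_lab
          g_head$Wt <- g_head$Wt + t(dlog) %*% fw$Z
          g_head$bt <- g_head$bt + colSums(dlog)
          dZ <- dlog %*% head$Wt
          g_enc <- encoder_backward(enc, fw$cache, dZ, g_enc)
        }
        st <- adam_step(enc$params, g_enc, opt_enc, config$learning_rate)
        enc$params <- st$params; opt_enc <- st$state
        st <- adam_step(head, g_head, opt_head, config$learning_rate)
        head <- st$params; opt_head <- st$state
      }
    }
    structure(list(encoder = enc, head = head, label_set = label_set,
                   config = config),
              class = "mdx_tagger")
  })
}

#' Predict IOB tags for sentences
#'
#' @param tagger an `mdx_tagger` from [train_tagger()].
#' @param sentences list of [sentence()] objects, character strings, or
#'   [tagged_sentence()] objects (whose tokenization is reused).
#' @return list of [tagged_sentence()] objects with legal (repaired) IOB
#'   labels; the number of truncated sentences is attached as attribute
#'   `n_truncated` and reported with a warning when positive.
#' @export
predict_tags <- function(tagger, sentences) {
  config <- tagger$config
  n_trunc <- 0L
  out <- lapply(sentences, function(s) {
    tg <- if (inherits(s, "mdx_tagged")) {
      s
    } else {
      txt <- if (inherits(s, "mdx_sentence")) s$text else s
      tk <- word_tokenize(txt)
      tagged_sentence(tk$tokens, rep("O", length(tk$tokens)),
                      text = txt, spans = tk$spans)
    }
    if (!length(tg$tokens)) {
      return(tagged_sentence(character(), character(),
                             text = tg$text,
                             spans = matrix(integer(), ncol = 2)))
    }
    p <- prepare_tagging_instance(tg, tagger$label_set, config)
    if (p$truncated) n_trunc <<- n_trunc + 1L
    fw <- encoder_forward(tagger$encoder, p$ids)
    logits <- sweep(fw$Z %*% t(tagger$head$Wt), 2L, tagger$head$bt, `+`)
    sub_labels <- tagger$label_set[max.col(logits, ties.method = "first")]
    tok_labels <- sub_labels[p$alignment$is_first]
    labels <- rep("O", length(tg$tokens))
    labels[seq_along(tok_labels)] <- tok_labels
    tagged_sentence(tg$tokens, repair_iob(labels),
                    text = tg$text, spans = tg$char_spans)
  })
  if (n_trunc > 0L) {
    warning(sprintf("%d sentence(s) exceeded max_length and were truncated",
                    n_trunc), call. = FALSE)
  }
  attr(out, "n_truncated") <- n_trunc
  out
}

# ---- dictionary MeSH disease linking ----------------------------------

fold_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Build a MeSH disease lexicon
#'
#' @param df data frame with columns `term`, `mesh_id` (`D`/`C`-prefixed
#'   descriptor ids). Term keys are case- and punctuation-folded; folding is
#'   idempotent.
#' @return object of class `mesh_lexicon`.
#' @export
mesh_lexicon <- function(df) {
  if (!all(c("term", "mesh_id") %in% names(df))) {
    stop_mirdex("MeSH lexicon needs columns term, mesh_id")
  }
  bad <- !grepl("^[DC][0-9]+$", df$mesh_id)
  if (any(bad)) stop_mirdex("invalid MeSH id '%s'", df$mesh_id[bad][1])
  keys <- fold_term(df$term)
  keep <- !duplicated(keys)
  structure(list(terms = stats::setNames(df$mesh_id[keep], keys[keep]),
                 max_words = max(c(1L, lengths(strsplit(keys, " "))))),
            class = "mesh_lexicon")
}

#' Load a MeSH disease lexicon from TSV
#'
#' @param path TSV with header columns `term`, `mesh_id`.
#' @return a `mesh_lexicon`.
#' @export
load_mesh_lexicon <- function(path) {
  mesh_lexicon(utils::read.delim(path, sep = "\t", quote = "",
                                 header = TRUE, colClasses = "character",
                                 encoding = "UTF-8"))
}

#' @export
print.mesh_lexicon <- function(x, ...) {
  cat(sprintf("<mesh_lexicon: %d folded term(s)>\n", length(x$terms)))
  invisible(x)
}

mesh_lookup <- function(lexicon, term) {
  id <- unname(lexicon$terms[fold_term(term)])
  if (length(id) == 0L || is.na(id)) character()
  else concept_id("MESH", id)
}

# abbreviation table from "long form (ABBR)" definitions in a document:
# returns named vector ABBR -> MESH:... for long forms found in the lexicon
abbreviation_table <- function(text, lexicon) {
  m <- gregexpr("\\(([A-Z]{2,8}s?)\\)", text, perl = TRUE)[[1]]
  tab <- character()
  if (m[1] == -1L) return(tab)
  for (i in seq_along(m)) {
    abbr <- gsub("[()]", "", substr(text, m[i],
                                    m[i] + attr(m, "match.length")[i] - 1L))
    before <- substr(text, 1L, m[i] - 1L)
    words <- regmatches(before,
                        gregexpr("[A-Za-z][A-Za-z'-]*", before))[[1]]
    k <- min(length(words), nchar(sub("s$", "", abbr)) + 2L)
    if (k == 0L) next
    tail_words <- utils::tail(words, k)
    for (j in seq_along(tail_words)) {
      cand <- paste(tail_words[j:length(tail_words)], collapse = " ")
      id <- mesh_lookup(lexicon, cand)
      if (length(id)) { tab[abbr] <- id; break }
    }
  }
  tab
}

#' Detect disease mentions with a dictionary
#'
#' Greedy longest-match scan of token n-grams against the folded MeSH
#' lexicon. Abbreviations defined earlier in the same document via the
#' `"long form (ABBR)"` pattern are also recognized when `context_text` is
#' supplied.
#'
#' @param sentence_text sentence to scan.
#' @param lexicon a `mesh_lexicon`.
#' @param context_text optional full document text used to resolve local
#'   abbreviation definitions.
#' @return list of disease [mention()]s with `ids` populated.
#' @export
detect_disease_mentions <- function(sentence_text, lexicon,
                                    context_text = NULL) {
  tk <- word_tokenize(sentence_text)
  n <- length(tk$tokens)
  if (n == 0L) return(list())
  abbr <- if (is.null(context_text)) character()
          else abbreviation_table(context_text, lexicon)
  out <- list()
  i <- 1L
  max_n <- min(lexicon$max_words, 6L)
  while (i <= n) {
    hit_len <- 0L; hit_ids <- character()
    for (len in rev(seq_len(min(max_n, n - i + 1L)))) {
      s0 <- tk$spans[i, 1]; e0 <- tk$spans[i + len - 1L, 2]
      surf <- slice0(sentence_text, s0, e0)
      ids <- mesh_lookup(lexicon, surf)
      if (!length(ids) && len == 1L) {
        id <- unname(abbr[tk$tokens[i]])
        if (length(id) == 1L && !is.na(id)) ids <- id
      }
      if (length(ids)) { hit_len <- len; hit_ids <- ids; break }
    }
    if (hit_len > 0L) {
      s0 <- tk$spans[i, 1]; e0 <- tk$spans[i + hit_len - 1L, 2]
      out[[length(out) + 1L]] <-
        mention(s0, e0, slice0(sentence_text, s0, e0), "disease",
                ids = hit_ids)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Link disease mentions to MeSH descriptors
#'
#' Dictionary linker: exact folded-term match against the lexicon, with
#' in-document abbreviation expansion (the `"temporal lobe epilepsy (TLE)"`
#' pattern) when `context_text` is given. Unmatched mentions keep empty
#' `ids` — never a guess. Any other normalizer with the same signature can
#' be dropped in wherever a linker is accepted.
#'
#' @param mentions list of disease [mention()]s.
#' @param lexicon a `mesh_lexicon`.
#' @param context_text optional document text for abbreviation scanning.
#' @return the mentions with `ids` filled where linkable.
#' @export
link_disease_mentions <- function(mentions, lexicon, context_text = NULL) {
  abbr <- if (is.null(context_text)) character()
          else abbreviation_table(context_text, lexicon)
  lapply(mentions, function(m) {
    ids <- mesh_lookup(lexicon, m$surface)
    if (!length(ids)) {
      id <- unname(abbr[m$surface])
      if (length(id) == 1L && !is.na(id)) ids <- id
    }
    m$ids <- ids
    m
  })
}
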