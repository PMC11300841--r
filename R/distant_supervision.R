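# Distant-supervision corpus construction: annotate documents, keep
# sentences with both entity classes, auto-label single-pair sentences
# against a knowledge base, route multi-mention or unnormalizable sentences
# to a manual-curation queue. Every kept sentence yields exactly one of
# {auto-labeled instance, curation item}.

#' Normalize a knowledge-base association table
#'
#' @param df data frame with columns `mirna` (canonical name, `MIMAT`
#'   accession, or `MIRBASE:` id), `disease_mesh` (`D`/`C` id or `MESH:`
#'   id), `pmid`, `source`. Names are normalized through the lexicon when
#'   supplied.
#' @param mirbase_lex optional `mirbase_lexicon` for name -> accession
#'   resolution.
#' @return validated KB data frame with columns `mirna_id`, `disease_id`,
#'   `pmid`, `source`.
#' @export
kb_table <- function(df, mirbase_lex = NULL) {
  need <- c("mirna", "disease_mesh", "pmid", "source")
  if (!all(need %in% names(df))) {
    stop_mirdex("KB needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(!nzchar(as.character(unlist(df[need]))))) {
    stop_mirdex("KB fields must be non-empty")
  }
  to_mirna_id <- function(x) {
    if (grepl("^MIRBASE:", x)) return(x)
    if (grepl("^(MIMAT|MI)[0-9]+$", x)) return(concept_id("MIRBASE", x))
    if (is.null(mirbase_lex)) {
      stop_mirdex("KB miRNA '%s' is a name but no lexicon was supplied", x)
    }
    id <- normalize_to_mirbase(x, mirbase_lex)
    if (!length(id)) stop_mirdex("KB miRNA name '%s' is unmapped", x)
    id[1]
  }
  to_mesh_id <- function(x) {
    if (grepl("^MESH:", x)) return(x)
    concept_id("MESH", x)
  }
  data.frame(
    mirna_id = vapply(as.character(df$mirna), to_mirna_id, character(1),
                      USE.NAMES = FALSE),
    disease_id = vapply(as.character(df$disease_mesh), to_mesh_id,
                        character(1), USE.NAMES = FALSE),
    pmid = as.character(df$pmid),
    source = as.character(df$source),
    stringsAsFactors = FALSE
  )
}

#' Read a knowledge-base TSV
#'
#' @param path TSV with header `mirna`, `disease_mesh`, `pmid`, `source`.
#' @inheritParams kb_table
#' @return KB data frame (see [kb_table()]).
#' @export
read_kb <- function(path, mirbase_lex = NULL) {
  kb_table(utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                             colClasses = "character", encoding = "UTF-8"),
           mirbase_lex)
}

#' Annotate documents with miRNA and disease mentions
#'
#' Runs a miRNA detector and a disease tagger (a `mesh_lexicon` for
#' dictionary tagging, or any function
#' `(sentence_text, context_text) -> mentions`) over every sentence.
#'
#' @param documents list of [document()]s.
#' @param mirna_detector function `sentence_text -> mentions`; defaults to
#'   the rule detector with miRBase normalization when `mirbase_lex` is
#'   given, else to [detect_mirna_mentions()].
#' @param disease_tagger a `mesh_lexicon` or tagging function.
#' @param mirbase_lex optional `mirbase_lexicon` for normalization.
#' @return the documents with sentence mention lists filled.
#' @export
annotate_documents <- function(documents, disease_tagger,
                               mirna_detector = NULL, mirbase_lex = NULL) {
  if (is.null(mirna_detector)) {
    mirna_detector <- if (is.null(mirbase_lex)) {
      detect_mirna_mentions
    } else {
      function(txt) annotate_mirna(txt, mirbase_lex)
    }
  }
  tag_disease <- if (inherits(disease_tagger, "mesh_lexicon")) {
    function(txt, ctx) detect_disease_mentions(txt, disease_tagger, ctx)
  } else {
    disease_tagger
  }
  lapply(documents, function(doc) {
    doc$sentences <- lapply(doc$sentences, function(s) {
      s$mentions <- c(mirna_detector(s$text), tag_disease(s$text, doc$text))
      validate_sentence(s)
      s
    })
    doc
  })
}

#' Keep sentences carrying both entity classes
#'
#' @param documents annotated documents.
#' @return list of candidate records, each
#'   `list(doc_id, sentence, doc_text)`, for sentences with at least one
#'   miRNA and at least one disease mention.
#' @export
filter_sentences <- function(documents) {
  out <- list()
  for (doc in documents) {
    for (s in doc$sentences) {
      if (length(mentions_of(s, "mirna")) >= 1L &&
          length(mentions_of(s, "disease")) >= 1L) {
        out[[length(out) + 1L]] <-
          list(doc_id = doc$doc_id, sentence = s, doc_text = doc$text)
      }
    }
  }
  out
}

#' Auto-label candidate sentences against a knowledge base
#'
#' Single-miRNA/single-disease sentences are labeled `positive` iff the
#' normalized pair occurs in the KB — for the sentence's own PMID under the
#' default `scope = "pmid"`, or anywhere in the KB with `scope = "global"` —
#' and `negative` (a closed-world negative candidate, flagged in the
#' `provenance` column for optional curation) otherwise. Sentences with
#' multiple miRNA or disease mentions, or with an unnormalizable mention,
#' are never auto-labeled: they go to the curation queue with a reason.
#'
#' @param candidates list from [filter_sentences()].
#' @param kb KB data frame from [kb_table()]/[read_kb()].
#' @param scope `"pmid"` (default) or `"global"`.
#' @return list with `instances` (relation-instance data frame with
#'   `mirna_id`, `disease_id`, `provenance` columns) and `queue` (data frame
#'   of curation items with a `reason` column: `multi_mirna`,
#'   `multi_disease`, `both` or `unnormalizable`).
#' @export
label_instances <- function(candidates, kb, scope = c("pmid", "global")) {
  scope <- match.arg(scope)
  kb_keys <- if (scope == "pmid") {
    paste(kb$mirna_id, kb$disease_id, kb$pmid)
  } else {
    paste(kb$mirna_id, kb$disease_id)
  }
  inst_rows <- list(); queue_rows <- list()
  for (cand in candidates) {
    s <- cand$sentence
    ms <- mentions_of(s, "mirna")
    ds <- mentions_of(s, "disease")
    reason <- NULL
    if (length(ms) > 1L && length(ds) > 1L) reason <- "both"
    else if (length(ms) > 1L) reason <- "multi_mirna"
    else if (length(ds) > 1L) reason <- "multi_disease"
    else if (!length(ms[[1]]$ids) || !length(ds[[1]]$ids)) {
      reason <- "unnormalizable"
    }
    if (!is.null(reason)) {
      queue_rows[[length(queue_rows) + 1L]] <- data.frame(
        doc_id = cand$doc_id, sentence_text = s$text, reason = reason,
        n_mirna = length(ms), n_disease = length(ds),
        stringsAsFactors = FALSE)
      next
    }
    m <- ms[[1]]; d <- ds[[1]]
    key <- if (scope == "pmid") {
      paste(m$ids[1], d$ids[1], cand$doc_id)
    } else {
      paste(m$ids[1], d$ids[1])
    }
    inst_rows[[length(inst_rows) + 1L]] <- data.frame(
      doc_id = cand$doc_id, sentence_text = s$text,
      mirna_start = m$start, mirna_end = m$end, mirna_surface = m$surface,
      disease_start = d$start, disease_end = d$end,
      disease_surface = d$surface,
      label = if (key %in% kb_keys) "positive" else "negative",
      score = NA_real_,
      mirna_id = m$ids[1], disease_id = d$ids[1],
      provenance = "auto", stringsAsFactors = FALSE)
  }
  instances <- if (length(inst_rows)) {
    relation_instances(do.call(rbind, inst_rows))
  } else {
    relation_instances(data.frame(
      doc_id = character(), sentence_text = character(),
      mirna_start = integer(), mirna_end = integer(),
      mirna_surface = character(), disease_start = integer(),
      disease_end = integer(), disease_surface = character(),
      label = character(), score = numeric(),
      mirna_id = character(), disease_id = character(),
      provenance = character(), stringsAsFactors = FALSE))
  }
  queue <- if (length(queue_rows)) {
    do.call(rbind, queue_rows)
  } else {
    data.frame(doc_id = character(), sentence_text = character(),
               reason = character(), n_mirna = integer(),
               n_disease = integer(), stringsAsFactors = FALSE)
  }
  list(instances = instances, queue = queue)
}

#' Merge relation corpora with provenance
#'
#' Instances from different sources are combined with their provenance
#' preserved. Duplicate (sentence, mention pair) entries collapse to a
#' single instance: identical labels merge silently, and a curated label
#' overrides auto or external labels. A label conflict that no curated
#' instance resolves is an error listing every conflicting pair.
#'
#' @param auto,curated,external relation-instance data frames (any may be
#'   `NULL`); a `provenance` column is added/overwritten with the argument
#'   name.
#' @return merged relation-instance data frame.
#' @export
merge_corpora <- function(auto = NULL, curated = NULL, external = NULL) {
  tag <- function(df, prov) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$provenance <- prov
    df
  }
  parts <- Filter(Negate(is.null),
                  list(tag(auto, "auto"), tag(curated, "curated"),
                       tag(external, "external")))
  if (!length(parts)) stop_mirdex("nothing to merge")
  cols <- Reduce(intersect, lapply(parts, names))
  all_df <- do.call(rbind, lapply(parts, function(p) p[, cols, drop = FALSE]))
  key <- paste(all_df$sentence_text, all_df$mirna_surface,
               all_df$mirna_start, all_df$disease_surface,
               all_df$disease_start, sep = "\r")
  keep <- logical(nrow(all_df))
  conflicts <- character()
  for (k in unique(key)) {
    idx <- which(key == k)
    labs <- unique(all_df$label[idx])
    cur <- idx[all_df$provenance[idx] == "curated"]
    if (length(labs) > 1L) {
      if (length(cur)) {
        keep[cur[1]] <- TRUE
      } else {
        conflicts <- c(conflicts, sprintf(
          "'%s' [%s vs %s]",
          substr(all_df$sentence_text[idx[1]], 1, 60),
          all_df$label[idx[1]], all_df$label[idx[2]]))
      }
    } else {
      keep[if (length(cur)) cur[1] else idx[1]] <- TRUE
    }
  }
  if (length(conflicts)) {
    stop_mirdex("label conflict(s) in merge: %s",
                paste(conflicts, collapse = "; "))
  }
  out <- all_df[keep, , drop = FALSE]
  rownames(out) <- NULL
  relation_instances(out)
}

#' Write the curation queue for external annotation
#'
#' Emits the queue as a TSV plus a standoff-style annotation file per
#' queued sentence (sentence text and the reason code), ready for import
#' into annotation tooling.
#'
#' @param queue data frame from [label_instances()].
#' @param dir output directory (created if needed).
#' @return the TSV path, invisibly.
#' @export
write_curation_queue <- function(queue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "curation_queue.tsv")
  utils::write.table(queue, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- file.path(dir, "curation_queue.txt")
  writeLines(sprintf("# %s\t%s\n%s", queue$doc_id, queue$reason,
                     queue$sentence_text), ann, useBytes = TRUE)
  invisible(tsv)
}
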