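# Large-collection inference and comparison against a reference association
# database. Every candidate (miRNA, disease) instance ends in exactly one of
# four buckets — emitted, below-threshold, classified-negative,
# unnormalized — whose counts sum to the number of candidates.

#' Run the full extraction pipeline over documents
#'
#' Detects and normalizes mentions, builds masked instances for every
#' (miRNA, disease) pair, scores them, and emits association records for
#' instances classified positive with `score >= threshold` (inclusive) and
#' with both entities normalized. Per-document failures are logged and the
#' run continues.
#'
#' @param documents list of [document()]s.
#' @param classifier an `mdx_relation_classifier`.
#' @param disease_tagger a `mesh_lexicon` or tagging function (see
#'   [annotate_documents()]).
#' @param mirbase_lex a `mirbase_lexicon` for miRNA normalization.
#' @param mirna_detector optional override, as in [annotate_documents()].
#' @param threshold confidence cutoff in `[0,1]` (default 0.9; the boundary
#'   is kept).
#' @return data frame of association records (`mirna_id`, `disease_id`,
#'   `doc_id`, `sentence_text`, `score`) with a `counters` attribute:
#'   `emitted`, `below_threshold`, `negative`, `unnormalized`,
#'   `total_candidates`, `n_failed_docs`.
#' @export
run_inference <- function(documents, classifier, disease_tagger,
                          mirbase_lex, mirna_detector = NULL,
                          threshold = 0.9) {
  counters <- c(emitted = 0L, below_threshold = 0L, negative = 0L,
                unnormalized = 0L, total_candidates = 0L)
  n_failed <- 0L
  rows <- list()
  for (doc in documents) {
    res <- tryCatch({
      ann <- annotate_documents(list(doc), disease_tagger,
                                mirna_detector = mirna_detector,
                                mirbase_lex = mirbase_lex)[[1]]
      for (s in ann$sentences) {
        instances <- make_instances(s, doc_id = ann$doc_id)
        counters["total_candidates"] <-
          counters["total_candidates"] + length(instances)
        for (mi in instances) {
          m_ids <- mi$provenance$mirna$ids
          d_ids <- mi$provenance$disease$ids
          if (!length(m_ids) || !length(d_ids)) {
            counters["unnormalized"] <- counters["unnormalized"] + 1L
            next
          }
          p <- predict_proba(classifier, list(mi))
          if (p < 0.5) {
            counters["negative"] <- counters["negative"] + 1L
          } else if (p < threshold) {
            counters["below_threshold"] <- counters["below_threshold"] + 1L
          } else {
            counters["emitted"] <- counters["emitted"] + 1L
            rows[[length(rows) + 1L]] <- data.frame(
              mirna_id = m_ids[1], disease_id = d_ids[1],
              doc_id = ann$doc_id, sentence_text = s$text, score = p,
              stringsAsFactors = FALSE)
          }
        }
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("document %s failed: %s", doc$doc_id,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!isTRUE(res)) n_failed <- n_failed + 1L
  }
  records <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(mirna_id = character(), disease_id = character(),
               doc_id = character(), sentence_text = character(),
               score = numeric(), stringsAsFactors = FALSE)
  }
  attr(records, "counters") <- c(as.list(counters),
                                 n_failed_docs = n_failed)
  records
}

#' Aggregate records to unique normalized pairs
#'
#' @param records association records from [run_inference()].
#' @return data frame with one row per unique `(mirna_id, disease_id)` pair:
#'   `n_evidence` (evidence counts summing to `nrow(records)`) and
#'   `max_score` (per-pair score aggregation).
#' @export
aggregate_unique <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(mirna_id = character(), disease_id = character(),
                      n_evidence = integer(), max_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$mirna_id, records$disease_id, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(mirna_id = records$mirna_id[i[1]],
               disease_id = records$disease_id[i[1]],
               n_evidence = length(i),
               max_score = max(records$score[i]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mirna_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter records by confidence
#'
#' Keeps records with `score >= cutoff` (boundary inclusive). The number of
#' dropped records is attached as attribute `n_dropped`, so kept + dropped
#' equals the input count.
#'
#' @param records association records.
#' @param cutoff confidence cutoff (default 0.9).
#' @return filtered records.
#' @export
filter_high_confidence <- function(records, cutoff = 0.9) {
  if (any(records$score < 0 | records$score > 1)) {
    stop_mirdex("scores must lie in [0,1]")
  }
  keep <- records$score >= cutoff
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read a disease-ontology mapping table
#'
#' @param path TSV with header `mondo_id`, `parent_mondo_id`, `mesh_id`,
#'   `umls_id` (empty string for absent cross-references). Each row states
#'   that `mondo_id` is a direct subclass of `parent_mondo_id` (roots may
#'   use an empty parent) and carries that concept's MeSH/UMLS
#'   cross-references.
#' @return the mapping data frame.
#' @export
read_mondo_mapping <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  need <- c("mondo_id", "parent_mondo_id", "mesh_id", "umls_id")
  if (!all(need %in% names(df))) {
    stop_mirdex("mapping table needs columns: %s",
                paste(need, collapse = ", "))
  }
  df
}

#' Expand a disease concept to its subclass closure's identifiers
#'
#' Walks the subclass relation from the root concept (cycle-safe, via a
#' visited set), collecting the MeSH and UMLS cross-references of the root
#' and every transitive subclass. Deterministic; offline (the mapping table
#' replaces any ontology API).
#'
#' @param root_concept MONDO id of the disease of interest.
#' @param mapping mapping data frame from [read_mondo_mapping()].
#' @return sorted character vector of `MESH:`/`UMLS:` concept ids.
#' @export
expand_disease_concepts <- function(root_concept, mapping) {
  known <- union(mapping$mondo_id, mapping$parent_mondo_id)
  if (!root_concept %in% known) {
    stop_mirdex("root concept '%s' absent from the mapping table",
                root_concept)
  }
  visited <- character()
  frontier <- root_concept
  while (length(frontier)) {
    cur <- frontier[1]; frontier <- frontier[-1]
    if (cur %in% visited) next
    visited <- c(visited, cur)
    kids <- mapping$mondo_id[mapping$parent_mondo_id == cur]
    frontier <- c(frontier, setdiff(kids, visited))
  }
  rows <- mapping[mapping$mondo_id %in% visited, , drop = FALSE]
  ids <- c(
    vapply(rows$mesh_id[nzchar(rows$mesh_id)],
           function(x) concept_id("MESH", x), character(1),
           USE.NAMES = FALSE),
    vapply(rows$umls_id[nzchar(rows$umls_id)],
           function(x) concept_id("UMLS", x), character(1),
           USE.NAMES = FALSE))
  sort(unique(ids))
}

#' Compare predicted unique pairs with a reference database
#'
#' Both sides are brought into the (miRBase id, MeSH id) namespace: a
#' reference disease given as a UMLS id is bridged to MeSH through the
#' mapping table; reference pairs with no bridge land in the `unmapped`
#' bucket and are reported, never silently dropped. The three result sets
#' partition the comparison: `novel` and `overlap` together are exactly the
#' predicted unique pairs (after any disease filter), and `overlap` with
#' `reference_only` are exactly the mapped reference pairs.
#'
#' @param predicted data frame with `mirna_id`, `disease_id` columns (e.g.
#'   from [aggregate_unique()]).
#' @param reference data frame with `mirna` (miRBase accession or id) and
#'   `disease` (`MESH:`/`UMLS:` id or bare accession) columns.
#' @param disease_filter optional character vector of disease concept ids
#'   (e.g. from [expand_disease_concepts()]); both sides are restricted to
#'   diseases in the set.
#' @param mapping optional mapping table for UMLS -> MeSH bridging.
#' @return list of class `comparison_report`: `novel`, `overlap`,
#'   `reference_only`, `unmapped` (data frames of pairs) and `counts`.
#' @export
compare_with_reference <- function(predicted, reference,
                                   disease_filter = NULL, mapping = NULL) {
  norm_mirna <- function(x) {
    ifelse(grepl("^MIRBASE:", x), x, paste0("MIRBASE:", x))
  }
  umls_to_mesh <- if (!is.null(mapping)) {
    rows <- nzchar(mapping$umls_id) & nzchar(mapping$mesh_id)
    stats::setNames(paste0("MESH:", mapping$mesh_id[rows]),
                    paste0("UMLS:", mapping$umls_id[rows]))
  } else {
    character()
  }
  norm_disease <- function(x) {
    x <- ifelse(grepl("^(MESH|UMLS):", x), x,
                ifelse(grepl("^C[0-9]{7}", x) & nchar(x) == 8L,
                       paste0("UMLS:", x), paste0("MESH:", x)))
    bridged <- unname(umls_to_mesh[x])
    ifelse(grepl("^UMLS:", x) & !is.na(bridged), bridged, x)
  }
  pred <- unique(data.frame(mirna_id = norm_mirna(predicted$mirna_id),
                            disease_id = norm_disease(predicted$disease_id),
                            stringsAsFactors = FALSE))
  ref <- unique(data.frame(mirna_id = norm_mirna(reference$mirna),
                           disease_id = norm_disease(reference$disease),
                           stringsAsFactors = FALSE))
  unmapped <- ref[grepl("^UMLS:", ref$disease_id), , drop = FALSE]
  ref <- ref[!grepl("^UMLS:", ref$disease_id), , drop = FALSE]
  if (!is.null(disease_filter)) {
    pred <- pred[pred$disease_id %in% disease_filter, , drop = FALSE]
    ref <- ref[ref$disease_id %in% disease_filter, , drop = FALSE]
  }
  pk <- paste(pred$mirna_id, pred$disease_id)
  rk <- paste(ref$mirna_id, ref$disease_id)
  report <- list(
    novel = pred[!(pk %in% rk), , drop = FALSE],
    overlap = pred[pk %in% rk, , drop = FALSE],
    reference_only = ref[!(rk %in% pk), , drop = FALSE],
    unmapped = unmapped,
    counts = c(novel = sum(!(pk %in% rk)),
               overlap = sum(pk %in% rk),
               reference_only = sum(!(rk %in% pk)),
               unmapped = nrow(unmapped))
  )
  structure(report, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison: %d novel, %d overlap, %d reference-only, %d unmapped>\n",
    x$counts["novel"], x$counts["overlap"], x$counts["reference_only"],
    x$counts["unmapped"]))
  invisible(x)
}

#' Write association records to TSV
#'
#' @param records association records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(records, path) {
  df <- records
  df$score <- sprintf("%.6f", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
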