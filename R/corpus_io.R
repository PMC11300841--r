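# Corpus readers/writers and deterministic stratified splitting.
#
# Formats handled here:
#   * IOB/CoNLL two-column token files (token TAB-or-space label, blank line
#     between sentences)
#   * the relation TSV dialect (one row per candidate relation instance)
#   * plain-text documents (one document per file)
#   * the PubmedArticle/MedlineCitation abstract subset of PubMed XML
#   * BRAT-style standoff (.txt + .ann with "T1\tmirna 10 16\tmiR-21" lines)

.relation_cols <- c("doc_id", "sentence_text",
                    "mirna_start", "mirna_end", "mirna_surface",
                    "disease_start", "disease_end", "disease_surface",
                    "label", "score")

#' Read an IOB/CoNLL token-label file
#'
#' One token per line with its label in the last column; blank lines separate
#' sentences. Labels must be `O`, `B-<class>` or `I-<class>`. Sequences that
#' are illegal under the IOB scheme (an `I-` tag with no matching `B-`) are
#' read verbatim; repair happens in [iob_decode()].
#'
#' @param path file path.
#' @return list of [tagged_sentence()] objects, in file order.
#' @seealso [write_iob()], [iob_decode()]
#' @export
read_iob <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  toks <- character(); labs <- character()
  flush <- function() {
    if (length(toks)) {
      out[[length(out) + 1L]] <<- tagged_sentence(toks, labs)
      toks <<- character(); labs <<- character()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) != 2L) {
      stop_mirdex("line %d: expected 2 columns (token, label), found %d",
                  i, length(parts))
    }
    if (!grepl("^(O|[BI]-[A-Za-z_][A-Za-z0-9_]*)$", parts[2])) {
      stop_mirdex("line %d: unrecognized IOB label '%s'", i, parts[2])
    }
    toks <- c(toks, parts[1]); labs <- c(labs, parts[2])
  }
  flush()
  out
}

#' Write tagged sentences to an IOB/CoNLL file
#'
#' Inverse of [read_iob()]: `read_iob(write_iob(x, f))` reproduces `x`'s
#' tokens and labels, and repeated writes are byte-identical.
#'
#' @param sentences list of [tagged_sentence()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_iob <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    if (!all(grepl("^(O|[BI]-(mirna|disease))$", s$labels))) {
      bad <- s$labels[!grepl("^(O|[BI]-(mirna|disease))$", s$labels)]
      stop_mirdex("unknown entity class in label '%s'", bad[1])
    }
    paste(paste(s$tokens, s$labels), collapse = "\n")
  }, character(1))
  writeLines(c(rbind(blocks, "")), path, useBytes = TRUE)
  invisible(path)
}

#' Construct a table of relation instances
#'
#' The canonical in-memory form of the relation corpus: a data frame with one
#' row per (sentence, miRNA mention, disease mention) instance. Offsets are
#' 0-based half-open and sentence-relative; surfaces are validated against
#' the sentence text.
#'
#' @param df data frame with columns `doc_id`, `sentence_text`,
#'   `mirna_start`, `mirna_end`, `mirna_surface`, `disease_start`,
#'   `disease_end`, `disease_surface`, `label`
#'   (`positive`/`negative`/`unknown`) and `score` (in `[0,1]` or `NA`).
#' @return the validated data frame with a derived `instance_id` column.
#' @export
relation_instances <- function(df) {
  missing_cols <- setdiff(.relation_cols, names(df))
  if (length(missing_cols)) {
    stop_mirdex("missing relation columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, union(.relation_cols, names(df))]
  for (col in c("mirna_start", "mirna_end", "disease_start", "disease_end")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$score <- as.numeric(df$score)
  for (i in seq_len(nrow(df))) {
    for (side in c("mirna", "disease")) {
      s0 <- df[[paste0(side, "_start")]][i]
      e0 <- df[[paste0(side, "_end")]][i]
      surf <- df[[paste0(side, "_surface")]][i]
      if (is.na(s0) || is.na(e0) || s0 < 0L || e0 <= s0 ||
          e0 > nchar(df$sentence_text[i])) {
        stop_mirdex("row %d: %s offsets [%s,%s) outside sentence", i, side,
                    s0, e0)
      }
      sl <- slice0(df$sentence_text[i], s0, e0)
      if (!identical(sl, surf)) {
        stop_mirdex("row %d: %s surface '%s' != sentence slice '%s'",
                    i, side, surf, sl)
      }
    }
  }
  if (!all(df$label %in% c("positive", "negative", "unknown"))) {
    stop_mirdex("labels must be positive/negative/unknown")
  }
  if (any(!is.na(df$score) & (df$score < 0 | df$score > 1))) {
    stop_mirdex("scores must lie in [0,1]")
  }
  df$instance_id <- paste(df$doc_id, df$mirna_start, df$mirna_end,
                          df$disease_start, df$disease_end,
                          substr(df$sentence_text, 1, 40), sep = "|")
  if (anyDuplicated(df$instance_id)) {
    stop_mirdex("duplicate relation instance id: %s",
                df$instance_id[duplicated(df$instance_id)][1])
  }
  rownames(df) <- NULL
  df
}

#' Read a relation corpus TSV
#'
#' Reads the tab-separated relation dialect (UTF-8, header row, columns as in
#' [relation_instances()], empty string for an absent score) and validates
#' every row: offsets must lie inside the sentence and each surface column
#' must equal the corresponding text slice.
#'
#' @param path TSV file path.
#' @return validated relation-instance data frame.
#' @export
read_relation_corpus <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(.relation_cols, names(df))
  if (length(missing_cols)) {
    stop_mirdex("relation TSV lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  df$score[df$score == ""] <- NA_character_
  relation_instances(df)
}

#' Write a relation corpus TSV
#'
#' Scores are serialized with fixed 6-digit precision so repeated writes of
#' the same corpus are byte-identical; absent scores become empty strings.
#'
#' @param instances relation-instance data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relation_corpus <- function(instances, path) {
  df <- relation_instances(instances)[, .relation_cols]
  df$score <- ifelse(is.na(df$score), "", sprintf("%.6f", df$score))
  lines <- c(paste(.relation_cols, collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Deterministic stratified corpus split
#'
#' Partitions instances into named splits with label proportions preserved
#' within one instance per split (largest-remainder allocation within each
#' stratum, seeded shuffle). The same `seed` always yields the same manifest.
#'
#' @param instances relation-instance data frame (or any data frame with an
#'   `instance_id` column and the stratification column).
#' @param fractions positive numeric vector summing to 1. Names become split
#'   names; unnamed vectors of length 2 and 3 default to
#'   `train`/`test` and `train`/`validation`/`test`.
#' @param seed integer seed.
#' @param stratify_on column to stratify on (default `"label"`).
#' @return a `data.frame(instance_id, split)` manifest with `seed` and
#'   `fractions` attributes.
#' @export
split_corpus <- function(instances, fractions, seed, stratify_on = "label") {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_mirdex("fractions must be positive and sum to 1")
  }
  if (is.null(names(fractions))) {
    names(fractions) <- switch(as.character(length(fractions)),
      "1" = "test",
      "2" = c("train", "test"),
      "3" = c("train", "validation", "test"),
      paste0("split", seq_along(fractions)))
  }
  if (is.null(instances$instance_id)) {
    stop_mirdex("instances need an instance_id column")
  }
  strata <- split(instances$instance_id, instances[[stratify_on]])
  k <- length(fractions)
  for (lab in names(strata)) {
    if (length(strata[[lab]]) < k) {
      stop_mirdex("label '%s' has %d instance(s), fewer than %d splits",
                  lab, length(strata[[lab]]), k)
    }
  }
  assign_split <- function(ids) {
    n <- length(ids)
    ideal <- fractions * n
    base <- floor(ideal)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    rep(names(fractions), times = base)
  }
  manifest <- with_seed(seed, {
    parts <- lapply(names(strata), function(lab) {
      ids <- strata[[lab]]
      ids <- ids[sample.int(length(ids))]
      data.frame(instance_id = ids, split = assign_split(ids),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  manifest <- manifest[match(instances$instance_id, manifest$instance_id), ]
  rownames(manifest) <- NULL
  attr(manifest, "seed") <- as.integer(seed)
  attr(manifest, "fractions") <- fractions
  manifest
}

#' Read documents for inference
#'
#' @param path a file, a character vector of files, or a directory.
#' @param format `"plain"` (one document per file, `doc_id` = file name
#'   without extension) or `"pubmed_xml"` (the
#'   `PubmedArticle`/`MedlineCitation` abstract subset; `doc_id` = PMID).
#'   Articles without an abstract text element are skipped; the number of
#'   skipped articles is attached as attribute `n_skipped` and reported with
#'   a warning.
#' @param splitter sentence segmentation function (default
#'   [split_sentences()]).
#' @return list of [document()] objects.
#' @export
read_documents <- function(path, format = c("plain", "pubmed_xml"),
                           splitter = split_sentences) {
  format <- match.arg(format)
  if (length(path) == 1L && dir.exists(path)) {
    path <- list.files(path, full.names = TRUE)
    path <- path[!dir.exists(path)]
    path <- sort(path)
  }
  if (format == "plain") {
    docs <- lapply(path, function(f) {
      txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n")
      document(tools::file_path_sans_ext(basename(f)), txt,
               sentences = splitter(txt), source = "other")
    })
    return(docs)
  }
  docs <- list()
  skipped <- 0L
  for (f in path) {
    xml <- xml2::read_xml(f)
    arts <- xml2::xml_find_all(xml, ".//PubmedArticle")
    if (length(arts) == 0L &&
        identical(xml2::xml_name(xml), "PubmedArticle")) {
      arts <- list(xml)
    }
    for (art in arts) {
      pmid <- xml2::xml_text(
        xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
      abst <- xml2::xml_find_all(
        art, ".//MedlineCitation/Article/Abstract/AbstractText")
      if (length(abst) == 0L) { skipped <- skipped + 1L; next }
      txt <- paste(trimws(xml2::xml_text(abst)), collapse = " ")
      if (is.na(pmid) || !nzchar(pmid)) { skipped <- skipped + 1L; next }
      docs[[length(docs) + 1L]] <-
        document(pmid, txt, sentences = splitter(txt),
                 source = "pubmed_abstract")
    }
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d article(s) without abstract text", skipped),
            call. = FALSE)
  }
  attr(docs, "n_skipped") <- skipped
  docs
}

#' Read a BRAT-style standoff annotated document
#'
#' Expects `<stem>.txt` with the document text and `<stem>.ann` with
#' `T`-lines of the form `T1\tmirna 10 16\tmiR-21` (document-level 0-based
#' half-open offsets). Mentions are attached to the sentence that contains
#' them.
#'
#' @param txt_path path to the `.txt` file.
#' @param ann_path path to the `.ann` file (default: `.txt` swapped for
#'   `.ann`).
#' @param doc_id document id (default: file stem).
#' @return a [document()] with mentions attached.
#' @export
read_brat <- function(txt_path, ann_path = sub("\\.txt$", ".ann", txt_path),
                      doc_id = tools::file_path_sans_ext(basename(txt_path))) {
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  sents <- split_sentences(text)
  ann <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  ann <- ann[grepl("^T", ann)]
  for (ln in ann) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 3L) stop_mirdex("malformed standoff line: %s", ln)
    meta <- strsplit(parts[2], " ")[[1]]
    cls <- meta[1]; s0 <- as.integer(meta[2]); e0 <- as.integer(meta[3])
    surf <- parts[3]
    hit <- FALSE
    for (i in seq_along(sents)) {
      st <- sents[[i]]$start
      en <- st + nchar(sents[[i]]$text)
      if (s0 >= st && e0 <= en) {
        m <- mention(s0 - st, e0 - st, surf, cls)
        sents[[i]]$mentions <- c(sents[[i]]$mentions, list(m))
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      warning(sprintf("annotation [%d,%d) crosses sentence boundaries; kept out",
                      s0, e0), call. = FALSE)
    }
  }
  sents <- lapply(sents, function(s) { validate_sentence(s); s })
  document(doc_id, text, sentences = sents, source = "other")
}

#' Write a document to BRAT-style standoff files
#'
#' @param doc a [document()].
#' @param txt_path output `.txt` path; the `.ann` file is written alongside.
#' @return the `.ann` path, invisibly.
#' @export
write_brat <- function(doc, txt_path) {
  ann_path <- sub("\\.txt$", ".ann", txt_path)
  writeLines(doc$text, txt_path, useBytes = TRUE)
  lines <- character(); k <- 0L
  for (s in doc$sentences) {
    for (m in s$mentions) {
      k <- k + 1L
      lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", k, m$entity_class,
                                s$start + m$start, s$start + m$end,
                                m$surface))
    }
  }
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(ann_path)
}

#' Read a local copy of the SCAI-MDC miRNA-disease relation corpus
#'
#' The deposited corpus (Zenodo record 10523046) ships train and test
#' portions; this reader expects a directory holding them as relation-dialect
#' TSV files whose names contain `train` and `test`. The package never
#' downloads: obtain the archive separately and convert/point this reader at
#' it.
#'
#' @param dir directory containing the corpus TSVs.
#' @return `list(train = , test = )` of relation-instance data frames.
#' @export
read_scai_mdc <- function(dir) {
  if (!dir.exists(dir)) stop_mirdex("corpus directory '%s' not found", dir)
  find1 <- function(tag) {
    f <- list.files(dir, pattern = paste0(tag, ".*\\.tsv$"),
                    full.names = TRUE, ignore.case = TRUE)
    if (length(f) != 1L) {
      stop_mirdex("expected exactly one %s TSV in %s, found %d",
                  tag, dir, length(f))
    }
    f
  }
  list(train = read_relation_corpus(find1("train")),
       test  = read_relation_corpus(find1("test")))
}

#' Label counts of a train/test relation corpus
#'
#' @param corpus a `list(train =, test =)` as returned by [read_scai_mdc()].
#' @return named integer vector `train_positive`, `train_negative`,
#'   `test_positive`, `test_negative`.
#' @export
corpus_label_counts <- function(corpus) {
  cnt <- function(df, lab) sum(df$label == lab)
  c(train_positive = cnt(corpus$train, "positive"),
    train_negative = cnt(corpus$train, "negative"),
    test_positive  = cnt(corpus$test, "positive"),
    test_negative  = cnt(corpus$test, "negative"))
}
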