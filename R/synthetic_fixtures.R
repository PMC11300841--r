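# Synthetic fixtures with known ground truth: templated documents with
# planted miRNA/disease mentions, a toy knowledge base consistent with the
# planted positives, name/term lexicons, and a lexically separable relation
# signal (positive and negative sentences use disjoint cue phrases). Every
# artifact is bit-for-bit reproducible under a fixed seed.

#' Configuration for the synthetic corpus generator
#'
#' @param n_documents number of documents.
#' @param sentences_per_document sentences per document.
#' @param mirna_vocabulary miRNA vocabulary size (synthetic names).
#' @param disease_vocabulary disease vocabulary size (synthetic terms).
#' @param positive_cues,negative_cues cue phrases; the positive/negative
#'   signal is carried lexically by these disjoint sets.
#' @param p_positive proportion of positive sentences, in (0,1).
#' @param p_multi proportion of sentences carrying three miRNA mentions
#'   (these mirror multi-mention literature sentences and are routed to
#'   curation by the distant-supervision builder).
#' @param seed integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_documents = 50L,
                             sentences_per_document = 3L,
                             mirna_vocabulary = 25L,
                             disease_vocabulary = 15L,
                             positive_cues = c(
                               "was upregulated", "was overexpressed",
                               "was strongly induced",
                               "was significantly elevated"),
                             negative_cues = c(
                               "was unchanged", "remained unaffected",
                               "showed no alteration",
                               "was stably expressed"),
                             p_positive = 0.5, p_multi = 0.1,
                             seed = 7L) {
  stopifnot(mirna_vocabulary >= 1L, disease_vocabulary >= 1L,
            length(positive_cues) >= 1L, length(negative_cues) >= 1L,
            p_positive > 0, p_positive < 1, p_multi >= 0, p_multi < 1)
  structure(list(
    n_documents = as.integer(n_documents),
    sentences_per_document = as.integer(sentences_per_document),
    mirna_vocabulary = as.integer(mirna_vocabulary),
    disease_vocabulary = as.integer(disease_vocabulary),
    positive_cues = positive_cues, negative_cues = negative_cues,
    p_positive = p_positive, p_multi = p_multi,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# deterministic synthetic miRNA name table (numbers from 9001 up, arms
# alternating) with MIMAT-style accessions that never collide with real ones
synthetic_mirna_table <- function(n) {
  num <- 9000L + seq_len(n)
  arm <- rep(c("5p", "3p"), length.out = n)
  data.frame(
    surface = sprintf("miR-%d-%s", num, arm),
    canonical_name = sprintf("hsa-miR-%d-%s", num, arm),
    accession = sprintf("MIMAT9%d%s", num, ifelse(arm == "5p", "5", "3")),
    stringsAsFactors = FALSE
  )
}

synthetic_disease_table <- function(n) {
  adj <- c("cortical", "hepatic", "renal", "spinal", "gastric", "ocular",
           "dermal", "cardiac", "pulmonary", "lingual", "tonsillar",
           "parietal", "femoral", "adrenal", "pineal", "tibial", "caudal",
           "frontal", "basal", "apical")
  noun <- c("syndrome", "neuropathy", "dystrophy", "fibrosis", "atrophy")
  grid <- expand.grid(adj = adj, noun = noun, stringsAsFactors = FALSE)
  if (n > nrow(grid)) stop_mirdex("disease vocabulary too large (max %d)",
                                  nrow(grid))
  data.frame(
    term = paste("synthetic", grid$adj[seq_len(n)], grid$noun[seq_len(n)]),
    mesh_id = sprintf("D9%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# the name -> accession pairs printed in published association examples;
# everything else in the fixture lexicon is synthetic
.reference_mirbase_rows <- data.frame(
  canonical_name = c("hsa-miR-501-3p", "hsa-miR-502-3p", "hsa-miR-877-5p",
                     "hsa-miR-133b", "hsa-miR-221-3p", "hsa-let-7b-5p",
                     "hsa-let-7b-3p", "hsa-miR-21-5p"),
  accession = c("MIMAT0004774", "MIMAT0004775", "MIMAT0004949",
                "MIMAT0000770", "MIMAT0000278", "MIMAT0000063",
                "MIMAT0004482", "MIMAT0000076"),
  type = "mature",
  stringsAsFactors = FALSE
)

.reference_mesh_rows <- data.frame(
  term = c("epilepsy", "epileptic seizures", "seizures",
           "temporal lobe epilepsy", "TLE",
           "Alzheimer disease", "Alzheimer's disease", "AD",
           "Parkinson disease", "Parkinson's disease", "PD"),
  mesh_id = c("D004827", "D012640", "D012640",
              "D004833", "D004833",
              "D000544", "D000544", "D000544",
              "D010300", "D010300", "D010300"),
  stringsAsFactors = FALSE
)

#' Generate fixture lexicons
#'
#' Builds a miRBase-style lexicon and a MeSH disease lexicon covering (i)
#' the name/accession and term/descriptor pairs needed for the worked
#' literature examples and (ii) the synthetic vocabularies used by
#' [generate_corpus()]. Deterministic (no randomness); regeneration is
#' byte-identical.
#'
#' @param config a [generator_config()] (controls synthetic vocabulary
#'   sizes).
#' @return list with `mirbase` (a `mirbase_lexicon`), `mesh` (a
#'   `mesh_lexicon`) and the underlying data frames `mirbase_table`,
#'   `mesh_table`.
#' @export
generate_lexicons <- function(config = generator_config()) {
  syn <- synthetic_mirna_table(config$mirna_vocabulary)
  mirbase_df <- rbind(
    .reference_mirbase_rows,
    data.frame(canonical_name = syn$canonical_name,
               accession = syn$accession, type = "mature",
               stringsAsFactors = FALSE),
    data.frame(canonical_name = c("hsa-mir-21", "hsa-let-7b"),
               accession = c("MI0000077", "MI0000063"),
               type = "precursor", stringsAsFactors = FALSE),
    data.frame(canonical_name = sprintf("hsa-mir-%d",
                                        9000L + seq_len(min(
                                          5L, config$mirna_vocabulary))),
               accession = sprintf("MI9%04d0", seq_len(min(
                 5L, config$mirna_vocabulary))),
               type = "precursor", stringsAsFactors = FALSE)
  )
  mesh_df <- rbind(.reference_mesh_rows,
                   synthetic_disease_table(config$disease_vocabulary))
  list(mirbase = mirbase_lexicon(mirbase_df),
       mesh = mesh_lexicon(mesh_df),
       mirbase_table = mirbase_df,
       mesh_table = mesh_df)
}

#' Generate a synthetic document corpus with known ground truth
#'
#' Each sentence is built from the template `"X <cue> in patients with Y"`;
#' positive sentences use positive cues and their normalized (miRNA,
#' disease) pair is inserted into the knowledge base under the document's
#' id, so distant supervision against the returned KB reproduces the
#' planted labels exactly on single-pair sentences. A `p_multi` fraction of
#' sentences enumerate three miRNAs (never auto-labelable). Gold mentions
#' carry their normalized ids.
#'
#' @param config a [generator_config()].
#' @return list with `documents` (gold-annotated), `kb` (KB data frame),
#'   `labels` (data frame: `doc_id`, `sentence_index`, `type`, `label` —
#'   `NA` for multi-mention sentences), `lexicons` and `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  lex <- generate_lexicons(config)
  mir <- synthetic_mirna_table(config$mirna_vocabulary)
  dis <- synthetic_disease_table(config$disease_vocabulary)
  with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    kb_rows <- list()
    lab_rows <- list()
    for (di in seq_len(config$n_documents)) {
      doc_id <- sprintf("SYN%05d", di)
      sent_objs <- list()
      texts <- character()
      probes <- character()
      offset <- 0L
      for (si in seq_len(config$sentences_per_document)) {
        positive <- stats::runif(1) < config$p_positive
        multi <- stats::runif(1) < config$p_multi
        repeat {  # resample until the sentence is unique within its document
          cue <- if (positive) sample(config$positive_cues, 1L)
                 else sample(config$negative_cues, 1L)
          d_row <- dis[sample.int(nrow(dis), 1L), ]
          m_rows <- mir[sample.int(nrow(mir), if (multi) 3L else 1L), ]
          probe <- paste(cue, d_row$term, paste(m_rows$surface,
                                                collapse = " "))
          if (!probe %in% probes) break
        }
        probes <- c(probes, probe)
        d_id <- concept_id("MESH", d_row$mesh_id)
        if (multi) {
          txt <- sprintf("The %s, %s, and %s %s in patients with %s.",
                         m_rows$surface[1], m_rows$surface[2],
                         m_rows$surface[3],
                         sub("^was ", "were ", cue), d_row$term)
          mentions <- list()
          for (surf in m_rows$surface) {
            s0 <- regexpr(surf, txt, fixed = TRUE)[[1]] - 1L
            mentions <- c(mentions, list(mention(
              s0, s0 + nchar(surf), surf, "mirna",
              ids = concept_id("MIRBASE",
                               m_rows$accession[m_rows$surface == surf]))))
          }
          d0 <- nchar(txt) - 1L - nchar(d_row$term)
          mentions <- c(mentions, list(
            mention(d0, d0 + nchar(d_row$term), d_row$term, "disease",
                    ids = d_id)))
          if (positive) {
            for (acc in m_rows$accession) {
              kb_rows[[length(kb_rows) + 1L]] <- data.frame(
                mirna = acc, disease_mesh = d_row$mesh_id, pmid = doc_id,
                source = "synthetic_kb", stringsAsFactors = FALSE)
            }
          }
          lab_rows[[length(lab_rows) + 1L]] <- data.frame(
            doc_id = doc_id, sentence_index = si, type = "multi",
            label = NA_character_, stringsAsFactors = FALSE)
        } else {
          m_row <- m_rows[1L, ]
          txt <- sprintf("%s %s in patients with %s.",
                         m_row$surface, cue, d_row$term)
          m0 <- 0L
          d0 <- nchar(txt) - 1L - nchar(d_row$term)
          mentions <- list(
            mention(m0, m0 + nchar(m_row$surface), m_row$surface, "mirna",
                    ids = concept_id("MIRBASE", m_row$accession)),
            mention(d0, d0 + nchar(d_row$term), d_row$term, "disease",
                    ids = d_id))
          if (positive) {
            kb_rows[[length(kb_rows) + 1L]] <- data.frame(
              mirna = m_row$accession, disease_mesh = d_row$mesh_id,
              pmid = doc_id, source = "synthetic_kb",
              stringsAsFactors = FALSE)
          }
          lab_rows[[length(lab_rows) + 1L]] <- data.frame(
            doc_id = doc_id, sentence_index = si, type = "single",
            label = if (positive) "positive" else "negative",
            stringsAsFactors = FALSE)
        }
        sent_objs[[si]] <- sentence(txt, start = offset,
                                    mentions = mentions)
        texts <- c(texts, txt)
        offset <- offset + nchar(txt) + 1L
      }
      docs[[di]] <- document(doc_id, paste(texts, collapse = " "),
                             sentences = sent_objs, source = "other")
    }
    kb <- if (length(kb_rows)) {
      kb_table(unique(do.call(rbind, kb_rows)))
    } else {
      data.frame(mirna_id = character(), disease_id = character(),
                 pmid = character(), source = character(),
                 stringsAsFactors = FALSE)
    }
    list(documents = docs, kb = kb,
         labels = do.call(rbind, lab_rows),
         lexicons = lex, config = config)
  })
}

#' Build labeled masked instances from a synthetic corpus
#'
#' Flattens the gold single-pair sentences of a [generate_corpus()] result
#' into labeled [masked_instance()]s — the lexically separable relation
#' corpus used to exercise classifier training.
#'
#' @param corpus a [generate_corpus()] result.
#' @return list of labeled masked instances.
#' @export
generate_separable_instances <- function(corpus) {
  out <- list()
  lab <- corpus$labels
  for (doc in corpus$documents) {
    for (si in seq_along(doc$sentences)) {
      row <- lab[lab$doc_id == doc$doc_id & lab$sentence_index == si, ]
      if (row$type != "single") next
      mi <- make_instances(doc$sentences[[si]], doc_id = doc$doc_id)[[1]]
      mi$label <- row$label
      out[[length(out) + 1L]] <- mi
    }
  }
  out
}

#' Synthetic disease-ontology mapping fixture
#'
#' A small subclass tree for the three case-study diseases (epilepsy with a
#' temporal-lobe subtype and a seizure sibling, Alzheimer's and Parkinson's
#' disease) with MeSH and UMLS cross-references. The tree shape is
#' synthetic; it stands in for an ontology export and is used to exercise
#' subclass expansion and UMLS-to-MeSH bridging offline.
#'
#' @return mapping data frame in the [read_mondo_mapping()] layout.
#' @export
synthetic_mondo_mapping <- function() {
  data.frame(
    mondo_id = c("MONDO:0005027", "MONDO:0006680", "MONDO:0005737",
                 "MONDO:0004975", "MONDO:0005180"),
    parent_mondo_id = c("", "MONDO:0005027", "MONDO:0005027", "", ""),
    mesh_id = c("D004827", "D004833", "D012640", "D000544", "D010300"),
    umls_id = c("C0014544", "C0014556", "C0036572",
                "C0002395", "C0030567"),
    stringsAsFactors = FALSE
  )
}
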