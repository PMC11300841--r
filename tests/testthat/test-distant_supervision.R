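# Distant-supervision corpus construction against a toy knowledge base.

make_annotated <- function() {
  corpus <- fixture("ds_corpus",
                    generate_corpus(generator_config(seed = 7)))
  bare <- lapply(corpus$documents, function(d) {
    d$sentences <- lapply(d$sentences, function(s) {
      s$mentions <- list(); s
    })
    d
  })
  list(corpus = corpus,
       annotated = annotate_documents(
         bare, corpus$lexicons$mesh,
         mirbase_lex = corpus$lexicons$mirbase))
}

test_that("annotation recovers all planted mentions", {
  x <- make_annotated()
  gold_docs <- x$corpus$documents
  for (i in seq_along(gold_docs)) {
    for (j in seq_along(gold_docs[[i]]$sentences)) {
      gold <- gold_docs[[i]]$sentences[[j]]$mentions
      got <- x$annotated[[i]]$sentences[[j]]$mentions
      key <- function(ms) sort(vapply(ms, function(m) {
        paste(m$start, m$end, m$entity_class, paste(m$ids, collapse = ","))
      }, character(1)))
      expect_equal(key(got), key(gold))
    }
  }
  # empty document stays empty; disease-only sentences keep their mentions
  empty <- annotate_documents(list(document("e1", "Nothing relevant.")),
                              x$corpus$lexicons$mesh,
                              mirbase_lex = x$corpus$lexicons$mirbase)
  expect_length(empty[[1]]$sentences[[1]]$mentions, 0L)
})

test_that("sentence filtering keeps exactly the dual-mention sentences", {
  x <- make_annotated()
  cand <- filter_sentences(x$annotated)
  for (c in cand) {
    expect_gte(length(mirdex:::mentions_of(c$sentence, "mirna")), 1L)
    expect_gte(length(mirdex:::mentions_of(c$sentence, "disease")), 1L)
  }
  # hand-built composition: 2 keepable of 4
  lex <- x$corpus$lexicons
  doc <- document("h1", paste(
    "miR-9001-5p was upregulated in patients with synthetic cortical syndrome.",
    "miR-9002-3p was unchanged without any disease term.",
    "Patients with synthetic hepatic neuropathy declined.",
    "Nothing at all here."))
  ann <- annotate_documents(list(doc), lex$mesh, mirbase_lex = lex$mirbase)
  expect_length(filter_sentences(ann), 1L)
})

test_that("auto-labeling reproduces planted labels and queues multi-mention sentences", {
  x <- make_annotated()
  cand <- filter_sentences(x$annotated)
  res <- label_instances(cand, x$corpus$kb)
  # conservation: every candidate is labeled or queued, never both
  expect_equal(length(cand), nrow(res$instances) + nrow(res$queue))
  # every multi-mention gold sentence is queued with the right reason
  gold <- x$corpus$labels
  expect_equal(nrow(res$queue), sum(gold$type == "multi"))
  expect_true(all(res$queue$reason == "multi_mirna"))
  # planted-truth recovery on single-pair sentences
  sent_tab <- do.call(rbind, lapply(x$corpus$documents, function(d) {
    data.frame(doc_id = d$doc_id,
               sentence_index = seq_along(d$sentences),
               sentence_text = vapply(d$sentences, `[[`, character(1),
                                      "text"),
               stringsAsFactors = FALSE)
  }))
  m <- merge(res$instances, sent_tab, by = c("doc_id", "sentence_text"))
  m <- merge(m, gold, by = c("doc_id", "sentence_index"))
  expect_equal(nrow(m), sum(gold$type == "single"))
  expect_true(all(m$label.x == m$label.y))
})

test_that("KB scope and monotonicity behave as documented", {
  lex <- generate_lexicons()
  doc <- document("PMIDX", paste("miR-9001-5p was upregulated in patients",
                                 "with synthetic cortical syndrome."))
  ann <- annotate_documents(list(doc), lex$mesh, mirbase_lex = lex$mirbase)
  cand <- filter_sentences(ann)
  acc <- synthetic_mirna_table(1)$accession
  mesh <- synthetic_disease_table(1)$mesh_id
  kb_match <- kb_table(data.frame(mirna = acc, disease_mesh = mesh,
                                  pmid = "PMIDX", source = "s"))
  kb_other <- kb_table(data.frame(mirna = acc, disease_mesh = mesh,
                                  pmid = "PMIDY", source = "s"))
  expect_equal(label_instances(cand, kb_match)$instances$label, "positive")
  expect_equal(label_instances(cand, kb_other)$instances$label, "negative")
  expect_equal(label_instances(cand, kb_other,
                               scope = "global")$instances$label,
               "positive")
  # enlarging the KB never flips positive -> negative
  expect_equal(label_instances(cand,
                               rbind(kb_match, kb_other))$instances$label,
               "positive")
  # unnormalizable mentions go to the queue
  doc2 <- document("PMIDZ", paste("miR-4242 was upregulated in patients",
                                  "with synthetic cortical syndrome."))
  ann2 <- annotate_documents(list(doc2), lex$mesh,
                             mirbase_lex = lex$mirbase)
  res2 <- label_instances(filter_sentences(ann2), kb_match)
  expect_equal(nrow(res2$instances), 0L)
  expect_equal(res2$queue$reason, "unnormalizable")
})

test_that("corpus merging keeps provenance and resolves duplicates", {
  base <- data.frame(
    doc_id = "d1", sentence_text = "miR-21 causes glioma",
    mirna_start = 0L, mirna_end = 6L, mirna_surface = "miR-21",
    disease_start = 14L, disease_end = 20L, disease_surface = "glioma",
    label = "positive", score = NA_real_, stringsAsFactors = FALSE)
  other <- base
  other$doc_id <- "d2"
  other$sentence_text <- "miR-22 causes ataxia"
  other$mirna_surface <- "miR-22"
  other$disease_surface <- "ataxia"
  # disjoint merge is additive and tags provenance
  merged <- merge_corpora(auto = relation_instances(base),
                          external = relation_instances(other))
  expect_equal(nrow(merged), 2L)
  expect_setequal(merged$provenance, c("auto", "external"))
  # identical duplicate collapses
  dup <- merge_corpora(auto = relation_instances(base),
                       external = relation_instances(base))
  expect_equal(nrow(dup), 1L)
  # curated label wins over a conflicting auto label
  flipped <- base; flipped$label <- "negative"
  win <- merge_corpora(auto = relation_instances(base),
                       curated = relation_instances(flipped))
  expect_equal(win$label, "negative")
  expect_equal(win$provenance, "curated")
  # unresolvable conflict errors, listing it
  expect_error(merge_corpora(auto = relation_instances(base),
                             external = relation_instances(flipped)),
               "conflict")
})

test_that("the curation queue exports to TSV and standoff text", {
  q <- data.frame(doc_id = "d1", sentence_text = "A and B in C.",
                  reason = "multi_mirna", n_mirna = 2L, n_disease = 1L,
                  stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  path <- write_curation_queue(q, d)
  expect_true(file.exists(path))
  back <- read.delim(path)
  expect_equal(back$reason, "multi_mirna")
  expect_true(file.exists(file.path(d, "curation_queue.txt")))
})
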