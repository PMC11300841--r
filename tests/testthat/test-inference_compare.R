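# End-to-end inference, aggregation, confidence filtering, reference
# comparison with ontology expansion.

inference_fixture <- function() {
  fixture("inference_run", {
    corpus <- generate_corpus(generator_config(n_documents = 20, seed = 31))
    bare <- lapply(corpus$documents, function(d) {
      d$sentences <- lapply(d$sentences, function(s) {
        s$mentions <- list(); s
      })
      d
    })
    records <- run_inference(bare, stm_fit(), corpus$lexicons$mesh,
                             corpus$lexicons$mirbase, threshold = 0.5)
    list(corpus = corpus, bare = bare, records = records)
  })
}

test_that("inference recovers planted positives and only those", {
  x <- inference_fixture()
  records <- x$records
  # gold pairs of single positive sentences
  gold <- x$corpus$labels
  sent_of <- function(doc, si) doc$sentences[[si]]
  gold_pos <- character(); gold_neg <- character()
  for (i in seq_along(x$corpus$documents)) {
    d <- x$corpus$documents[[i]]
    rows <- gold[gold$doc_id == d$doc_id & gold$type == "single", ]
    for (j in seq_len(nrow(rows))) {
      s <- sent_of(d, rows$sentence_index[j])
      m <- mirdex:::mentions_of(s, "mirna")[[1]]
      di <- mirdex:::mentions_of(s, "disease")[[1]]
      key <- paste(m$ids[1], di$ids[1], d$doc_id)
      if (rows$label[j] == "positive") gold_pos <- c(gold_pos, key)
      else gold_neg <- c(gold_neg, key)
    }
  }
  got <- paste(records$mirna_id, records$disease_id, records$doc_id)
  expect_true(all(gold_pos %in% got))
  expect_length(intersect(got, gold_neg), 0L)
  # conservation of candidate instances over the four buckets
  cnt <- attr(records, "counters")
  expect_equal(cnt$emitted + cnt$below_threshold + cnt$negative +
                 cnt$unnormalized,
               cnt$total_candidates)
  expect_equal(cnt$emitted, nrow(records))
})

test_that("degenerate thresholds and inputs behave as documented", {
  x <- inference_fixture()
  none <- run_inference(x$bare[1:3], stm_fit(), x$corpus$lexicons$mesh,
                        x$corpus$lexicons$mirbase, threshold = 1.01)
  expect_equal(nrow(none), 0L)
  no_disease <- document("nd1", "miR-9001-5p was upregulated overall.")
  out <- run_inference(list(no_disease), stm_fit(),
                       x$corpus$lexicons$mesh, x$corpus$lexicons$mirbase)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "counters")$total_candidates, 0L)
})

test_that("aggregation to unique pairs conserves evidence counts", {
  rec <- data.frame(
    mirna_id = c("MIRBASE:M1", "MIRBASE:M1", "MIRBASE:M1", "MIRBASE:M2"),
    disease_id = c("MESH:D1", "MESH:D1", "MESH:D1", "MESH:D2"),
    doc_id = c("a", "b", "c", "a"),
    sentence_text = "s", score = c(0.91, 0.95, 0.99, 0.6),
    stringsAsFactors = FALSE)
  u <- aggregate_unique(rec)
  expect_equal(nrow(u), 2L)
  expect_equal(u$n_evidence[u$mirna_id == "MIRBASE:M1"], 3L)
  expect_equal(u$max_score[u$mirna_id == "MIRBASE:M1"], 0.99)
  expect_equal(sum(u$n_evidence), nrow(rec))
  expect_equal(nrow(aggregate_unique(rec[0, ])), 0L)
  # fixture with known composition: 10 pairs over 40 records
  withr::with_seed(41, {
    pairs <- sprintf("P%02d", 1:10)
    draw <- sample(pairs, 40, replace = TRUE)
    rec2 <- data.frame(mirna_id = paste0("MIRBASE:", draw),
                       disease_id = "MESH:D1", doc_id = "d",
                       sentence_text = "s", score = runif(40),
                       stringsAsFactors = FALSE)
  })
  u2 <- aggregate_unique(rec2)
  expect_equal(sort(u2$n_evidence),
               sort(unname(as.vector(table(draw)))))
})

test_that("confidence filtering keeps the 0.9 boundary inclusive", {
  rec <- data.frame(mirna_id = "M", disease_id = "D", doc_id = "x",
                    sentence_text = "s",
                    score = c(0.95, 0.9, 0.8999999, 0.5),
                    stringsAsFactors = FALSE)
  kept <- filter_high_confidence(rec)
  expect_equal(kept$score, c(0.95, 0.9))
  expect_equal(attr(kept, "n_dropped"), 2L)
  expect_equal(nrow(kept) + attr(kept, "n_dropped"), nrow(rec))
  expect_error(filter_high_confidence(transform(rec, score = score * 2)),
               "\\[0,1\\]")
})

test_that("ontology expansion walks the subclass closure safely", {
  map <- synthetic_mondo_mapping()
  ids <- expand_disease_concepts("MONDO:0005027", map)  # epilepsy + subtypes
  expect_setequal(ids, c("MESH:D004827", "MESH:D004833", "MESH:D012640",
                         "UMLS:C0014544", "UMLS:C0014556",
                         "UMLS:C0036572"))
  # leaf with a single xref pair
  expect_setequal(expand_disease_concepts("MONDO:0004975", map),
                  c("MESH:D000544", "UMLS:C0002395"))
  # three-level hand-built tree
  tree <- data.frame(
    mondo_id = c("R", "A", "B", "C"),
    parent_mondo_id = c("", "R", "A", "B"),
    mesh_id = c("D100000", "D100001", "", "D100003"),
    umls_id = c("", "", "C1000002", ""),
    stringsAsFactors = FALSE)
  expect_setequal(expand_disease_concepts("R", tree),
                  c("MESH:D100000", "MESH:D100001", "MESH:D100003",
                    "UMLS:C1000002"))
  expect_setequal(expand_disease_concepts("B", tree),
                  c("UMLS:C1000002", "MESH:D100003"))
  # cyclic fixture terminates via the visited set
  cyc <- data.frame(mondo_id = c("X", "Y"), parent_mondo_id = c("Y", "X"),
                    mesh_id = c("D200000", "D200001"), umls_id = c("", ""),
                    stringsAsFactors = FALSE)
  expect_setequal(expand_disease_concepts("X", cyc),
                  c("MESH:D200000", "MESH:D200001"))
  expect_error(expand_disease_concepts("MONDO:404", map), "absent")
})

test_that("reference comparison partitions predictions and reference", {
  pred <- data.frame(mirna_id = c("MIRBASE:MIMAT1", "MIRBASE:MIMAT2"),
                     disease_id = c("MESH:D1", "MESH:D2"),
                     stringsAsFactors = FALSE)
  ref <- data.frame(mirna = c("MIMAT2", "MIMAT3"),
                    disease = c("MESH:D2", "MESH:D3"),
                    stringsAsFactors = FALSE)
  rep <- compare_with_reference(pred, ref)
  expect_equal(unname(rep$counts[c("novel", "overlap", "reference_only")]),
               c(1L, 1L, 1L))
  # empty reference: everything is novel
  rep2 <- compare_with_reference(pred, ref[0, ])
  expect_equal(unname(rep2$counts["novel"]), 2L)
  # UMLS reference ids bridge through the mapping; unbridgeable reported
  map <- synthetic_mondo_mapping()
  ref3 <- data.frame(mirna = c("MIMAT1", "MIMAT9"),
                     disease = c("UMLS:C0014544", "UMLS:C9999999"),
                     stringsAsFactors = FALSE)
  pred3 <- data.frame(mirna_id = "MIRBASE:MIMAT1",
                      disease_id = "MESH:D004827",
                      stringsAsFactors = FALSE)
  rep3 <- compare_with_reference(pred3, ref3, mapping = map)
  expect_equal(unname(rep3$counts["overlap"]), 1L)
  expect_equal(unname(rep3$counts["unmapped"]), 1L)
  # partition property fuzzed over random pair sets
  withr::with_seed(55, {
    for (i in 1:25) {
      universe <- sprintf("MESH:D%06d", 1:8)
      p <- data.frame(mirna_id = "MIRBASE:MIMAT1",
                      disease_id = sample(universe, sample(1:8, 1)),
                      stringsAsFactors = FALSE)
      r <- data.frame(mirna = "MIMAT1",
                      disease = sample(universe, sample(1:8, 1)),
                      stringsAsFactors = FALSE)
      rp <- compare_with_reference(p, r)
      expect_equal(nrow(rp$novel) + nrow(rp$overlap), nrow(unique(p)))
      expect_equal(nrow(rp$overlap) + nrow(rp$reference_only),
                   nrow(unique(r)))
      expect_length(intersect(paste(rp$novel$disease_id),
                              paste(rp$overlap$disease_id)), 0L)
    }
  })
  # disease filter restricts both sides
  flt <- compare_with_reference(pred, ref, disease_filter = "MESH:D2")
  expect_equal(unname(flt$counts), c(0L, 1L, 0L, 0L))
})

test_that("association records round-trip through the output TSV", {
  x <- inference_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_associations(x$records, f)
  back <- read.delim(f, colClasses = "character")
  expect_equal(nrow(back), nrow(x$records))
  expect_equal(names(back), c("mirna_id", "disease_id", "doc_id",
                              "sentence_text", "score"))
})
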