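# Corpus readers/writers, splitting, document ingestion.

test_that("IOB files parse to sentences, tokens and mention spans", {
  f <- withr::local_tempfile(fileext = ".iob")
  writeLines(c("The O", "miR-21 B-mirna", ""), f)
  sents <- read_iob(f)
  expect_length(sents, 1L)
  expect_equal(sents[[1]]$tokens, c("The", "miR-21"))
  expect_length(iob_decode(sents[[1]]), 1L)

  writeLines(character(), f)
  expect_length(read_iob(f), 0L)

  writeLines(c("tok O", "bad O extra"), f)
  expect_error(read_iob(f), "line 2")
  writeLines(c("tok X-mirna"), f)
  expect_error(read_iob(f), "label")
})

test_that("an I- tag with no B- survives reading and is repaired on decode", {
  f <- withr::local_tempfile(fileext = ".iob")
  writeLines(c("The O", "epilepsy I-disease", ""), f)
  sents <- read_iob(f)
  expect_equal(sents[[1]]$labels, c("O", "I-disease"))
  ms <- iob_decode(sents[[1]])
  expect_length(ms, 1L)
  expect_equal(ms[[1]]$surface, "epilepsy")
})

test_that("IOB write/read round-trips and repeated writes are byte-identical", {
  withr::with_seed(404, {
    sents <- lapply(1:100, function(i) random_tagged_sentence())
    f1 <- withr::local_tempfile(fileext = ".iob")
    f2 <- withr::local_tempfile(fileext = ".iob")
    write_iob(sents, f1)
    back <- read_iob(f1)
    expect_length(back, 100L)
    for (i in seq_along(sents)) {
      expect_equal(back[[i]]$tokens, sents[[i]]$tokens)
      expect_equal(back[[i]]$labels, sents[[i]]$labels)
    }
    write_iob(back, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  })
  s <- tagged_sentence(c("no", "entities"), c("O", "O"))
  f <- withr::local_tempfile()
  write_iob(list(s), f)
  expect_equal(read_iob(f)[[1]]$labels, c("O", "O"))
  bad <- tagged_sentence("x", "B-gene")
  expect_error(write_iob(list(bad), withr::local_tempfile()), "class")
})

test_that("relation TSV read validates offsets and surfaces", {
  txt <- "miR-21 causes glioma"
  df <- data.frame(doc_id = "d1", sentence_text = txt,
                   mirna_start = 0L, mirna_end = 6L, mirna_surface = "miR-21",
                   disease_start = 14L, disease_end = 20L,
                   disease_surface = "glioma", label = "positive",
                   score = NA_real_, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_relation_corpus(relation_instances(df), f)
  back <- read_relation_corpus(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$mirna_surface, "miR-21")

  bad <- df; bad$mirna_surface <- "miR-22"
  expect_error(relation_instances(bad), "surface")
  bad2 <- df; bad2$disease_end <- 99L
  expect_error(relation_instances(bad2), "outside")
  two <- rbind(df, df)
  expect_error(relation_instances(two), "duplicate")
})

test_that("relation corpora round-trip through TSV with stable bytes", {
  corpus <- sep_corpus()
  ds <- label_instances(filter_sentences(corpus$documents), corpus$kb)
  inst <- ds$instances[1:50, ]
  inst$score <- c(rep(NA_real_, 10), round(runif(40), 4))
  inst <- relation_instances(inst)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_relation_corpus(inst, f1)
  back <- read_relation_corpus(f1)
  cols <- c("doc_id", "sentence_text", "mirna_start", "mirna_end",
            "mirna_surface", "disease_start", "disease_end",
            "disease_surface", "label")
  expect_equal(back[, cols], inst[, cols])
  expect_equal(back$score, inst$score, tolerance = 1e-6)
  write_relation_corpus(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # empty corpus -> header-only file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_relation_corpus(inst[0, ], f3)
  expect_length(readLines(f3), 1L)
  expect_equal(nrow(read_relation_corpus(f3)), 0L)
})

test_that("stratified splits are exact, deterministic partitions", {
  df <- data.frame(instance_id = sprintf("i%03d", 1:100),
                   label = rep(c("positive", "negative"), each = 50),
                   stringsAsFactors = FALSE)
  man <- split_corpus(df, c(0.8, 0.2), seed = 3)
  tab <- table(df$label[match(man$instance_id, df$instance_id)], man$split)
  expect_equal(unname(tab["positive", "train"]), 40)
  expect_equal(unname(tab["negative", "train"]), 40)
  expect_equal(unname(tab["positive", "test"]), 10)
  expect_equal(sort(man$instance_id), sort(df$instance_id))
  expect_identical(man, split_corpus(df, c(0.8, 0.2), seed = 3))
  expect_false(identical(man$split, split_corpus(df, c(0.8, 0.2),
                                                 seed = 4)$split))
  # label proportions survive a single-split pass (test-set layout 460/290)
  df2 <- data.frame(instance_id = sprintf("j%03d", 1:750),
                    label = rep(c("positive", "negative"), c(460, 290)),
                    stringsAsFactors = FALSE)
  man2 <- split_corpus(df2, c(test = 1.0), seed = 1)
  expect_equal(mean(df2$label[match(man2$instance_id,
                                    df2$instance_id)] == "positive"),
               460 / 750)
  # errors
  rare <- data.frame(instance_id = c("a", "b", "c"),
                     label = c("positive", "positive", "negative"))
  expect_error(split_corpus(rare, c(0.5, 0.3, 0.2), seed = 1), "fewer")
  expect_error(split_corpus(df, c(0.5, 0.4), seed = 1), "sum to 1")
})

test_that("plain and PubMed XML documents are read with sentence offsets", {
  d <- withr::local_tempdir()
  writeLines("miR-21 rises in glioma. It marks tumor grade.",
             file.path(d, "doc1.txt"))
  docs <- read_documents(file.path(d, "doc1.txt"), "plain")
  expect_length(docs, 1L)
  expect_equal(docs[[1]]$doc_id, "doc1")
  expect_length(docs[[1]]$sentences, 2L)
  s2 <- docs[[1]]$sentences[[2]]
  expect_equal(substr(docs[[1]]$text, s2$start + 1,
                      s2$start + nchar(s2$text)), s2$text)

  xml <- system.file("extdata", "pubmed_fixture.xml", package = "mirdex")
  expect_warning(pm <- read_documents(xml, "pubmed_xml"), "skipped 1")
  expect_equal(vapply(pm, `[[`, character(1), "doc_id"),
               c("36454178", "32648622"))
  expect_equal(attr(pm, "n_skipped"), 1L)
  expect_equal(pm[[1]]$source, "pubmed_abstract")
  expect_length(pm[[2]]$sentences, 2L)
})

test_that("sentence splitter honors the abbreviation blacklist", {
  txt <- "Levels rose (see Fig. 2A). Bagewadi et al. report more. Done."
  sents <- split_sentences(txt)
  expect_length(sents, 3L)
  expect_match(sents[[1]]$text, "Fig. 2A", fixed = TRUE)
  expect_match(sents[[2]]$text, "et al. report", fixed = TRUE)
  expect_length(split_sentences("Single sentence without terminator"), 1L)
  expect_length(split_sentences("   "), 0L)
  # sentences may open with a lowercase miRNA-style token
  expect_length(split_sentences(
    "Levels rose in cortex. miR-21 was elevated too."), 2L)
  # but an unknown lowercase continuation does not split
  expect_length(split_sentences("Values approx. doubled overall"), 1L)
})

test_that("BRAT standoff round-trips through document-level offsets", {
  txt <- "miR-21 causes glioma. Unrelated closing sentence."
  doc <- document("b1", txt)
  m <- mention(0L, 6L, "miR-21", "mirna")
  d <- mention(14L, 20L, "glioma", "disease")
  doc$sentences[[1]]$mentions <- list(m, d)
  base <- withr::local_tempfile(fileext = ".txt")
  write_brat(doc, base)
  back <- read_brat(base, doc_id = "b1")
  ms <- back$sentences[[1]]$mentions
  expect_length(ms, 2L)
  expect_setequal(vapply(ms, `[[`, character(1), "surface"),
                  c("miR-21", "glioma"))
  ann <- readLines(sub("\\.txt$", ".ann", base))
  expect_match(ann[1], "^T1\tmirna 0 6\tmiR-21$")
})

test_that("mention and sentence invariants are enforced", {
  expect_error(mention(5, 3, "x", "mirna"), "start < end")
  expect_error(sentence("short", mentions = list(
    mention(0, 99, "short", "mirna"))), "exceeds")
  expect_error(sentence("miR-21 here", mentions = list(
    mention(0, 6, "miR-99", "mirna"))), "surface")
  expect_error(sentence("miR-21 and miR-22", mentions = list(
    mention(0, 9, "miR-21 an", "mirna"),
    mention(4, 10, "21 and", "mirna"))), "overlap")
  expect_error(concept_id("MESH", "X123"), "not valid")
  expect_equal(concept_id("MIRBASE", "MIMAT0000063"),
               "MIRBASE:MIMAT0000063")
})
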