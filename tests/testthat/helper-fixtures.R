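# Shared fixtures, built once per test run and cached (model fits are the
# expensive part; every consumer reuses the same seeded fit).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# lexically separable relation corpus: ~460 labeled single-pair instances
sep_corpus <- function() {
  fixture("sep_corpus", generate_corpus(generator_config(n_documents = 170,
                                                         seed = 7)))
}

sep_instances <- function() {
  fixture("sep_instances", generate_separable_instances(sep_corpus()))
}

sep_train_idx <- function() seq_len(400L)
sep_val_idx <- function() setdiff(seq_along(sep_instances()), sep_train_idx())

sep_labels <- function() {
  vapply(sep_instances(), function(i) i$label, character(1))
}

stm_fit <- function() {
  fixture("stm_fit",
          fine_tune_stm(sep_instances()[sep_train_idx()],
                        config = tiny_encoder_config(seed = 7)))
}

stm_val_auroc <- function() {
  fixture("stm_val_auroc", {
    p <- predict_proba(stm_fit(), sep_instances()[sep_val_idx()])
    auroc(sep_labels()[sep_val_idx()], p)
  })
}

aux_instances <- function() {
  fixture("aux_instances", generate_separable_instances(
    generate_corpus(generator_config(n_documents = 80, seed = 21))))
}

mtm_fit <- function() {
  fixture("mtm_fit", fine_tune_mtm(
    list(name = "mirna_disease",
         instances = sep_instances()[sep_train_idx()]),
    list(list(name = "auxiliary", instances = aux_instances())),
    tiny_encoder_config(seed = 7)))
}

mtm_val_auroc <- function() {
  fixture("mtm_val_auroc", {
    p <- predict_proba(mtm_fit(), sep_instances()[sep_val_idx()])
    auroc(sep_labels()[sep_val_idx()], p)
  })
}

# tagging fixture: 270 gold-annotated sentences, 200 train / 70 held out
tagging_sentences <- function() {
  fixture("tagging_sentences", {
    corpus <- generate_corpus(generator_config(n_documents = 90, seed = 11))
    sents <- unlist(lapply(corpus$documents, function(d) d$sentences),
                    recursive = FALSE)
    lapply(sents, iob_encode)
  })
}

tagger_fit <- function() {
  fixture("tagger_fit", train_tagger(
    tagging_sentences()[1:200], tagging_sentences()[201:270],
    tiny_encoder_config(seed = 13, epochs = 10L)))
}

# the published worked examples: sentence, highlighted mention, accession
worked_example_rows <- function() {
  ad <- paste("The miR-501-3p, miR-502-3p, and miR-877-5p were identified",
              "as potential synaptosomal miRNAs upregulated with disease",
              "progression based on AD Braak stages.")
  pd <- paste("Elevated miR-133b and miR-221-3p distinguished PD from",
              "controls with 84.8% sensitivity and 88.9% specificity.")
  ep1 <- paste("Overexpression of let-7b inhibited hippocampal glial cell",
               "activation, inflammatory response and epileptic seizures by",
               "targeting Stat3.")
  ep2 <- paste("LncRNA H19 could competitively bind to let-7b to promote",
               "hippocampal glial cell activation and epileptic seizures by",
               "targeting Stat3 in a rat model of TLE.")
  data.frame(
    sentence = c(ad, ad, ad, pd, pd, ep1, ep2),
    mirna = c("miR-501-3p", "miR-502-3p", "miR-877-5p",
              "miR-133b", "miR-221-3p", "let-7b", "let-7b"),
    accession = c("MIMAT0004774", "MIMAT0004775", "MIMAT0004949",
                  "MIMAT0000770", "MIMAT0000278", "MIMAT0000063",
                  "MIMAT0000063"),
    stringsAsFactors = FALSE
  )
}

# a random legally-labeled tagged sentence (for round-trip/fuzz tests)
random_tagged_sentence <- function(n_tokens = NULL) {
  if (is.null(n_tokens)) n_tokens <- sample(3:12, 1)
  vocab <- c("the", "miR-21", "let-7b", "glioma", "expression", "cells",
             "tumor", "levels", "was", "elevated", "in", "patients")
  tokens <- sample(vocab, n_tokens, replace = TRUE)
  labels <- rep("O", n_tokens)
  i <- 1L
  while (i <= n_tokens) {
    if (stats::runif(1) < 0.3) {
      cls <- sample(c("mirna", "disease"), 1)
      len <- min(sample(1:2, 1), n_tokens - i + 1L)
      labels[i] <- paste0("B-", cls)
      if (len > 1L) labels[i + 1L] <- paste0("I-", cls)
      i <- i + len + 1L  # gap so same-class mentions stay separate
    } else {
      i <- i + 1L
    }
  }
  tagged_sentence(tokens, labels)
}
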