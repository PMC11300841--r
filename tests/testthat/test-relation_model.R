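# Entity masking, STM/MTM fine-tuning, scoring, HPO contract.

test_that("masking builds one instance per mention pair", {
  s <- sentence("miR-21 causes glioma", mentions = list(
    mention(0, 6, "miR-21", "mirna"), mention(14, 20, "glioma", "disease")))
  inst <- make_instances(s, doc_id = "d1")
  expect_length(inst, 1L)
  expect_equal(inst[[1]]$masked_text, "@MIRNA$ causes @DISEASE$")
  expect_equal(unmask_instance(inst[[1]]), "miR-21 causes glioma")

  # multi-miRNA sentence: one instance per miRNA, others left verbatim
  txt <- "The miR-501-3p, miR-502-3p, and miR-877-5p were linked to AD."
  ms <- detect_mirna_mentions(txt)
  d0 <- regexpr("AD", txt)[[1]] - 1L
  s2 <- sentence(txt, mentions = c(ms, list(
    mention(d0, d0 + 2L, "AD", "disease"))))
  inst2 <- make_instances(s2, doc_id = "36454178")
  expect_length(inst2, 3L)
  masked_one <- inst2[[2]]$masked_text
  expect_match(masked_one, "miR-501-3p", fixed = TRUE)
  expect_match(masked_one, "@MIRNA$", fixed = TRUE)
  expect_false(grepl("miR-502-3p", masked_one, fixed = TRUE))

  # pair-count conservation on random mention inventories
  withr::with_seed(12, {
    for (rep in 1:20) {
      nm <- sample(0:3, 1); nd <- sample(0:3, 1)
      words <- c(sprintf("miR-%d", 100 + seq_len(nm) * 7),
                 sprintf("dis%d", seq_len(nd)))
      txt <- paste(c(words, "end"), collapse = " ")
      offs <- cumsum(c(0, nchar(words) + 1L))
      mens <- lapply(seq_along(words), function(i) {
        mention(offs[i], offs[i] + nchar(words[i]), words[i],
                if (i <= nm) "mirna" else "disease")
      })
      sx <- sentence(txt, mentions = mens)
      expect_length(make_instances(sx), nm * nd)
    }
  })
})

test_that("masked instances validate their placeholders", {
  expect_error(masked_instance("no placeholders at all"), "exactly one")
  expect_error(masked_instance("@MIRNA$ and @MIRNA$ with @DISEASE$"),
               "exactly one")
  ok <- masked_instance("@MIRNA$ drives @DISEASE$", label = "positive")
  expect_equal(ok$label, "positive")
  expect_error(masked_instance("@MIRNA$ x @DISEASE$", label = "maybe"),
               "label")
})

test_that("the STM learns the separable corpus and is reproducible", {
  expect_gte(stm_val_auroc(), 0.95)
  # untrained scores sit near chance on the balanced held-out set
  clf0 <- fine_tune_stm(sep_instances()[sep_train_idx()],
                        config = tiny_encoder_config(seed = 7, epochs = 0L))
  p0 <- predict_proba(clf0, sep_instances()[sep_val_idx()])
  a0 <- auroc(sep_labels()[sep_val_idx()], p0)
  expect_gte(a0, 0.4)
  expect_lte(a0, 0.6)
  # learning sanity: training strictly improves over the untrained encoder
  expect_gt(stm_val_auroc(), a0)
  # same seed, identical scores
  clf2 <- fine_tune_stm(sep_instances()[sep_train_idx()],
                        config = tiny_encoder_config(seed = 7))
  p1 <- predict_proba(stm_fit(), sep_instances()[sep_val_idx()])
  p2 <- predict_proba(clf2, sep_instances()[sep_val_idx()])
  expect_identical(p1, p2)
  expect_error(fine_tune_stm(list()), "empty")
})

test_that("the MTM stays within the non-degradation band of the STM", {
  expect_gte(mtm_val_auroc(), stm_val_auroc() - 0.05)
  expect_error(fine_tune_mtm(list(name = "p",
                                  instances = sep_instances()[1:10]),
                             list()),
               "auxiliary")
  unlabeled <- lapply(sep_instances()[1:5], function(i) {
    i$label <- NA_character_; i
  })
  expect_error(fine_tune_mtm(list(name = "p", instances = unlabeled),
                             list(list(name = "a",
                                       instances = sep_instances()[1:5]))),
               "unlabeled")
})

test_that("scores are probabilities, order-preserving, and guarded", {
  clf <- stm_fit()
  val <- sep_instances()[sep_val_idx()]
  p <- predict_proba(clf, val)
  expect_true(all(p >= 0 & p <= 1))
  # permutation equivariance and duplicate stability
  perm <- rev(seq_along(val))
  expect_identical(predict_proba(clf, val[perm]), p[perm])
  expect_identical(predict_proba(clf, val[c(1, 1)]), p[c(1, 1)])
  # fuzz: random masked texts always score in [0,1]
  withr::with_seed(77, {
    fuzz <- replicate(200, paste(
      "@MIRNA$", paste(sample(letters, sample(1:8, 1), replace = TRUE),
                       collapse = " "), "@DISEASE$"))
  })
  pf <- predict_proba(clf, as.list(fuzz))
  expect_true(all(pf >= 0 & pf <= 1))
  broken <- masked_instance("@MIRNA$ x @DISEASE$")
  broken$masked_text <- "no placeholders"
  expect_error(predict_proba(clf, list(broken)), "placeholder")
  # the single-logit sigmoid head also yields probabilities
  sig <- fine_tune_stm(sep_instances()[1:60],
                       config = tiny_encoder_config(seed = 3, epochs = 2L,
                                                    head = "sigmoid1"))
  ps <- predict_proba(sig, val[1:10])
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("hyperparameter search honors budget, dominance and pruning", {
  # budget 1 returns that trial's configuration
  space1 <- hpo_space(list(lr = list(0.1)), budget = 1L)
  res1 <- optimize_hyperparameters(space1, function(params, report) 0.7,
                                   seed = 1)
  expect_equal(res1$best_params$lr, 0.1)
  expect_equal(res1$best_value, 0.7)
  expect_equal(nrow(res1$trials), 1L)

  # two-point grid with a deterministic dominant configuration
  space2 <- hpo_space(list(width = list(4, 16)), budget = 12L,
                      pruning = FALSE)
  res2 <- optimize_hyperparameters(
    space2, function(params, report) if (params$width == 16) 0.9 else 0.6,
    seed = 2)
  expect_equal(res2$best_params$width, 16)

  # pruned trials are logged and never win
  space3 <- hpo_space(list(q = list(1)), budget = 3L, pruning = TRUE)
  trial_values <- c(1.0, 0.1, 0.9)
  counter <- 0L
  res3 <- optimize_hyperparameters(space3, function(params, report) {
    counter <<- counter + 1L
    v <- trial_values[counter]
    report(1, v)   # the 0.1 trial falls below the running median here
    v
  }, seed = 3)
  expect_equal(res3$trials$state, c("completed", "pruned", "completed"))
  expect_equal(res3$best_value, 1.0)

  # all trials failing aggregates the failures
  expect_error(
    optimize_hyperparameters(space1, function(params, report)
      stop("boom"), seed = 4),
    "boom")
})
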