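# Entity-masked sentence classification of miRNA-disease relations.
#
# Each candidate (miRNA mention, disease mention) pair in a sentence becomes
# one masked instance: the two mentions are replaced by the atomic
# placeholder tokens "@MIRNA$" and "@DISEASE$" (all other mentions stay
# verbatim). A linear head over the pooled encoder output classifies the
# instance; STM trains one head, MTM trains one head per task over a shared
# encoder and scores with the primary head only.

MIRNA_PLACEHOLDER <- "@MIRNA$"
DISEASE_PLACEHOLDER <- "@DISEASE$"

#' Construct a masked relation instance
#'
#' @param masked_text sentence text with exactly one miRNA and one disease
#'   placeholder.
#' @param label `"positive"`, `"negative"` or `NA`.
#' @param provenance list carrying at least `instance_id`, `doc_id`,
#'   `sentence_text` and the masked mention spans, sufficient to reconstruct
#'   the original sentence.
#' @return object of class `mdx_masked`.
#' @export
masked_instance <- function(masked_text, label = NA_character_,
                            provenance = list()) {
  n_m <- lengths(regmatches(masked_text,
                            gregexpr(MIRNA_PLACEHOLDER, masked_text,
                                     fixed = TRUE)))
  n_d <- lengths(regmatches(masked_text,
                            gregexpr(DISEASE_PLACEHOLDER, masked_text,
                                     fixed = TRUE)))
  if (n_m != 1L || n_d != 1L) {
    stop_mirdex(
      "masked text must contain exactly one %s and one %s (found %d, %d)",
      MIRNA_PLACEHOLDER, DISEASE_PLACEHOLDER, n_m, n_d)
  }
  if (!is.na(label) && !label %in% c("positive", "negative")) {
    stop_mirdex("label must be positive, negative or NA")
  }
  structure(list(masked_text = masked_text, label = label,
                 provenance = provenance),
            class = "mdx_masked")
}

#' Build masked instances from a sentence
#'
#' One instance per (miRNA mention, disease mention) pair; only the pair's
#' two mentions are masked, the rest of the sentence (including other
#' mentions) is untouched. Returns an empty list when either class is
#' absent.
#'
#' @param s a [sentence()] carrying mentions.
#' @param doc_id document id recorded in provenance.
#' @return list of [masked_instance()] objects; length equals
#'   `#mirna * #disease` mentions.
#' @export
make_instances <- function(s, doc_id = "doc") {
  mirnas <- mentions_of(s, "mirna")
  diseases <- mentions_of(s, "disease")
  out <- list()
  for (mi in mirnas) {
    for (di in diseases) {
      spans <- list(list(start = mi$start, end = mi$end,
                         ph = MIRNA_PLACEHOLDER),
                    list(start = di$start, end = di$end,
                         ph = DISEASE_PLACEHOLDER))
      spans <- spans[order(-vapply(spans, `[[`, integer(1), "start"))]
      txt <- s$text
      for (sp in spans) {  # replace right-to-left so offsets stay valid
        txt <- paste0(substr(txt, 1L, sp$start),
                      sp$ph,
                      substr(txt, sp$end + 1L, nchar(txt)))
      }
      prov <- list(
        instance_id = paste(doc_id, mi$start, mi$end, di$start, di$end,
                            sep = "|"),
        doc_id = doc_id, sentence_text = s$text,
        mirna = mi, disease = di
      )
      out[[length(out) + 1L]] <- masked_instance(txt, provenance = prov)
    }
  }
  out
}

#' Reconstruct the original sentence of a masked instance
#'
#' @param mi a [masked_instance()] with full provenance.
#' @return the unmasked sentence text.
#' @export
unmask_instance <- function(mi) {
  mi$provenance$sentence_text
}

# ---- training ---------------------------------------------------------

prepare_relation_instance <- function(mi, config) {
  tk <- word_tokenize(mi$masked_text)
  al <- unlist(subtoken_map(tk$tokens), use.names = FALSE)
  ids <- subtoken_ids(al, config$vocab_size)
  if (length(ids) > config$max_length) ids <- ids[seq_len(config$max_length)]
  y <- if (is.na(mi$label)) NA_integer_
       else if (mi$label == "positive") 2L else 1L
  list(ids = ids, y = y)
}

new_cls_head <- function(config) {
  k <- if (config$head == "sigmoid1") 1L else 2L
  list(W = matrix(stats::rnorm(k * config$out_dim, sd = 0.2), k,
                  config$out_dim),
       b = numeric(k))
}

pool_forward <- function(Z, pooling) {
  if (pooling == "first") Z[1L, ] else colMeans(Z)
}

pool_backward <- function(dpool, Tn, pooling) {
  if (pooling == "first") {
    dZ <- matrix(0, Tn, length(dpool))
    dZ[1L, ] <- dpool
    dZ
  } else {
    matrix(rep(dpool / Tn, each = Tn), Tn, length(dpool))
  }
}

# positive-class probability and dlogits for one instance
cls_forward <- function(head, pooled, config) {
  logits <- as.numeric(head$W %*% pooled + head$b)
  if (config$head == "sigmoid1") {
    p <- 1 / (1 + exp(-logits))
    list(p_pos = p, logits = logits)
  } else {
    pr <- softmax(matrix(logits, 1L))
    list(p_pos = pr[1L, 2L], logits = logits)
  }
}

# gradient of the cross-entropy loss wrt logits; y: 1 = negative, 2 = positive
cls_dlogits <- function(fwd, y, config) {
  if (config$head == "sigmoid1") {
    fwd$p_pos - (y == 2L)
  } else {
    pr <- softmax(matrix(fwd$logits, 1L))[1L, ]
    tgt <- c(0, 0); tgt[y] <- 1
    pr - tgt
  }
}

train_relation_heads <- function(tasks, config) {
  # tasks: named list of lists(prep = per-instance prep with task tag)
  with_seed(config$seed, {
    enc <- encoder_init(config)
    heads <- lapply(tasks, function(t) new_cls_head(config))
    schedule <- do.call(rbind, lapply(seq_along(tasks), function(ti) {
      cbind(task = ti, idx = seq_along(tasks[[ti]]))
    }))
    opt_enc <- adam_init(enc$params)
    opt_heads <- lapply(heads, adam_init)
    n <- nrow(schedule)
    bs <- max(1L, config$batch_size)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)   # proportional task mixing within each epoch
      for (b0 in seq(1L, n, by = bs)) {
        rows <- perm[b0:min(b0 + bs - 1L, n)]
        g_enc <- zero_grads(enc$params)
        g_heads <- lapply(heads, zero_grads)
        m <- length(rows)
        for (r in rows) {
          ti <- schedule[r, "task"]
          p <- tasks[[ti]][[schedule[r, "idx"]]]
          fw <- encoder_forward(enc, p$ids)
          pooled <- pool_forward(fw$Z, config$pooling)
          cf <- cls_forward(heads[[ti]], pooled, config)
          dlog <- cls_dlogits(cf, p$y, config) / m
          g_heads[[ti]]$W <- g_heads[[ti]]$W + outer(dlog, pooled)
          g_heads[[ti]]$b <- g_heads[[ti]]$b + dlog
          dpool <- as.numeric(t(heads[[ti]]$W) %*% dlog)
          dZ <- pool_backward(dpool, length(p$ids), config$pooling)
          g_enc <- encoder_backward(enc, fw$cache, dZ, g_enc)
        }
        st <- adam_step(enc$params, g_enc, opt_enc, config$learning_rate)
        enc$params <- st$params; opt_enc <- st$state
        for (ti in seq_along(heads)) {
          st <- adam_step(heads[[ti]], g_heads[[ti]], opt_heads[[ti]],
                          config$learning_rate)
          heads[[ti]] <- st$params; opt_heads[[ti]] <- st$state
        }
      }
    }
    list(encoder = enc, heads = heads)
  })
}

check_task_labels <- function(instances, what) {
  labs <- vapply(instances, `[[`, character(1), "label")
  if (anyNA(labs)) {
    stop_mirdex("%s contains unlabeled instances", what)
  }
  if (!all(labs %in% c("positive", "negative"))) {
    stop_mirdex("%s has labels outside {positive, negative}", what)
  }
  invisible(labs)
}

#' Fine-tune a single-task relation classifier (STM)
#'
#' Trains the shared encoder plus one linear classification head on labeled
#' masked instances. Deterministic for fixed `config$seed`; `epochs = 0`
#' returns the untrained (randomly initialized) classifier whose scores are
#' near chance.
#'
#' @param train_instances non-empty list of labeled [masked_instance()]s.
#' @param val_instances optional validation instances (not used for
#'   early stopping; available to callers for model selection).
#' @param config an [tiny_encoder_config()].
#' @return object of class `mdx_relation_classifier` exposing
#'   [predict_proba()].
#' @export
fine_tune_stm <- function(train_instances, val_instances = NULL,
                          config = tiny_encoder_config()) {
  if (!length(train_instances)) stop_mirdex("empty training set")
  check_task_labels(train_instances, "training set")
  prep <- lapply(train_instances, prepare_relation_instance, config = config)
  fit <- train_relation_heads(list(primary = prep), config)
  structure(list(encoder = fit$encoder, head = fit$heads$primary,
                 config = config, mode = "STM"),
            class = "mdx_relation_classifier")
}

#' Fine-tune a multi-task relation classifier (MTM)
#'
#' One shared encoder updated by every task's head; batches mix tasks in
#' proportion to their sizes within each epoch (seed-controlled order). The
#' returned classifier scores with the primary head only.
#'
#' @param primary list with elements `name` and `instances` (labeled
#'   [masked_instance()]s) for the task of interest.
#' @param auxiliary non-empty list of further tasks in the same form; every
#'   task must carry binary positive/negative labels.
#' @param config an [tiny_encoder_config()].
#' @return `mdx_relation_classifier` for the primary task.
#' @export
fine_tune_mtm <- function(primary, auxiliary, config = tiny_encoder_config()) {
  if (!length(auxiliary)) {
    stop_mirdex("MTM requires at least one auxiliary task")
  }
  tasks <- c(list(primary), auxiliary)
  names(tasks) <- vapply(seq_along(tasks), function(i) {
    tasks[[i]]$name %||% paste0("task", i)
  }, character(1))
  preps <- lapply(tasks, function(t) {
    check_task_labels(t$instances,
                      sprintf("task '%s'", t$name %||% "?"))
    lapply(t$instances, prepare_relation_instance, config = config)
  })
  fit <- train_relation_heads(preps, config)
  structure(list(encoder = fit$encoder, head = fit$heads[[1L]],
                 config = config, mode = "MTM",
                 task_names = names(tasks)),
            class = "mdx_relation_classifier")
}

#' @export
print.mdx_relation_classifier <- function(x, ...) {
  cat(sprintf("<%s relation classifier: %s head, pooling=%s>\n",
              x$mode, x$config$head, x$config$pooling))
  invisible(x)
}

#' Score masked instances
#'
#' Returns the positive-class probability for each instance (softmax over
#' two logits by default, or a single logit through a sigmoid with
#' `head = "sigmoid1"`). Order-preserving; an instance missing a
#' placeholder is an error.
#'
#' @param classifier an `mdx_relation_classifier`.
#' @param instances list of [masked_instance()]s (or character vector of
#'   masked texts).
#' @return numeric vector of probabilities in `[0,1]`.
#' @export
predict_proba <- function(classifier, instances) {
  config <- classifier$config
  vapply(instances, function(mi) {
    if (is.character(mi)) mi <- masked_instance(mi)
    if (!inherits(mi, "mdx_masked")) {
      stop_mirdex("predict_proba expects masked instances")
    }
    # re-validate placeholders (instances may have been edited)
    if (!grepl(MIRNA_PLACEHOLDER, mi$masked_text, fixed = TRUE) ||
        !grepl(DISEASE_PLACEHOLDER, mi$masked_text, fixed = TRUE)) {
      stop_mirdex("instance is missing an entity placeholder")
    }
    p <- prepare_relation_instance(mi, config)
    fw <- encoder_forward(classifier$encoder, p$ids)
    pooled <- pool_forward(fw$Z, config$pooling)
    cls_forward(classifier$head, pooled, config)$p_pos
  }, numeric(1))
}

# ---- hyperparameter optimization hook ---------------------------------

#' Define a hyperparameter search space
#'
#' @param params named list; each element is either a length-2 numeric
#'   `c(min, max)` range (sampled uniformly, on a log scale if
#'   `log = TRUE` is attached via [log_range()]) or a list/vector of
#'   discrete choices.
#' @param objective `"auroc"` or `"f1"` (maximized).
#' @param budget number of trials (>= 1).
#' @param pruning enable the median pruner on intermediate reports.
#' @return a list of class `hpo_space`.
#' @export
hpo_space <- function(params, objective = c("auroc", "f1"), budget = 10L,
                      pruning = TRUE) {
  if (!length(params)) stop_mirdex("empty search space")
  if (budget < 1L) stop_mirdex("budget must be >= 1")
  structure(list(params = params, objective = match.arg(objective),
                 budget = as.integer(budget), pruning = isTRUE(pruning)),
            class = "hpo_space")
}

#' Mark a numeric range as log-uniform
#' @param min,max positive range bounds.
#' @return range vector with a `log` attribute.
#' @export
log_range <- function(min, max) {
  structure(c(min, max), log = TRUE)
}

sample_params <- function(space) {
  lapply(space$params, function(p) {
    if (is.list(p) || length(p) != 2L || !is.numeric(p)) {
      return(p[[sample.int(length(p), 1L)]])
    }
    if (isTRUE(attr(p, "log"))) {
      exp(stats::runif(1L, log(p[1]), log(p[2])))
    } else if (is.integer(p)) {
      sample(seq(p[1], p[2]), 1L)
    } else {
      stats::runif(1L, p[1], p[2])
    }
  })
}

#' Random-search hyperparameter optimization with median pruning
#'
#' Implements the suggest/report/prune contract: each trial receives sampled
#' parameters and a `report(step, value)` callback. With pruning enabled, a
#' trial whose intermediate value falls below the median of earlier trials
#' at the same step is halted; pruned or failed trials are never returned as
#' best. Deterministic under `seed`.
#'
#' @param space an [hpo_space()].
#' @param trainer function `(params, report) -> objective value` that trains
#'   and evaluates one configuration, optionally calling `report` at
#'   intermediate steps.
#' @param seed integer seed for the parameter sampler.
#' @return list with `best_params`, `best_value` and `trials` (a data frame
#'   log with one row per trial: id, parameters as JSON, objective, state).
#' @export
optimize_hyperparameters <- function(space, trainer, seed = 1L) {
  stopifnot(inherits(space, "hpo_space"))
  history <- list()   # per step: numeric vector of reported values
  trials <- data.frame(trial = integer(), params = character(),
                       value = numeric(), state = character(),
                       stringsAsFactors = FALSE)
  best_params <- NULL; best_value <- -Inf
  failures <- character()
  with_seed(seed, {
    for (tr in seq_len(space$budget)) {
      params <- sample_params(space)
      pruned <- FALSE
      report <- function(step, value) {
        key <- as.character(step)
        prior <- history[[key]] %||% numeric()
        history[[key]] <<- c(prior, value)
        if (space$pruning && length(prior) >= 1L &&
            value < stats::median(prior)) {
          pruned <<- TRUE
          stop(structure(class = c("mdx_prune", "condition"),
                         list(message = "pruned", call = NULL)))
        }
        invisible(value)
      }
      value <- tryCatch(
        trainer(params, report),
        mdx_prune = function(e) NA_real_,
        error = function(e) {
          failures <<- c(failures, conditionMessage(e))
          NA_real_
        }
      )
      state <- if (pruned) "pruned"
               else if (is.na(value)) "failed"
               else "completed"
      trials <- rbind(trials, data.frame(
        trial = tr,
        params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
        value = if (state == "completed") value else NA_real_,
        state = state, stringsAsFactors = FALSE))
      if (state == "completed" && value > best_value) {
        best_value <- value
        best_params <- params
      }
    }
  })
  if (is.null(best_params)) {
    stop_mirdex("all %d trial(s) failed or were pruned%s", space$budget,
                if (length(failures)) {
                  paste0(": ", paste(unique(failures), collapse = "; "))
                } else "")
  }
  list(best_params = best_params, best_value = best_value, trials = trials)
}
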