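# Evaluation: entity-level NER metrics, threshold-free binary-classification
# metrics, confusion counts, stratified k-fold cross-validation.

prf_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0   # 0/0 convention: 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

mention_key <- function(m) paste(m$start, m$end, m$entity_class, sep = "|")

#' Entity-level precision, recall and F1
#'
#' Exact matching by default: a predicted mention counts as a true positive
#' iff a gold mention with identical (start, end, class) exists in the same
#' sentence. `matching = "overlap"` relaxes this to any same-class span
#' overlap (greedy one-to-one). Per-class scores plus a micro average that
#' pools tp/fp/fn over classes. Degenerate 0/0 ratios are reported as 0.
#'
#' @param gold,predicted lists (one element per sentence) of [mention()]
#'   lists.
#' @param matching `"exact"` (default) or `"overlap"`.
#' @return list with `per_class` (data frame) and `micro` (named list).
#' @export
ner_prf <- function(gold, predicted, matching = c("exact", "overlap")) {
  matching <- match.arg(matching)
  if (length(gold) != length(predicted)) {
    stop_mirdex("gold and predicted must have one element per sentence")
  }
  classes <- unique(c(
    unlist(lapply(gold, function(s)
      vapply(s, `[[`, character(1), "entity_class"))),
    unlist(lapply(predicted, function(s)
      vapply(s, `[[`, character(1), "entity_class")))))
  if (!length(classes)) classes <- character()
  counts <- stats::setNames(
    rep(list(c(tp = 0L, fp = 0L, fn = 0L)), length(classes)), classes)
  for (i in seq_along(gold)) {
    for (cls in classes) {
      g <- Filter(function(m) m$entity_class == cls, gold[[i]])
      p <- Filter(function(m) m$entity_class == cls, predicted[[i]])
      if (matching == "exact") {
        gk <- vapply(g, mention_key, character(1))
        pk <- vapply(p, mention_key, character(1))
        tp <- length(intersect(gk, pk))
        counts[[cls]] <- counts[[cls]] +
          c(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
      } else {
        used <- logical(length(g))
        tp <- 0L
        for (pm in p) {
          hit <- which(!used & vapply(g, function(gm) {
            pm$start < gm$end && gm$start < pm$end
          }, logical(1)))
          if (length(hit)) { used[hit[1]] <- TRUE; tp <- tp + 1L }
        }
        counts[[cls]] <- counts[[cls]] +
          c(tp = tp, fp = length(p) - tp, fn = length(g) - tp)
      }
    }
  }
  per_class <- do.call(rbind, lapply(classes, function(cls) {
    x <- prf_from_counts(unname(counts[[cls]]["tp"]),
                         unname(counts[[cls]]["fp"]),
                         unname(counts[[cls]]["fn"]))
    data.frame(class = cls, precision = x$precision, recall = x$recall,
               f1 = x$f1, tp = x$tp, fp = x$fp, fn = x$fn,
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  tot <- Reduce(`+`, counts, c(tp = 0L, fp = 0L, fn = 0L))
  list(per_class = per_class,
       micro = prf_from_counts(unname(tot["tp"]), unname(tot["fp"]),
                               unname(tot["fn"])))
}

as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative"))) {
      stop_mirdex("character labels must be positive/negative")
    }
    return(as.integer(labels == "positive"))
  }
  if (!all(labels %in% c(0, 1))) stop_mirdex("labels must be binary")
  as.integer(labels)
}

#' Binary confusion counts
#'
#' @param labels,predicted parallel binary vectors (logical, 0/1 or
#'   `"positive"`/`"negative"`).
#' @return named integer vector `tp`, `fp`, `fn`, `tn` summing to
#'   `length(labels)`.
#' @export
confusion_matrix <- function(labels, predicted) {
  y <- as_binary(labels); p <- as_binary(predicted)
  if (length(y) != length(p)) {
    stop_mirdex("labels (%d) and predictions (%d) differ in length",
                length(y), length(p))
  }
  c(tp = sum(y == 1L & p == 1L), fp = sum(y == 0L & p == 1L),
    fn = sum(y == 1L & p == 0L), tn = sum(y == 0L & p == 0L))
}

#' Area under the ROC curve
#'
#' Computed from ranks (Mann-Whitney statistic), which equals the
#' probability that a random positive outscores a random negative with ties
#' counted as one half.
#'
#' @param labels binary labels with at least one positive and one negative.
#' @param scores parallel numeric scores.
#' @return AUROC in `[0,1]`.
#' @export
auroc <- function(labels, scores) {
  y <- as_binary(labels)
  if (length(y) != length(scores)) stop_mirdex("length mismatch")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_mirdex("AUROC needs both a positive and a negative example")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise (non-interpolated) average precision: thresholds at every
#' distinct score, AP = sum over thresholds of
#' (recall step) x (precision at that threshold). Invariant under strictly
#' monotone score transforms.
#'
#' @param labels binary labels with at least one positive.
#' @param scores parallel numeric scores.
#' @return AUPR in `[0,1]`.
#' @export
aupr <- function(labels, scores) {
  y <- as_binary(labels)
  if (length(y) != length(scores)) stop_mirdex("length mismatch")
  P <- sum(y == 1L)
  if (P == 0L) stop_mirdex("AUPR needs at least one positive example")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # cumulative counts at the end of each tie group
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(y)[grp_end]
  cn <- grp_end
  prev_tp <- c(0L, ctp[-length(ctp)])
  sum((ctp - prev_tp) * (ctp / cn)) / P
}

#' Stratified k-fold cross-validation
#'
#' Folds are disjoint, cover the corpus and preserve label proportions per
#' fold; assignment is deterministic for a fixed seed. For each fold the
#' trainer is fit on the other k-1 folds and the metric evaluated on the
#' held-out fold; the mean and standard deviation over folds are reported.
#'
#' @param instances list of labeled instances (each with a `label` field) or
#'   a data frame with a `label` column.
#' @param k number of folds (>= 2); every label must occur at least k times.
#' @param seed integer seed for fold assignment.
#' @param trainer function `(train, val) -> model`.
#' @param metric function `(model, val) -> numeric`.
#' @return list of class `cv_report`: `per_fold`, `mean`, `sd`, `k`,
#'   `seed`, `folds` (assignment vector).
#' @export
cross_validate <- function(instances, k, seed, trainer, metric) {
  if (k < 2L) stop_mirdex("k must be >= 2")
  labels <- if (is.data.frame(instances)) {
    instances$label
  } else {
    vapply(instances, function(x) as.character(x$label %||% x[["label"]]),
           character(1))
  }
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop_mirdex("label '%s' occurs %d time(s), fewer than k = %d folds",
                names(tab)[which.min(tab)], min(tab), k)
  }
  folds <- integer(n)
  with_seed(seed, {
    for (lab in names(tab)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  subset_at <- function(sel) {
    if (is.data.frame(instances)) instances[sel, , drop = FALSE]
    else instances[sel]
  }
  per_fold <- vapply(seq_len(k), function(f) {
    model <- trainer(subset_at(folds != f), subset_at(folds == f))
    metric(model, subset_at(folds == f))
  }, numeric(1))
  structure(list(per_fold = per_fold, mean = mean(per_fold),
                 sd = stats::sd(per_fold), k = as.integer(k),
                 seed = as.integer(seed), folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: %.4f +/- %.4f\n", x$k, x$mean, x$sd))
  invisible(x)
}

#' Write a metric report to JSON or TSV
#'
#' @param report a named list or data frame of metric values.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    df <- if (is.data.frame(report)) report else {
      data.frame(metric = names(report),
                 value = vapply(report, function(v)
                   paste(format(v), collapse = ","), character(1)))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
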