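# A small trainable text encoder satisfying the contract used by the tagging
# and relation modules: text -> one vector per subtoken. Architecture:
# subtoken embeddings -> context-window concatenation (previous/current/next)
# -> dense tanh layer -> dense tanh layer. Gradients are written out
# explicitly; parameters are updated with Adam. All training entry points are
# seeded and restore the caller's RNG.
#
# Any object implementing `encoder_forward(enc, ids)` returning a
# `length(ids) x out_dim` matrix (plus a backward pass for training) can be
# substituted; the pipeline only relies on this contract.

#' Word-level tokenizer with character spans
#'
#' Splits text into word tokens (keeping internal hyphens and slashes, so
#' `"miR-501-3p"` is one token), entity placeholder tokens (`"@MIRNA$"`,
#' `"@DISEASE$"`) and single punctuation marks.
#'
#' @param text a single string.
#' @return list with `tokens` (character) and `spans`
#'   (`n x 2` integer matrix of 0-based half-open offsets).
#' @export
word_tokenize <- function(text) {
  pat <- "@[A-Z]+\\$|[A-Za-z0-9]+(?:[-/'][A-Za-z0-9]+)*|[^A-Za-z0-9@\\s]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(tokens = character(),
                spans = matrix(integer(), ncol = 2)))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  list(tokens = regmatches(text, list(m))[[1]],
       spans = cbind(starts, starts + lens))
}

.PLACEHOLDER_IDS <- c("@MIRNA$" = 1L, "@DISEASE$" = 2L)

# split one word token into subtokens: placeholders stay atomic, other
# tokens are case-folded, split at hyphens/slashes, then chunked to <= 4
# characters (a fixed wordpiece-like scheme with a hashed vocabulary).
subtokenize_token <- function(token) {
  if (token %in% names(.PLACEHOLDER_IDS)) return(token)
  pieces <- strsplit(tolower(token), "[-/]")[[1]]
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) pieces <- token
  unlist(lapply(pieces, function(p) {
    n <- nchar(p)
    if (n <= 4L) return(p)
    starts <- seq(1L, n, by = 4L)
    substring(p, starts, pmin(starts + 3L, n))
  }), use.names = FALSE)
}

#' Map each token of a sentence to its subtokens
#'
#' @param tokens character vector of word tokens.
#' @return list (one element per token) of character subtoken vectors; every
#'   token maps to at least one subtoken.
#' @export
subtoken_map <- function(tokens) {
  lapply(tokens, subtokenize_token)
}

# deterministic string hash into [from, to]
hash_id <- function(s, from, to) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% (to - from + 1L)
  as.integer(h) + from
}

subtoken_ids <- function(subtokens, vocab_size) {
  vapply(subtokens, function(s) {
    ph <- .PLACEHOLDER_IDS[s]
    if (!is.na(ph)) return(unname(ph))
    hash_id(s, 3L, vocab_size)
  }, integer(1), USE.NAMES = FALSE)
}

#' Default configuration of the small encoder
#'
#' A 2-layer, small-width, hashed-vocabulary encoder that trains on a single
#' CPU in seconds to minutes; the desk-scale stand-in for large pretrained
#' transformer encoders. Deterministic under `seed`.
#'
#' @param vocab_size hashed subtoken vocabulary size.
#' @param dim embedding width.
#' @param hidden width of the first dense layer.
#' @param out_dim per-subtoken output width.
#' @param max_length maximum subtoken sequence length; longer inputs are
#'   truncated (with a warning counter at prediction time).
#' @param learning_rate,epochs,batch_size training hyperparameters.
#' @param pooling sentence pooling for classification: `"mean"` (default) or
#'   `"first"`.
#' @param head classifier head: `"softmax2"` (two logits, default) or
#'   `"sigmoid1"` (single logit through a sigmoid).
#' @param seed integer seed controlling initialization and batch order.
#' @return a named list of class `encoder_config`.
#' @export
tiny_encoder_config <- function(vocab_size = 521L, dim = 24L, hidden = 32L,
                                out_dim = 32L, max_length = 96L,
                                learning_rate = 0.01, epochs = 12L,
                                batch_size = 16L,
                                pooling = c("mean", "first"),
                                head = c("softmax2", "sigmoid1"),
                                seed = 42L) {
  structure(list(
    vocab_size = as.integer(vocab_size), dim = as.integer(dim),
    hidden = as.integer(hidden), out_dim = as.integer(out_dim),
    max_length = as.integer(max_length),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    pooling = match.arg(pooling), head = match.arg(head),
    seed = as.integer(seed)
  ), class = "encoder_config")
}

# parameter initialization (call inside with_seed)
encoder_init <- function(config) {
  rn <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.2), r, c)
  structure(list(
    params = list(
      E  = rn(config$vocab_size, config$dim),
      W1 = rn(config$hidden, 3L * config$dim),
      b1 = numeric(config$hidden),
      W2 = rn(config$out_dim, config$hidden),
      b2 = numeric(config$out_dim)
    ),
    config = config
  ), class = "tiny_encoder")
}

# forward pass: ids -> list(Z = T x out_dim, cache for backward)
encoder_forward <- function(enc, ids) {
  p <- enc$params
  Tn <- length(ids)
  emb <- p$E[ids, , drop = FALSE]
  d <- enc$config$dim
  zero <- matrix(0, 1L, d)
  prev <- rbind(zero, emb[-Tn, , drop = FALSE])
  nxt  <- rbind(emb[-1L, , drop = FALSE], zero)
  if (Tn == 1L) { prev <- zero; nxt <- zero }
  C <- cbind(prev, emb, nxt)
  H1 <- tanh(sweep(C %*% t(p$W1), 2L, p$b1, `+`))
  Z  <- tanh(sweep(H1 %*% t(p$W2), 2L, p$b2, `+`))
  list(Z = Z, cache = list(ids = ids, C = C, H1 = H1, Z = Z))
}

# backward pass: accumulate parameter gradients into `grads` given dL/dZ
encoder_backward <- function(enc, cache, dZ, grads) {
  p <- enc$params
  d <- enc$config$dim
  Tn <- length(cache$ids)
  dA2 <- dZ * (1 - cache$Z^2)
  grads$W2 <- grads$W2 + t(dA2) %*% cache$H1
  grads$b2 <- grads$b2 + colSums(dA2)
  dH1 <- dA2 %*% p$W2
  dA1 <- dH1 * (1 - cache$H1^2)
  grads$W1 <- grads$W1 + t(dA1) %*% cache$C
  grads$b1 <- grads$b1 + colSums(dA1)
  dC <- dA1 %*% p$W1
  ids <- cache$ids
  add_rows <- function(M, rows, contrib) {
    agg <- rowsum(contrib, group = rows)
    idx <- as.integer(rownames(agg))
    M[idx, ] <- M[idx, , drop = FALSE] + agg
    M
  }
  # column blocks of dC: [1..d] previous token, [d+1..2d] current,
  # [2d+1..3d] next token
  grads$E <- add_rows(grads$E, ids, dC[, d + seq_len(d), drop = FALSE])
  if (Tn > 1L) {
    grads$E <- add_rows(grads$E, ids[-Tn],
                        dC[-1L, seq_len(d), drop = FALSE])
    grads$E <- add_rows(grads$E, ids[-1L],
                        dC[-Tn, 2L * d + seq_len(d), drop = FALSE])
  }
  grads
}

zero_grads <- function(params) {
  lapply(params, function(p) { p[] <- 0; p })
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# softmax rows
softmax <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}
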