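# Pluggable text encoder.
#
# The classifier track only requires an object honouring the encoder
# contract: a tokenizer producing integer token ids with sequence-start [CLS]
# and separator [SEP] marker tokens, and an embedding function mapping one
# token-id window to a fixed-dimension vector. The reference configuration is
# a 12-layer, 12-head, 110M-parameter pretrained encoder with 768-dimensional
# output; the package ships a small randomly initialized single-head
# self-attention encoder with the same interface so everything runs and is
# tested without downloads. Pretrained weights are an opt-in drop-in via the
# same contract.

PAD_ID <- 1L
CLS_ID <- 2L
SEP_ID <- 3L
N_SPECIAL <- 3L

#' Tokenize note text
#'
#' Lower-cases and splits on non-alphanumeric characters; purely lexical, no
#' vocabulary needed.
#'
#' @param text A single string.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- stringr::str_extract_all(tolower(text), "[a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Deterministic token -> id hashing into (N_SPECIAL, vocab_size].
hash_tokens <- function(tokens, vocab_size) {
  m <- vocab_size - N_SPECIAL
  purrr::map_int(tokens, function(tok) {
    h <- 0
    for (c in utf8ToInt(tok)) h <- (h * 31 + c) %% m
    as.integer(h + N_SPECIAL + 1L)
  })
}

#' Small randomly initialized transformer encoder (test fixture)
#'
#' A single-head scaled-dot-product self-attention block with residual
#' connection over hashed token embeddings; window embedding is the masked
#' mean of the contextualized token vectors. Deterministic given `seed`;
#' embedding dimension is constant across windows. Intended as the
#' desk-scale stand-in for a pretrained encoder -- it carries no language
#' knowledge at initialization, but its embeddings (and attention weights)
#' are trainable when the classifier is configured to fine-tune.
#'
#' @param dim Embedding dimension (reference encoders use 768; the fixture
#'   defaults to 32).
#' @param vocab_size Hashed vocabulary size including the 3 special ids
#'   (PAD/CLS/SEP).
#' @param seed Integer seed for weight initialization.
#' @return A `perio_encoder` object.
#' @export
fixture_encoder <- function(dim = 32, vocab_size = 1024, seed = 1L) {
  stopifnot(dim >= 2, vocab_size > N_SPECIAL + 1)
  params <- with_seed(seed, list(
    E = matrix(rnorm(vocab_size * dim, sd = 0.5), vocab_size, dim),
    Wq = init_matrix(dim, dim), Wk = init_matrix(dim, dim),
    Wv = init_matrix(dim, dim)
  ))
  params$E[PAD_ID, ] <- 0
  structure(list(dim = dim, vocab_size = vocab_size, params = params,
                 seed = as.integer(seed)),
            class = "perio_encoder")
}

#' @export
print.perio_encoder <- function(x, ...) {
  cat("<perio_encoder> dim ", x$dim, ", vocab ", x$vocab_size,
      ", single-head self-attention, random init (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Partition a note into fixed-length token windows
#'
#' Tokens are hashed to ids and split into consecutive non-overlapping
#' windows of `window_length` content tokens; each window is wrapped in
#' [CLS]/[SEP] markers and the final window is right-padded. A padding mask
#' accompanies every window. Concatenating the windows and stripping marker
#' and pad ids recovers the token-id sequence exactly.
#'
#' @param text Note text (single string).
#' @param encoder A `perio_encoder` (supplies the hashing vocabulary).
#' @param window_length Content tokens per window (default 100).
#' @return List with integer matrices `ids` and `mask`, one row per window,
#'   `window_length + 2` columns.
#' @export
window_note <- function(text, encoder, window_length = 100) {
  stopifnot(window_length >= 1)
  ids <- hash_tokens(tokenize_text(text), encoder$vocab_size)
  if (length(ids) == 0) {
    abort("empty tokenization: note has no tokens")
  }
  n_win <- ceiling(length(ids) / window_length)
  width <- window_length + 2L
  mat <- matrix(PAD_ID, n_win, width)
  mask <- matrix(0L, n_win, width)
  for (i in seq_len(n_win)) {
    chunk <- ids[((i - 1) * window_length + 1):min(i * window_length, length(ids))]
    row <- c(CLS_ID, chunk, SEP_ID)
    mat[i, seq_along(row)] <- row
    mask[i, seq_along(row)] <- 1L
  }
  list(ids = mat, mask = mask)
}

# --- encoder forward/backward -----------------------------------------------

# One window: ids/mask integer vectors. Returns embedding + cache.
encoder_forward <- function(params, ids, mask) {
  X <- params$E[ids, , drop = FALSE]
  d <- ncol(X)
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  S <- (Q %*% t(K)) / sqrt(d)
  S[, mask == 0] <- -1e9
  A <- softmax_rows(S)
  H <- A %*% V
  Z <- X + H
  nm <- sum(mask)
  z <- colSums(Z * mask) / nm
  list(z = z, X = X, Q = Q, K = K, V = V, A = A, ids = ids, mask = mask,
       nm = nm)
}

# Backward through one window given dz (gradient w.r.t. the embedding).
# Returns gradients for E (dense matrix), Wq, Wk, Wv.
encoder_backward <- function(params, cache, dz, train_attention = TRUE) {
  d <- length(dz)
  dZ <- (cache$mask / cache$nm) %o% dz
  dX <- dZ
  dH <- dZ
  dA <- dH %*% t(cache$V)
  dV <- t(cache$A) %*% dH
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dS <- dS / sqrt(d)
  dQ <- dS %*% cache$K
  dK <- t(dS) %*% cache$Q
  dX <- dX + dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  out <- list(E = rowsum_into(dX, cache$ids, nrow(params$E)))
  if (train_attention) {
    out$Wq <- t(cache$X) %*% dQ
    out$Wk <- t(cache$X) %*% dK
    out$Wv <- t(cache$X) %*% dV
  }
  out
}

# Scatter-add rows of dX into a vocab_size x dim gradient matrix.
rowsum_into <- function(dX, ids, vocab_size) {
  g <- matrix(0, vocab_size, ncol(dX))
  s <- rowsum(dX, group = ids)
  g[as.integer(rownames(s)), ] <- s
  g
}
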