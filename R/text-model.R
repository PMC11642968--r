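# Long-text track: window the note, embed each window with the encoder,
# aggregate window embeddings with an LSTM, classify with a dense + dropout +
# softmax head. Trained with Adam, per-example losses multiplied by balanced
# class weights, exponential learning-rate decay, and early stopping on
# validation loss with best-weight restoration.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the text classifier
#'
#' Defaults mirror the reference configuration: 100-token windows, dropout
#' 0.2, 64 dense units, ReLU, Adam at learning rate 5e-6 with a 0.97
#' per-epoch exponential decay, 40 epochs, batch size 20, 80% training
#' fraction, balanced class weights, early stopping on validation loss with
#' best-weight restoration. The reference learning rate suits fine-tuning a
#' large pretrained encoder; with the small randomly initialized fixture
#' encoder, pass a proportionally larger rate (the package's own experiments
#' use 0.01). `momentum` is recorded for completeness but unused: Adam has no
#' classical momentum parameter.
#'
#' @param window_length Content tokens per window.
#' @param lstm_units LSTM hidden size (aggregator over windows).
#' @param decay_rate Per-epoch exponential learning-rate decay factor.
#' @param dropout_rate Dropout probability on the dense layer.
#' @param dense_units Units in the dense ReLU layer.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size Training schedule.
#' @param train_fraction Train share of the data at the pipeline level.
#' @param val_fraction Fraction of the training portion carved out
#'   (stratified) as the early-stopping validation set.
#' @param patience Early-stopping patience in epochs.
#' @param class_weighting `"balanced"` (w_k = n / (K n_k)) or `"none"`.
#' @param fine_tune Train the encoder's embeddings and attention weights
#'   alongside the classifier head.
#' @param momentum Recorded, unused (see above).
#' @param seed Integer seed for initialization, batching and dropout.
#' @return A `perio_text_config` list.
#' @export
text_train_config <- function(window_length = 100, lstm_units = 32,
                              decay_rate = 0.97, dropout_rate = 0.2,
                              dense_units = 64, learning_rate = 5e-6,
                              epochs = 40, batch_size = 20,
                              train_fraction = 0.8, val_fraction = 0.2,
                              patience = 5, class_weighting = "balanced",
                              fine_tune = TRUE, momentum = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(window_length >= 1, lstm_units >= 1, dense_units >= 1,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            epochs >= 1, batch_size >= 1, patience >= 1,
            train_fraction > 0, train_fraction < 1,
            val_fraction > 0, val_fraction < 1,
            class_weighting %in% c("balanced", "none"))
  structure(cfg, class = c("perio_text_config", "list"))
}

#' Balanced class weights
#'
#' `w_k = n / (K * n_k)` for class counts `n_k` over `K` classes, so that
#' `sum(w_k * n_k) = n` exactly and rare classes carry proportionally larger
#' per-example loss.
#'
#' @param labels Integer class labels coded `1..K`.
#' @param K Number of classes (default `max(labels)`).
#' @return Numeric vector of `K` weights.
#' @export
#' @examples
#' compute_class_weights(c(1, 1, 2), K = 2) # 0.75, 1.5
compute_class_weights <- function(labels, K = max(labels)) {
  counts <- tabulate(as.integer(labels), nbins = K)
  if (any(counts == 0)) {
    abort("every class must be present at least once",
          class = "periodx_config_error")
  }
  length(labels) / (K * counts)
}

#' Build the windowed-encoder text classifier
#'
#' Architecture: per-window encoder embeddings -> LSTM aggregation over the
#' window sequence -> dense(`dense_units`, ReLU) -> dropout -> softmax over
#' `K` classes.
#'
#' @param encoder A `perio_encoder` (see [fixture_encoder()]); any object
#'   with the same contract works.
#' @param K Number of classes (4 for stage, 3 for grade).
#' @param config A [text_train_config()].
#' @return An unfitted `perio_text_model`.
#' @export
build_text_model <- function(encoder, K, config = text_train_config()) {
  if (!is.numeric(K) || K < 2) abort("K must be at least 2")
  d <- encoder$dim
  h <- config$lstm_units
  params <- with_seed(derive_seed(config$seed, "text-init"), list(
    Wx = init_matrix(d, 4 * h), Wh = init_matrix(h, 4 * h) * 0.1,
    b = rep(0, 4 * h),
    W4 = init_matrix(h, config$dense_units), b4 = rep(0, config$dense_units),
    W5 = init_matrix(config$dense_units, K), b5 = rep(0, K)
  ))
  structure(list(encoder = encoder, K = as.integer(K), config = config,
                 params = params, fitted = FALSE, history = NULL),
            class = "perio_text_model")
}

#' @export
print.perio_text_model <- function(x, ...) {
  cat("<perio_text_model> encoder dim ", x$encoder$dim, " -> LSTM(",
      x$config$lstm_units, ") -> dense(", x$config$dense_units,
      ") -> softmax(", x$K, "); ",
      if (x$fitted) paste0("fitted, ", nrow(x$history), " epochs") else "unfitted",
      "\n", sep = "")
  invisible(x)
}

# --- LSTM over the window sequence -------------------------------------------

lstm_forward <- function(params, xs) {
  Tn <- nrow(xs)
  h <- ncol(params$Wh)  / 4
  h_prev <- matrix(0, 1, h)
  c_prev <- matrix(0, 1, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    pre <- xs[t, , drop = FALSE] %*% params$Wx + h_prev %*% params$Wh +
      matrix(params$b, 1)
    i <- sigmoid(pre[, 1:h, drop = FALSE])
    f <- sigmoid(pre[, (h + 1):(2 * h), drop = FALSE])
    o <- sigmoid(pre[, (2 * h + 1):(3 * h), drop = FALSE])
    g <- tanh(pre[, (3 * h + 1):(4 * h), drop = FALSE])
    c_t <- f * c_prev + i * g
    h_t <- o * tanh(c_t)
    cache[[t]] <- list(x = xs[t, , drop = FALSE], h_prev = h_prev,
                       c_prev = c_prev, i = i, f = f, o = o, g = g,
                       c = c_t, tc = tanh(c_t))
    h_prev <- h_t
    c_prev <- c_t
  }
  list(h = h_prev, cache = cache)
}

lstm_backward <- function(params, cache, dh) {
  Tn <- length(cache)
  h <- ncol(dh)
  dWx <- params$Wx * 0
  dWh <- params$Wh * 0
  db <- params$b * 0
  dxs <- matrix(0, Tn, nrow(params$Wx))
  dc <- matrix(0, 1, h)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_prev <- dc * cc$f
    dpre <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    dWx <- dWx + t(cc$x) %*% dpre
    dWh <- dWh + t(cc$h_prev) %*% dpre
    db <- db + as.numeric(dpre)
    dxs[t, ] <- dpre %*% t(params$Wx)
    dh <- dpre %*% t(params$Wh)
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db, dxs = dxs)
}

# --- per-note forward/backward -----------------------------------------------

# win: list(ids, mask); drop_mask NULL at inference.
note_forward <- function(params, enc_params, win, drop_mask = NULL,
                         keep_cache = FALSE) {
  Tn <- nrow(win$ids)
  d <- ncol(enc_params$E)
  xs <- matrix(0, Tn, d)
  enc_caches <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    ec <- encoder_forward(enc_params, win$ids[t, ], win$mask[t, ])
    xs[t, ] <- ec$z
    if (keep_cache) enc_caches[[t]] <- ec
  }
  note_forward_from_xs(params, xs, drop_mask, enc_caches)
}

note_forward_from_xs <- function(params, xs, drop_mask = NULL,
                                 enc_caches = NULL) {
  lstm <- lstm_forward(params, xs)
  z4 <- lstm$h %*% params$W4 + matrix(params$b4, 1)
  a4 <- relu(z4)
  a4d <- if (is.null(drop_mask)) a4 else a4 * drop_mask
  logits <- a4d %*% params$W5 + matrix(params$b5, 1)
  p <- softmax_rows(logits)
  list(p = p, a4 = a4, a4d = a4d, lstm = lstm, xs = xs,
       enc_caches = enc_caches, drop_mask = drop_mask)
}

# Gradient of scale * ce(p, y) w.r.t. all trainable params.
note_backward <- function(params, enc_params, fwd, y, scale, K, fine_tune) {
  dlogits <- (fwd$p - one_hot(y, K)) * scale
  g <- list(
    W5 = t(fwd$a4d) %*% dlogits,
    b5 = as.numeric(dlogits)
  )
  da4d <- dlogits %*% t(params$W5)
  da4 <- if (is.null(fwd$drop_mask)) da4d else da4d * fwd$drop_mask
  dz4 <- da4 * (fwd$a4 > 0)
  g$W4 <- t(fwd$lstm$h) %*% dz4
  g$b4 <- as.numeric(dz4)
  dh <- dz4 %*% t(params$W4)
  lb <- lstm_backward(params, fwd$lstm$cache, dh)
  g$Wx <- lb$Wx
  g$Wh <- lb$Wh
  g$b <- lb$b
  if (fine_tune) {
    for (t in seq_len(nrow(lb$dxs))) {
      eg <- encoder_backward(enc_params, fwd$enc_caches[[t]], lb$dxs[t, ])
      g <- grad_add(g, eg)
    }
  }
  g
}

#' Train the text classifier
#'
#' Carves a stratified validation set (`val_fraction`) out of the supplied
#' notes for early stopping, trains with Adam on class-weighted multi-class
#' cross-entropy, decays the learning rate by `decay_rate` each epoch, halts
#' when validation loss has not improved for `patience` epochs, and restores
#' the weights of the best validation-loss epoch. With `fine_tune = TRUE`
#' the encoder's embedding and attention matrices receive gradients;
#' otherwise window embeddings are precomputed once and the encoder stays
#' frozen. Bit-reproducible given the config seed.
#'
#' @param model An unfitted `perio_text_model` from [build_text_model()].
#' @param notes Tibble with `chart_number` and `text`.
#' @param labels Integer labels coded `1..K`, aligned with `notes`.
#' @return The fitted model, with a per-epoch `history` tibble (losses,
#'   accuracies, learning rate) and `best_epoch`.
#' @export
train_text_model <- function(model, notes, labels) {
  stopifnot(inherits(model, "perio_text_model"),
            nrow(notes) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("single-class training labels", class = "periodx_config_error")
  }
  cfg <- model$config
  K <- model$K
  w_class <- if (cfg$class_weighting == "balanced") {
    compute_class_weights(labels, K)
  } else {
    rep(1, K)
  }
  enc_params <- model$encoder$params
  params <- model$params
  fine_tune <- isTRUE(cfg$fine_tune)
  if (fine_tune) params <- c(params, enc_params)

  wins <- purrr::map(notes$text, window_note, encoder = model$encoder,
                     window_length = cfg$window_length)
  df <- tibble::tibble(idx = seq_along(labels), y = labels)
  # Stratified validation carve; classes too rare to split (a single
  # example) stay entirely in the training portion.
  single <- df$y %in% as.integer(names(which(table(df$y) < 2)))
  carve <- split_data(df[!single, , drop = FALSE], 1 - cfg$val_fraction,
                      stratify = TRUE, label_col = "y",
                      seed = derive_seed(cfg$seed, "text-val"))
  tr <- c(carve$train$idx, df$idx[single])
  va <- carve$test$idx

  # Class weights multiply the training loss only; monitored losses are
  # unweighted so rare-class examples do not dominate early stopping.
  eval_split <- function(p_all, idx) {
    p <- p_all[idx, , drop = FALSE]
    y <- labels[idx]
    list(loss = ce_loss(p, y, rep(1, length(y))),
         acc = mean(argmax_rows(p) == y))
  }
  forward_all <- function(params) {
    ep <- if (fine_tune) params[c("E", "Wq", "Wk", "Wv")] else enc_params
    t(vapply(wins, function(w) {
      as.numeric(note_forward(params, ep, w)$p)
    }, numeric(K)))
  }

  with_seed(derive_seed(cfg$seed, "text-train"), {
    # Frozen encoder: window embeddings never change; compute once.
    xs_cache <- if (!fine_tune) {
      purrr::map(wins, function(w) {
        Tn <- nrow(w$ids)
        xs <- matrix(0, Tn, model$encoder$dim)
        for (t in seq_len(Tn)) {
          xs[t, ] <- encoder_forward(enc_params, w$ids[t, ], w$mask[t, ])$z
        }
        xs
      })
    }
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    hist <- list()
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate * cfg$decay_rate^(ep - 1)
      ord <- sample(tr)
      for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        grads <- list()
        ep_enc <- if (fine_tune) params[c("E", "Wq", "Wk", "Wv")] else enc_params
        for (i in batch) {
          drop_mask <- if (cfg$dropout_rate > 0) {
            matrix((runif(cfg$dense_units) >= cfg$dropout_rate) /
                     (1 - cfg$dropout_rate), 1)
          }
          fwd <- if (fine_tune) {
            note_forward(params, ep_enc, wins[[i]], drop_mask,
                         keep_cache = TRUE)
          } else {
            note_forward_from_xs(params, xs_cache[[i]], drop_mask)
          }
          g <- note_backward(params, ep_enc, fwd, labels[i],
                             w_class[labels[i]] / length(batch), K, fine_tune)
          grads <- grad_add(grads, g)
        }
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      p_all <- forward_all(params)
      m_tr <- eval_split(p_all, tr)
      m_va <- eval_split(p_all, va)
      hist[[ep]] <- tibble::tibble(
        epoch = ep, lr = lr, train_loss = m_tr$loss, train_accuracy = m_tr$acc,
        val_loss = m_va$loss, val_accuracy = m_va$acc
      )
      if (m_va$loss < best$loss - 1e-9) {
        best <- list(loss = m_va$loss, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    params <- best$params
    if (fine_tune) {
      model$encoder$params <- params[c("E", "Wq", "Wk", "Wv")]
      params <- params[setdiff(names(params), c("E", "Wq", "Wk", "Wv"))]
    }
    model$params <- params
    model$fitted <- TRUE
    model$history <- purrr::list_rbind(hist)
    model$best_epoch <- best$epoch
    model$class_weights <- w_class
    model
  })
}

#' Predict stage/grade from note text
#'
#' Deterministic at inference (no dropout): argmax over the softmax output,
#' exact ties broken toward the lowest class code.
#'
#' @param model A fitted `perio_text_model`.
#' @param notes Tibble with `chart_number` and `text`; may be empty.
#' @return Tibble with `chart_number`, `pred`, and probability columns
#'   `p_1..p_K`.
#' @export
predict_text <- function(model, notes) {
  stopifnot(inherits(model, "perio_text_model"))
  if (nrow(notes) == 0) {
    out <- tibble::tibble(chart_number = integer(0), pred = integer(0))
    for (k in seq_len(model$K)) out[[paste0("p_", k)]] <- numeric(0)
    return(out)
  }
  p <- t(vapply(notes$text, function(txt) {
    win <- window_note(txt, model$encoder, model$config$window_length)
    as.numeric(note_forward(model$params, model$encoder$params, win)$p)
  }, numeric(model$K), USE.NAMES = FALSE))
  out <- tibble::tibble(chart_number = notes$chart_number,
                        pred = argmax_rows(p))
  colnames(p) <- paste0("p_", seq_len(model$K))
  dplyr::bind_cols(out, tibble::as_tibble(p))
}
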