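# Analytic gradients of both networks checked against central finite
# differences at tiny sizes.

num_grad <- function(loss_fn, params, nm, idx, eps = 1e-6) {
  sapply(idx, function(i) {
    p1 <- params
    p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] - eps
    (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
  })
}

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))

test_that("MLP backward matches numerical gradients", {
  px <- asNamespace("periodx")
  withr::with_seed(4, {
    x <- matrix(rnorm(12), 4, 3)
    y <- c(1L, 2L, 3L, 2L)
    w <- c(1, 2, 0.5, 1)
    params <- withr::with_seed(5, list(
      W1 = px$init_matrix(3, 5), b1 = rnorm(5),
      W2 = px$init_matrix(5, 4), b2 = rnorm(4),
      W3 = px$init_matrix(4, 3), b3 = rnorm(3)
    ))
  })
  loss_fn <- function(p) px$ce_loss(px$mlp_forward(p, x)$p, y, w)
  fwd <- px$mlp_forward(params, x)
  g <- px$mlp_backward(params, x, fwd, y, w, 3)
  for (nm in names(g)) {
    idx <- seq_len(min(5, length(params[[nm]])))
    expect_lt(rel_err(num_grad(loss_fn, params, nm, idx), g[[nm]][idx]), 1e-5)
  }
})

test_that("text-model backward (attention + LSTM + head) matches numerical gradients", {
  px <- asNamespace("periodx")
  enc <- fixture_encoder(4, 23, seed = 2)
  cfg <- text_train_config(window_length = 5, lstm_units = 3, dense_units = 4,
                           dropout_rate = 0, learning_rate = 1, seed = 3)
  m <- build_text_model(enc, 3, cfg)
  win <- window_note("the quick brown fox jumps over a lazy dog near the river today",
                     enc, 5)
  params <- c(m$params, enc$params)
  y <- 2L
  loss_fn <- function(p) {
    ep <- p[c("E", "Wq", "Wk", "Wv")]
    -log(px$note_forward(p, ep, win)$p[1, y])
  }
  ep <- params[c("E", "Wq", "Wk", "Wv")]
  fwd <- px$note_forward(params, ep, win, NULL, keep_cache = TRUE)
  g <- px$note_backward(params, ep, fwd, y, 1, 3, fine_tune = TRUE)
  withr::with_seed(6, {
    for (nm in names(g)) {
      idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      expect_lt(rel_err(num_grad(loss_fn, params, nm, idx), g[[nm]][idx]),
                1e-4)
    }
  })
})

test_that("Adam minimizes a simple quadratic", {
  px <- asNamespace("periodx")
  params <- list(w = c(5, -3))
  state <- px$adam_init(params)
  for (i in 1:400) {
    g <- list(w = 2 * params$w)
    upd <- px$adam_step(params, g, state, lr = 0.05)
    params <- upd$params
    state <- upd$state
  }
  expect_lt(max(abs(params$w)), 1e-2)
})
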