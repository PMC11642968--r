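# Minimal neural-network primitives in base R matrix code.
#
# No R deep-learning framework is used: both classifiers in this package are
# small enough that explicit forward/backward passes over a flat list of
# parameter matrices are clearer, dependency-free, and fast at the problem
# sizes involved. Gradients are verified against numerical differentiation in
# the test suite.

relu <- function(x) pmax(x, 0)

# Numerically stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

one_hot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# Weighted multi-class cross-entropy: mean over rows of w_i * -log p[i, y_i].
ce_loss <- function(p, y, w) {
  -sum(w * log(pmax(p[cbind(seq_along(y), y)], 1e-12))) / length(y)
}

# He-scaled Gaussian init.
init_matrix <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# Adam over a named list of numeric arrays.
adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate grads b into a (same shapes; missing entries allowed in b).
grad_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

grad_scale <- function(g, s) purrr::map(g, ~ .x * s)

#' Break probability ties toward the lowest class code
#'
#' `which.max` semantics: the first maximum wins, so exact ties resolve to
#' the lowest class code.
#' @noRd
argmax_rows <- function(p) {
  as.integer(apply(p, 1, which.max))
}
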