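# Local-surrogate token importance.
#
# Explains one prediction of any text classifier by fitting a weighted linear
# surrogate: random token-masked variants of the note are scored by the model,
# weighted by proximity to the original (exponential kernel on the fraction of
# tokens retained), and regressed -- token-presence indicators against the
# target-class probability. The surrogate's coefficients are the importances.
# Masking deletes tokens outright rather than substituting a reserved mask id,
# so the explainer works with any encoder.

#' Token importance for one note
#'
#' The interpretable representation is the note's unique tokens: each
#' perturbation keeps or drops every occurrence of a token, the model scores
#' the perturbed text, and a ridge-stabilized weighted linear model maps
#' presence indicators to the target-class probability. Sample weights are
#' `exp(-(1 - kept_fraction)^2 / kernel_width^2)`. Reproducible given `seed`.
#'
#' @param predict_fn Function mapping a character vector of texts to a
#'   numeric probability matrix (rows sum to 1).
#' @param note Note text (single string, at least 2 tokens).
#' @param target_class Column of the probability matrix to explain.
#' @param n_samples Number of masked variants (at least 50).
#' @param kernel_width Proximity kernel width (default 0.25).
#' @param seed Integer seed.
#' @return A `perio_attribution` tibble: `token`, `weight` (signed surrogate
#'   coefficient), ordered by decreasing weight; attributes record
#'   `n_samples`, `seed`, `target_class` and the original probability.
#' @export
token_importance <- function(predict_fn, note, target_class, n_samples = 500,
                             kernel_width = 0.25, seed = 1L) {
  stopifnot(is.function(predict_fn), n_samples >= 50, kernel_width > 0)
  tokens <- tokenize_text(note)
  if (length(tokens) < 2) {
    abort("note must contain at least 2 tokens")
  }
  vocab <- unique(tokens)
  m <- length(vocab)
  with_seed(seed, {
    # Keep each unique token independently with probability 0.5; force at
    # least one kept token per variant so the model always sees text.
    Z <- matrix(runif(n_samples * m) < 0.5, n_samples, m)
    empty <- rowSums(Z) == 0
    Z[cbind(which(empty), sample.int(m, sum(empty), replace = TRUE))] <- TRUE
    texts <- purrr::map_chr(seq_len(n_samples), function(i) {
      paste(tokens[tokens %in% vocab[Z[i, ]]], collapse = " ")
    })
    p <- predict_fn(texts)
    if (is.null(dim(p))) p <- matrix(p, ncol = 1)
    y <- p[, target_class]
    kept_frac <- rowSums(Z) / m
    w <- exp(-(1 - kept_frac)^2 / kernel_width^2)
    # Weighted ridge with intercept; tiny penalty only stabilizes collinear
    # or constant designs, it does not shrink real effects noticeably.
    X <- cbind(1, Z * 1)
    A <- t(X) %*% (X * w) + diag(c(0, rep(1e-6, m)))
    beta <- solve(A, t(X) %*% (w * y))
    out <- tibble::tibble(token = vocab, weight = as.numeric(beta[-1])) |>
      dplyr::arrange(dplyr::desc(.data$weight))
    structure(out, class = c("perio_attribution", class(out)),
              n_samples = n_samples, seed = as.integer(seed),
              target_class = target_class,
              p_original = as.numeric(predict_fn(note)[1, target_class]))
  })
}

#' Write token attributions as CSV
#'
#' @param attribution A `perio_attribution` tibble.
#' @param path Output path (`token,weight`).
#' @return `path`, invisibly.
#' @export
write_attribution <- function(attribution, path) {
  readr::write_csv(attribution[, c("token", "weight")], path)
  invisible(path)
}
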