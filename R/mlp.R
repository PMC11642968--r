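# Tabular track: feed-forward classifier over the extracted feature table.
#
# Architecture fixed at two ReLU hidden layers (the grid explores 4-20 units
# in each), softmax output, multi-class cross-entropy on one-hot targets,
# Adam, batch size 16, 30 epochs.

#' Stratified train/test split
#'
#' Disjoint, exhaustive partition of a table. With stratification the
#' training set holds `floor(train_fraction * n)` rows apportioned across
#' classes by largest remainder, so each class's train share is within one
#' row of `train_fraction`.
#'
#' @param table Data frame.
#' @param train_fraction Fraction of rows to train on (default 0.70).
#' @param stratify Stratify by `label_col` (default `TRUE`).
#' @param label_col Column name holding integer class labels.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
#' @examples
#' df <- tibble::tibble(x = 1:10, y = rep(1:2, each = 5))
#' sp <- split_data(df, 0.7, label_col = "y", seed = 1)
#' nrow(sp$train)
split_data <- function(table, train_fraction = 0.70, stratify = TRUE,
                       label_col = "stage", seed = 1L) {
  stopifnot(is.data.frame(table), train_fraction > 0, train_fraction < 1,
            label_col %in% names(table))
  n <- nrow(table)
  with_seed(seed, {
    if (!stratify) {
      idx <- sample.int(n, floor(train_fraction * n))
    } else {
      y <- table[[label_col]]
      counts <- table(y)
      if (any(counts < 2)) {
        abort("stratified split needs at least 2 rows per class",
              class = "periodx_config_error")
      }
      n_train <- scale_counts(as.integer(counts), floor(train_fraction * n))
      idx <- unlist(purrr::map2(names(counts), n_train, function(cls, k) {
        rows <- which(y == cls)
        rows[sample.int(length(rows), k)]
      }))
    }
    list(train = table[sort(idx), , drop = FALSE],
         test = table[setdiff(seq_len(n), idx), , drop = FALSE])
  })
}

# --- feature preparation -----------------------------------------------------
# Median imputation for general numerics, 0 for binary coded flags, plus a
# missingness indicator per field that had any NA at fit time; non-flag
# columns are standardized by training mean/sd.

fit_feature_prep <- function(df) {
  stopifnot(is.data.frame(df))
  cols <- names(df)
  is_flag <- purrr::map_lgl(df, function(x) {
    v <- unique(x[!is.na(x)])
    length(v) > 0 && all(v %in% c(0, 1))
  })
  fill <- purrr::map_dbl(df, function(x) {
    m <- stats::median(x, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  fill[is_flag] <- 0
  has_na <- purrr::map_lgl(df, anyNA)
  center <- purrr::map_dbl(df, ~ mean(.x, na.rm = TRUE))
  center[is.na(center)] <- 0
  scale <- purrr::map_dbl(df, ~ stats::sd(.x, na.rm = TRUE))
  scale[is.na(scale) | scale == 0] <- 1
  center[is_flag] <- 0
  scale[is_flag] <- 1
  list(columns = cols, is_flag = is_flag, fill = fill, has_na = has_na,
       center = center, scale = scale)
}

apply_feature_prep <- function(df, prep) {
  missing_cols <- setdiff(prep$columns, names(df))
  if (length(missing_cols) > 0) {
    abort(glue::glue("feature columns absent from data: {paste(missing_cols, collapse = ', ')}"))
  }
  df <- df[, prep$columns, drop = FALSE]
  x <- purrr::imap(df, function(col, nm) {
    v <- as.numeric(col)
    v[is.na(v)] <- prep$fill[[nm]]
    (v - prep$center[[nm]]) / prep$scale[[nm]]
  })
  ind <- purrr::imap(df[, prep$has_na, drop = FALSE],
                     ~ as.numeric(is.na(.x)))
  if (length(ind) > 0) names(ind) <- paste0(names(ind), "_missing")
  m <- do.call(cbind, c(x, ind))
  if (any(!is.finite(m))) {
    abort("non-finite feature values after imputation")
  }
  m
}

# --- MLP core ----------------------------------------------------------------

mlp_forward <- function(params, x) {
  z1 <- sweep(x %*% params$W1, 2, params$b1, `+`)
  a1 <- relu(z1)
  z2 <- sweep(a1 %*% params$W2, 2, params$b2, `+`)
  a2 <- relu(z2)
  z3 <- sweep(a2 %*% params$W3, 2, params$b3, `+`)
  list(p = softmax_rows(z3), a1 = a1, a2 = a2)
}

mlp_backward <- function(params, x, fwd, y, w, K) {
  n <- nrow(x)
  dz3 <- (fwd$p - one_hot(y, K)) * (w / n)
  da2 <- dz3 %*% t(params$W3)
  dz2 <- da2 * (fwd$a2 > 0)
  da1 <- dz2 %*% t(params$W2)
  dz1 <- da1 * (fwd$a1 > 0)
  list(W1 = t(x) %*% dz1, b1 = colSums(dz1),
       W2 = t(fwd$a1) %*% dz2, b2 = colSums(dz2),
       W3 = t(fwd$a2) %*% dz3, b3 = colSums(dz3))
}

#' Train the feed-forward tabular classifier
#'
#' Two ReLU hidden layers, softmax output over `K` classes, multi-class
#' cross-entropy on one-hot targets, Adam optimizer. Missing feature cells
#' are imputed (median for numerics, 0 for 0/1 flags) with per-field
#' missingness indicator columns; training is reproducible under a fixed
#' seed.
#'
#' @param train Data frame holding feature columns and the label column.
#' @param label_col Label column name (integer codes `1..K`).
#' @param feature_cols Feature column names; default every numeric column
#'   except `label_col`, `chart_number`, `stage`, `grade`.
#' @param hidden Two hidden-layer sizes, e.g. `c(15, 13)`.
#' @param epochs,batch_size,learning_rate Training hyperparameters (defaults
#'   30, 16, 0.01).
#' @param class_weights Optional per-class loss multipliers (see
#'   [compute_class_weights()]); default unweighted.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A fitted `perio_mlp` object with elements `params`, `prep`,
#'   `classes`, `history`, `config`.
#' @export
train_mlp <- function(train, label_col = "stage", feature_cols = NULL,
                      hidden = c(15, 13), epochs = 30, batch_size = 16,
                      learning_rate = 1e-2, class_weights = NULL, seed = 1L) {
  stopifnot(length(hidden) == 2, all(hidden >= 1))
  y <- as.integer(train[[label_col]])
  K <- max(2L, max(y))
  feature_cols <- feature_cols %||%
    setdiff(names(train)[purrr::map_lgl(train, is.numeric)],
            c(label_col, "chart_number", "stage", "grade"))
  prep <- fit_feature_prep(train[, feature_cols, drop = FALSE])
  x <- apply_feature_prep(train[, feature_cols, drop = FALSE], prep)
  w_class <- class_weights %||% rep(1, K)
  w <- w_class[y]
  with_seed(seed, {
    d <- ncol(x)
    params <- list(
      W1 = init_matrix(d, hidden[1]), b1 = rep(0, hidden[1]),
      W2 = init_matrix(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
      W3 = init_matrix(hidden[2], K), b3 = rep(0, K)
    )
    state <- adam_init(params)
    history <- numeric(epochs)
    n <- nrow(x)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (batch in split(ord, ceiling(seq_along(ord) / batch_size))) {
        xb <- x[batch, , drop = FALSE]
        fwd <- mlp_forward(params, xb)
        grads <- mlp_backward(params, xb, fwd, y[batch], w[batch], K)
        upd <- adam_step(params, grads, state, learning_rate)
        params <- upd$params
        state <- upd$state
      }
      history[ep] <- ce_loss(mlp_forward(params, x)$p, y, w)
    }
    structure(list(
      params = params, prep = prep, feature_cols = feature_cols,
      label_col = label_col, classes = seq_len(K),
      history = tibble::tibble(epoch = seq_len(epochs), loss = history),
      config = list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                    learning_rate = learning_rate, seed = as.integer(seed))
    ), class = "perio_mlp")
  })
}

#' Predict classes from a fitted tabular classifier
#'
#' @param object A `perio_mlp` from [train_mlp()].
#' @param newdata Data frame with the training feature columns.
#' @param ... Unused.
#' @return Tibble with `pred` (argmax class, exact ties broken toward the
#'   lowest class code) and probability columns `p_1..p_K` (each row sums
#'   to 1).
#' @export
predict.perio_mlp <- function(object, newdata, ...) {
  x <- apply_feature_prep(newdata[, object$feature_cols, drop = FALSE],
                          object$prep)
  p <- mlp_forward(object$params, x)$p
  out <- tibble::tibble(pred = argmax_rows(p))
  colnames(p) <- paste0("p_", object$classes)
  dplyr::bind_cols(out, tibble::as_tibble(p))
}

#' @export
print.perio_mlp <- function(x, ...) {
  cat("<perio_mlp> ", length(x$feature_cols), " features -> ",
      paste(x$config$hidden, collapse = "/"), " -> ",
      length(x$classes), " classes; final loss ",
      signif(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.perio_mlp <- function(x, ...) {
  tibble::tibble(
    layer = c("hidden1", "hidden2", "output"),
    n_in = c(nrow(x$params$W1), nrow(x$params$W2), nrow(x$params$W3)),
    n_out = c(ncol(x$params$W1), ncol(x$params$W2), ncol(x$params$W3)),
    n_parameters = c(length(x$params$W1) + length(x$params$b1),
                     length(x$params$W2) + length(x$params$b2),
                     length(x$params$W3) + length(x$params$b3))
  )
}

#' @export
glance.perio_mlp <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = length(x$feature_cols),
    hidden1 = x$config$hidden[1], hidden2 = x$config$hidden[2],
    epochs = x$config$epochs,
    final_loss = utils::tail(x$history$loss, 1)
  )
}

#' Grid search over two-hidden-layer architectures
#'
#' Trains one model per `(hidden1, hidden2)` cell on an 80% carve-out of
#' `train` and scores validation accuracy on the remaining 20% (stratified).
#' The selected architecture maximizes validation accuracy; ties resolve to
#' the first cell in row-major grid order (smallest sizes). Deterministic
#' given `seed`: every cell shares the same derived initialization seed and
#' the same validation carve-out.
#'
#' @inheritParams train_mlp
#' @param hidden1,hidden2 Candidate unit counts for each hidden layer
#'   (default `4:20`, the full published grid).
#' @param validation_fraction Carve-out fraction used for selection.
#' @return A `perio_grid` list: `best_hidden`, `best_accuracy`, `grid`
#'   (tibble of all cells with validation accuracy), plus the winning fitted
#'   model as `model`.
#' @export
grid_search <- function(train, label_col = "stage", feature_cols = NULL,
                        hidden1 = 4:20, hidden2 = 4:20,
                        validation_fraction = 0.2, epochs = 30,
                        batch_size = 16, learning_rate = 1e-2,
                        class_weights = NULL, seed = 1L) {
  stopifnot(length(hidden1) > 0, length(hidden2) > 0)
  if (length(unique(train[[label_col]])) < 2) {
    abort("degenerate training set: single class", class = "periodx_config_error")
  }
  carve <- split_data(train, 1 - validation_fraction, stratify = TRUE,
                      label_col = label_col, seed = derive_seed(seed, "grid-carve"))
  cells <- tidyr::expand_grid(hidden1 = hidden1, hidden2 = hidden2)
  fit_seed <- derive_seed(seed, "grid-fit")
  acc <- purrr::pmap_dbl(cells, function(hidden1, hidden2) {
    fit <- train_mlp(carve$train, label_col = label_col,
                     feature_cols = feature_cols,
                     hidden = c(hidden1, hidden2), epochs = epochs,
                     batch_size = batch_size, learning_rate = learning_rate,
                     class_weights = class_weights, seed = fit_seed)
    mean(predict(fit, carve$test)$pred == carve$test[[label_col]])
  })
  grid <- dplyr::mutate(cells, val_accuracy = acc)
  best <- which.max(acc)
  model <- train_mlp(train, label_col = label_col, feature_cols = feature_cols,
                     hidden = c(grid$hidden1[best], grid$hidden2[best]),
                     epochs = epochs, batch_size = batch_size,
                     learning_rate = learning_rate,
                     class_weights = class_weights, seed = fit_seed)
  structure(list(
    best_hidden = c(grid$hidden1[best], grid$hidden2[best]),
    best_accuracy = acc[best],
    grid = grid,
    model = model
  ), class = "perio_grid")
}

#' @export
print.perio_grid <- function(x, ...) {
  cat("<perio_grid> ", nrow(x$grid), " cells; selected (",
      paste(x$best_hidden, collapse = ", "), ") at validation accuracy ",
      round(x$best_accuracy, 3), "\n", sep = "")
  invisible(x)
}
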