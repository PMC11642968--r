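# Tabular classifier: splitting, training, prediction, grid search.

test_that("70/30 split matches floor arithmetic and stratifies within one row", {
  df <- tibble::tibble(x = seq_len(309),
                       stage = rep(1:4, times = c(6, 36, 206, 61)))
  sp <- split_data(df, 0.70, label_col = "stage", seed = 1)
  expect_equal(nrow(sp$train), 216L)
  expect_equal(nrow(sp$test), 93L)
  expect_length(intersect(sp$train$x, sp$test$x), 0L)
  expect_setequal(c(sp$train$x, sp$test$x), df$x)
  per_class <- table(sp$train$stage)
  expect_true(all(abs(per_class - 0.7 * c(6, 36, 206, 61)) <= 1))

  df2 <- tibble::tibble(x = 1:10, y = rep(1:2, each = 5))
  sp2 <- split_data(df2, 0.7, label_col = "y", seed = 2)
  expect_equal(nrow(sp2$train), 7L)
  expect_true(all(sort(as.integer(table(sp2$train$y))) == c(3, 4)))

  expect_identical(split_data(df2, 0.7, label_col = "y", seed = 9),
                   split_data(df2, 0.7, label_col = "y", seed = 9))
  expect_error(split_data(tibble::tibble(y = c(1, 2, 2)), 0.7, label_col = "y",
                          seed = 1),
               class = "periodx_config_error")
})

make_blobs <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    x1 = c(rnorm(n, -2), rnorm(n, 2)),
    x2 = rnorm(2 * n),
    y = rep(1:2, each = n)
  ))
}

test_that("probabilities are normalized and training is seed-reproducible", {
  df <- make_blobs(30, seed = 5)
  f1 <- train_mlp(df, label_col = "y", hidden = c(6, 5), epochs = 10, seed = 7)
  f2 <- train_mlp(df, label_col = "y", hidden = c(6, 5), epochs = 10, seed = 7)
  expect_identical(f1$params, f2$params)
  p <- predict(f1, df)
  probs <- as.matrix(p[, c("p_1", "p_2")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(probs >= 0))
  expect_identical(p, predict(f1, df))
})

test_that("a one-row training set is memorized", {
  df <- tibble::tibble(x1 = 1, x2 = -1, y = 2L)
  fit <- train_mlp(df, label_col = "y", hidden = c(4, 4), epochs = 30, seed = 1)
  expect_equal(predict(fit, df)$pred, 2L)
})

test_that("missing cells are imputed with indicator columns", {
  df <- make_blobs(25, seed = 6)
  df$x2[c(3, 10)] <- NA
  fit <- train_mlp(df, label_col = "y", hidden = c(5, 4), epochs = 10, seed = 2)
  expect_true(fit$prep$has_na[["x2"]])
  newdata <- df[1:4, ]
  newdata$x2[2] <- NA
  expect_equal(nrow(predict(fit, newdata)), 4L)
  bad <- df
  bad$x1[1] <- Inf
  expect_error(train_mlp(bad, label_col = "y", seed = 1), "non-finite")
})

test_that("argmax prediction breaks exact ties toward the lowest class code", {
  am <- getFromNamespace("argmax_rows", "periodx")
  expect_equal(am(matrix(c(0.1, 0.2, 0.6, 0.1), 1)), 3L)
  expect_equal(am(matrix(c(0.5, 0.5), 1)), 1L)
  expect_equal(am(matrix(c(0.2, 0.4, 0.4), 1)), 2L)
})

test_that("grid search selects the best validation cell deterministically", {
  df <- make_blobs(40, seed = 8)
  gs <- grid_search(df, label_col = "y", hidden1 = c(4, 8), hidden2 = c(4, 6),
                    epochs = 8, seed = 3)
  expect_equal(nrow(gs$grid), 4L)
  expect_true(all(gs$best_accuracy >= gs$grid$val_accuracy))
  # linearly separable blobs are essentially solved
  expect_gte(gs$best_accuracy, 0.95)

  one <- grid_search(df, label_col = "y", hidden1 = 5, hidden2 = 7,
                     epochs = 5, seed = 3)
  expect_equal(one$best_hidden, c(5, 7))

  gs2 <- grid_search(df, label_col = "y", hidden1 = c(4, 8), hidden2 = c(4, 6),
                     epochs = 8, seed = 3)
  expect_identical(gs$grid, gs2$grid)

  expect_error(grid_search(dplyr::mutate(df, y = 1L), label_col = "y"),
               class = "periodx_config_error")
})

test_that("prediction errors name absent feature columns", {
  df <- make_blobs(20, seed = 9)
  fit <- train_mlp(df, label_col = "y", hidden = c(4, 4), epochs = 5, seed = 1)
  expect_error(predict(fit, df[, "x1"]), "x2")
})

test_that("tidy and glance summarize the fitted network", {
  df <- make_blobs(20, seed = 10)
  fit <- train_mlp(df, label_col = "y", hidden = c(6, 5), epochs = 5, seed = 1)
  td <- tidy(fit)
  expect_equal(td$n_out, c(6, 5, 2))
  gl <- glance(fit)
  expect_equal(gl$hidden1, 6)
  expect_true(is.finite(gl$final_loss))
})
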