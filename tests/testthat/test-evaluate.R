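# Confusion matrices, metric identities, comparison tables.

test_that("confusion counts true-by-predicted cells", {
  cm <- confusion(c(1, 1, 2), c(1, 2, 2), K = 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(true = 1:2, pred = 1:2)))
  expect_equal(sum(cm), 3L)
  y <- sample(1:4, 50, replace = TRUE)
  expect_true(all(unclass(confusion(y, y, 4)) ==
                    diag(as.integer(table(factor(y, 1:4))))))
  expect_error(confusion(1:3, 1:2), "length")
  expect_error(confusion(c(1, 5), c(1, 1), K = 4), "coded")
})

test_that("perfect predictions give accuracy 1 and recall 1 for supported classes", {
  y <- rep(1:3, times = c(4, 5, 2))
  rep_ <- metrics(confusion(y, y, 3))
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$by_class$recall, rep(1, 3))
  expect_equal(rep_$by_class$support, c(4L, 5L, 2L))
})

test_that("metrics agree with a brute-force counter on random instances", {
  brute <- function(true, pred, K) {
    out <- lapply(seq_len(K), function(k) {
      tp <- sum(true == k & pred == k)
      fp <- sum(true != k & pred == k)
      fn <- sum(true == k & pred != k)
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p, r, f)
    })
    do.call(rbind, out)
  }
  withr::with_seed(99, {
    for (i in 1:100) {
      K <- sample(2:4, 1)
      n <- sample(2:30, 1)
      true <- sample(seq_len(K), n, replace = TRUE)
      pred <- sample(seq_len(K), n, replace = TRUE)
      m <- metrics(confusion(true, pred, K))
      b <- brute(true, pred, K)
      expect_equal(m$by_class$precision, b[, 1], tolerance = 1e-12)
      expect_equal(m$by_class$recall, b[, 2], tolerance = 1e-12)
      expect_equal(m$by_class$f1, b[, 3], tolerance = 1e-12)
      expect_equal(m$accuracy, mean(true == pred), tolerance = 1e-12)
      # micro-averaged recall equals accuracy for single-label multi-class
      micro <- sum(diag(m$cm)) / sum(m$cm)
      expect_equal(micro, m$accuracy, tolerance = 1e-12)
      # F1 between min and max of P and R when both positive
      pos <- b[, 1] > 0 & b[, 2] > 0
      expect_true(all(b[pos, 3] >= pmin(b[pos, 1], b[pos, 2]) - 1e-12))
      expect_true(all(b[pos, 3] <= pmax(b[pos, 1], b[pos, 2]) + 1e-12))
      expect_true(all(m$by_class$precision >= 0 & m$by_class$precision <= 1))
    }
  })
})

test_that("presentation rounding is two-decimal half-up with optional pre-rounded F1", {
  cm <- confusion(rep(1:2, c(8, 4)), c(rep(1, 6), 2, 2, rep(2, 3), 1), K = 2)
  m <- metrics(cm)
  pm <- present_metrics(m, digits = 2)
  expect_equal(pm$precision, round_half_up(m$by_class$precision, 2))
  pm2 <- present_metrics(m, recompute_f1 = TRUE)
  expect_equal(pm2$f1, round_half_up(f1_score(pm2$precision, pm2$recall), 2))
})

test_that("model comparison is antisymmetric and keeps the two-row-per-class layout", {
  y <- rep(1:4, times = c(2, 5, 20, 5))
  pa <- pmin(y + c(rep(0, 25), rep(1, 7)), 4)
  pb <- pmax(y - c(rep(1, 4), rep(0, 28)), 1)
  ra <- metrics(confusion(y, pa, 4))
  rb <- metrics(confusion(y, pb, 4))
  cmp <- compare_models(ra, rb, names = c("text", "mlp"))
  expect_equal(nrow(cmp$table), 8L)
  expect_equal(as.integer(table(cmp$table$class)), rep(2L, 4))
  expect_equal(cmp$table$model[1:2], c("text", "mlp"))
  rev_ <- compare_models(rb, ra, names = c("mlp", "text"))
  expect_equal(cmp$delta$delta_f1, -rev_$delta$delta_f1)
  same <- compare_models(ra, ra)
  expect_true(all(same$delta$delta_precision == 0))
  rb3 <- metrics(confusion(rep(1:3, 4), rep(1:3, 4), 3))
  expect_error(compare_models(ra, rb3), "class set")
})

test_that("metrics and confusion CSVs are written", {
  y <- rep(1:3, times = c(3, 6, 3))
  m <- metrics(confusion(y, rev(y), 3))
  dir <- withr::local_tempdir()
  write_metrics(m, file.path(dir, "m.csv"), file.path(dir, "cm.csv"))
  back <- readr::read_csv(file.path(dir, "m.csv"), show_col_types = FALSE)
  expect_equal(back$precision, m$by_class$precision)
  cmback <- readr::read_csv(file.path(dir, "cm.csv"), show_col_types = FALSE)
  expect_equal(dim(cmback), c(3L, 4L))
})
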