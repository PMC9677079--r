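# Confusion counts, the four performance metrics, and the ablation grid.

test_that("confusion counts tally one-vs-rest statistics", {
  # perfect predictions on a balanced 4 x 200 problem
  y <- rep(0:3, each = 200)
  cm <- confusion_matrix(y, y, 4)
  expect_true(all(cm$per_class$tp == 200))
  expect_true(all(cm$per_class$fp == 0) && all(cm$per_class$fn == 0))
  expect_true(all(cm$per_class$tp + cm$per_class$tn + cm$per_class$fp +
                    cm$per_class$fn == cm$N))
  # degenerate predictor: everything called class 0
  cm0 <- confusion_matrix(y, rep(0L, 800), 4)
  expect_identical(cm0$per_class$tp[1], 200L)
  expect_identical(cm0$per_class$fp[1], 600L)
  expect_identical(cm0$per_class$tp[2], 0L)
  expect_identical(sum(diag(cm0$table)), 200L)
  expect_error(confusion_matrix(integer(0), integer(0), 4), "empty")
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 4), "lie in")
})

test_that("metrics match direct substitution and a brute-force implementation", {
  y <- rep(0:3, each = 200)
  expect_true(all(classification_metrics(confusion_matrix(y, y, 4))[, 1:4] == 1))
  # binary counts TP=8, FP=2, FN=2, TN=8 for the positive class
  yt <- c(rep(1L, 10), rep(0L, 10))
  yp <- c(rep(1L, 8), 0L, 0L, rep(0L, 8), 1L, 1L)
  pc <- tidy(confusion_matrix(yt, yp, 2))
  expect_equal(pc$precision[2], 0.8)
  expect_equal(pc$recall[2], 0.8)
  expect_equal(pc$f1[2], 0.8)
  # brute-force oracle over the full m x m matrix, random labels
  withr::with_seed(5, {
    for (rep in 1:5) {
      m <- sample(2:5, 1); n <- 200
      yt <- sample(0:(m - 1), n, TRUE)
      yp <- sample(0:(m - 1), n, TRUE)
      got_w <- classification_metrics(confusion_matrix(yt, yp, m), "weighted")
      got_m <- classification_metrics(confusion_matrix(yt, yp, m), "macro")
      prec <- rec <- f1 <- sup <- numeric(m)
      for (k in 0:(m - 1)) {
        tp <- sum(yt == k & yp == k); fp <- sum(yt != k & yp == k)
        fn <- sum(yt == k & yp != k)
        prec[k + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec[k + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
        f1[k + 1] <- if (prec[k + 1] + rec[k + 1] > 0)
          2 * prec[k + 1] * rec[k + 1] / (prec[k + 1] + rec[k + 1]) else 0
        sup[k + 1] <- sum(yt == k)
      }
      expect_equal(got_w$accuracy, mean(yt == yp), tolerance = 1e-12)
      expect_equal(got_w$precision, sum(prec * sup / n), tolerance = 1e-12)
      expect_equal(got_w$recall, sum(rec * sup / n), tolerance = 1e-12)
      expect_equal(got_w$f1, sum(f1 * sup / n), tolerance = 1e-12)
      expect_equal(got_m$recall, mean(rec), tolerance = 1e-12)
    }
  })
})

test_that("on balanced labels weighted recall equals accuracy and matches macro", {
  withr::with_seed(6, {
    y <- rep(0:3, each = 50)
    p <- sample(0:3, 200, TRUE)
    cm <- confusion_matrix(y, p, 4)
    w <- classification_metrics(cm, "weighted")
    mac <- classification_metrics(cm, "macro")
    expect_equal(w$recall, w$accuracy, tolerance = 1e-12)
    expect_equal(w$recall, mac$recall, tolerance = 1e-12)
    expect_equal(w$precision, mac$precision, tolerance = 1e-12)
  })
})

test_that("metric identities hold across random confusion tables", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      y <- sample(0:2, 60, TRUE)
      p <- sample(0:2, 60, TRUE)
      cm <- suppressWarnings(confusion_matrix(y, p, 3))
      met <- suppressWarnings(classification_metrics(cm))
      pc <- tidy(cm)
      expect_true(met$accuracy >= 0 && met$accuracy <= 1)
      expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
      expect_true(all((pc$f1 == 0) == (pc$precision * pc$recall == 0)))
    }
  })
})

test_that("the ablation grid enumerates the six published variants", {
  v <- ablation_variants()
  expect_identical(nrow(v), 6L)
  expect_identical(sum(v$use_mresblock), 3L)
  expect_identical(as.character(sort(unique(v$dropout_kind))),
                   c("alpha", "none", "standard"))
  # within each residual-block arm, all three dropout conditions appear
  expect_identical(sort(v$dropout_kind[v$use_mresblock]), sort(v$dropout_kind[!v$use_mresblock]))
})

test_that("identical variant flags and seed give identical ablation rows", {
  root <- fixture_dataset(0.0026)
  data <- list(train = load_split(root, "train"), test = load_split(root, "test"))
  twice <- ablation_variants()[c(1, 1), ]
  cfg <- train_config(epochs = 1, augment = FALSE, learning_rate = 1e-3,
                      monitor = "accuracy", seed = 21, batch_size = 4)
  res <- run_ablation(data, cfg, variants = twice, seed = 22)
  expect_identical(nrow(res), 2L)
  expect_equal(res$test_accuracy[1], res$test_accuracy[2], tolerance = 1e-12)
  expect_equal(res$test_f1[1], res$test_f1[2], tolerance = 1e-12)
  expect_true(all(c("test_accuracy", "test_precision", "test_recall", "test_f1")
                  %in% names(res)))
})
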