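# Loss, schedule, preprocessing, augmentation, and the training loop.

test_that("categorical cross-entropy matches closed forms and a brute-force oracle", {
  expect_lt(cce_loss(one_hot(0L, 4), matrix(c(1, 0, 0, 0), 1)), 1e-6)
  expect_equal(cce_loss(one_hot(0L, 4), matrix(0.25, 1, 4)), log(4), tolerance = 1e-12)
  # mean reduction over observations
  y <- one_hot(c(0L, 1L), 2)
  p <- rbind(c(0.9, 0.1), c(0.4, 0.6))
  l1 <- cce_loss(y[1, , drop = FALSE], p[1, , drop = FALSE])
  l2 <- cce_loss(y[2, , drop = FALSE], p[2, , drop = FALSE])
  expect_equal(cce_loss(y, p), (l1 + l2) / 2, tolerance = 1e-12)
  # brute-force per-element oracle on random valid (Y, P)
  withr::with_seed(1, {
    n <- 50; m <- 4
    lab <- sample(0:(m - 1), n, TRUE)
    pr <- matrix(stats::rgamma(n * m, 1), n, m)
    pr <- pr / rowSums(pr)
    oracle <- 0
    for (o in 1:n) {
      for (c in 1:m) {
        yoc <- as.numeric(lab[o] == c - 1)
        oracle <- oracle - yoc * log(max(pr[o, c], 1e-7))
      }
    }
    expect_equal(cce_loss(one_hot(lab, m), pr), oracle / n, tolerance = 1e-10)
  })
  expect_error(cce_loss(one_hot(0L, 4), matrix(0.5, 1, 2)), "shape mismatch")
  expect_error(cce_loss(matrix(c(0.5, 0.5, 0, 0), 1), matrix(0.25, 1, 4)), "one-hot")
})

test_that("plateau schedule halves after patience and clamps at the floor", {
  s <- plateau_schedule(1e-5, 0.5, 2, 1e-6)
  # improvement resets the counter and keeps the rate
  s <- schedule_step(s, 0.5)
  s <- schedule_step(s, 0.6)
  expect_equal(s$current_lr, 1e-5)
  expect_identical(s$epochs_since_improvement, 0L)
  # two consecutive non-improving epochs halve it
  s <- schedule_step(s, 0.6) # tie counts as no improvement
  s <- schedule_step(s, 0.55)
  expect_equal(s$current_lr, 5e-6)
  # at the floor it stays put
  sf <- plateau_schedule(1e-6, 0.5, 2, 1e-6)
  sf <- schedule_step(schedule_step(schedule_step(sf, 1), 0.5), 0.5)
  expect_equal(sf$current_lr, 1e-6)
})

test_that("a never-improving metric walks the exact halving trace to the floor", {
  s <- plateau_schedule(1e-5)
  trace <- numeric(20)
  for (e in 1:20) {
    trace[e] <- s$current_lr
    s <- schedule_step(s, 0.5) # constant metric: improves only over -Inf once
  }
  expect_identical(unique(trace), c(1e-5, 5e-6, 2.5e-6, 1.25e-6, 1e-6))
  expect_equal(s$current_lr, 1e-6)
  # trace is non-increasing and bounded below by the floor
  expect_true(all(diff(trace) <= 0))
  expect_true(all(trace >= 1e-6))
  # number of distinct values is bounded by the halving depth
  expect_lte(length(unique(trace)), 1 + ceiling(log2(1e-5 / 1e-6)) + 1)
})

test_that("preprocessing rescales by 1/255 and validates its input", {
  img255 <- array(255, c(4, 4, 3))
  expect_equal(preprocess(img255), array(1, c(4, 4, 3)))
  expect_equal(preprocess(array(0, c(4, 4, 3))), array(0, c(4, 4, 3)))
  expect_equal(preprocess(array(51, c(2, 2, 3)))[1], 0.2)
  expect_error(preprocess(array(1, c(4, 4, 2))), "H x W x 3")
  expect_error(preprocess(array(300, c(4, 4, 3))), "outside")
  resized <- preprocess(array(128, c(8, 8, 3)), image_size = c(4, 4))
  expect_identical(dim(resized), c(4L, 4L, 3L))
})

test_that("augmentation is identity by default, mirrors exactly, and is seed-deterministic", {
  img <- withr::with_seed(2, array(stats::runif(6 * 6 * 3), c(6, 6, 3)))
  expect_identical(augment_image(img), img)
  flipped <- augment_image(img, hflip = TRUE)
  expect_identical(flipped, img[, 6:1, , drop = FALSE]) # index-reversal oracle
  expect_identical(augment_image(flipped, hflip = TRUE), img)
  vflipped <- augment_image(img, vflip = TRUE)
  expect_identical(vflipped, img[6:1, , , drop = FALSE])
  a1 <- withr::with_seed(3, endofuse:::random_augment(img))
  a2 <- withr::with_seed(3, endofuse:::random_augment(img))
  expect_identical(a1, a2)
  rot <- augment_image(img, angle = 10)
  expect_identical(dim(rot), dim(img))
})

test_that("train config defaults follow the published hyper-parameters", {
  cfg <- train_config()
  expect_identical(cfg$batch_size, 8L)
  expect_identical(cfg$epochs, 25L)
  expect_identical(cfg$optimizer, "adam")
  expect_equal(cfg$learning_rate, 1e-5)
  expect_equal(cfg$rescale, 1 / 255)
  expect_equal(cfg$lr_factor, 0.5)
  expect_identical(cfg$lr_patience, 2L)
  expect_equal(cfg$lr_floor, 1e-6)
})

test_that("a short training run produces a coherent, reproducible history", {
  root <- fixture_dataset(0.0026) # 2 images per class per split
  tr <- load_split(root, "train")
  expect_error(train(assemble_model(seed = 1),
                     list(train = list(images = list(), labels = integer()))),
               "empty")
  cfg <- train_config(epochs = 2, augment = FALSE, learning_rate = 1e-3,
                      monitor = "accuracy", seed = 11, batch_size = 4)
  m <- assemble_model(seed = 12)
  feats <- list(train = precompute_features(m, tr$images))
  fit <- train(m, list(train = tr), cfg, features = feats)
  h <- fit$history
  expect_identical(nrow(h), 2L)
  expect_true(all(is.finite(h$loss)))
  expect_true(all(h$accuracy >= 0 & h$accuracy <= 1))
  # learning-rate trace equals an independent simulation of the schedule
  # on the recorded metric sequence (the recurrence oracle)
  s <- plateau_schedule(cfg$learning_rate, cfg$lr_factor, cfg$lr_patience, cfg$lr_floor)
  for (e in seq_len(nrow(h))) {
    expect_equal(h$lr[e], s$current_lr)
    s <- schedule_step(s, h$accuracy[e])
  }
  # determinism: identical seed, identical trace
  fit2 <- train(assemble_model(seed = 12), list(train = tr), cfg, features = feats)
  expect_equal(fit$history$loss, fit2$history$loss, tolerance = 1e-12)
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit$history), "ggplot")
})

test_that("training learns a trivially separable two-class problem", {
  # two visually distinct synthetic classes at full resolution
  root <- file.path(tempdir(), "twoclass")
  if (!dir.exists(root)) {
    lay <- dataset_layout(classes = c("normal", "polyps"), train = 8, validation = 2,
                          test = 4)
    generate_dataset(root, lay, seed = 33, scale = 1)
  }
  tr <- load_split(root, "train")
  m <- assemble_model(num_classes = 2, seed = 13)
  cfg <- train_config(epochs = 6, augment = FALSE, learning_rate = 1e-3,
                      monitor = "accuracy", seed = 14)
  fit <- train(m, list(train = tr), cfg)
  # rises well above chance within ten epochs on separable classes
  expect_gt(max(fit$history$accuracy), 0.9)
})
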