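# Correctness of the layer-graph engine itself: compiled kernels against
# naive double-precision oracles, and backpropagated gradients against
# central finite differences on a small graph.

test_that("compiled convolution matches a naive direct-convolution oracle", {
  cases <- list(
    list(h = 5, w = 6, c = 3, f = 4, k = c(3, 3), s = c(1, 1), p = c(0, 0, 0, 0), bias = TRUE),
    list(h = 7, w = 7, c = 2, f = 3, k = c(3, 3), s = c(2, 2), p = c(0, 1, 0, 1), bias = FALSE),
    list(h = 6, w = 5, c = 4, f = 2, k = c(1, 1), s = c(1, 1), p = c(0, 0, 0, 0), bias = TRUE),
    list(h = 9, w = 9, c = 1, f = 2, k = c(5, 5), s = c(2, 2), p = c(1, 2, 1, 2), bias = FALSE)
  )
  for (cs in cases) {
    x <- random_image_batch(cs$h, cs$w, cs$c, n = 2, seed = cs$h * 10 + cs$f)
    w <- withr::with_seed(3, array(rnorm(prod(cs$k) * cs$c * cs$f), c(cs$k, cs$c, cs$f)))
    b <- if (cs$bias) withr::with_seed(4, rnorm(cs$f)) else numeric(0)
    got <- endofuse:::cpp_conv2d_fwd(x, dim(x), w, dim(w), b,
                                     cs$s[1], cs$s[2], cs$p[1], cs$p[2], cs$p[3], cs$p[4])
    want <- naive_conv2d(x, w, b, cs$s, cs$p)
    expect_equal(dim(got), dim(want))
    expect_lt(max(abs(got - want)), 1e-5) # float32 working precision
  }
})

test_that("depthwise convolution parameter count and values are per-channel", {
  x <- random_image_batch(6, 6, 3, n = 1, seed = 5)
  w <- withr::with_seed(6, array(rnorm(3 * 3 * 3), c(3, 3, 3)))
  got <- endofuse:::cpp_dwconv_fwd(x, dim(x), w, dim(w), numeric(0),
                                   1, 1, 1, 1, 1, 1)
  # oracle: each channel convolved with its own kernel
  for (c in 1:3) {
    wc <- array(0, c(3, 3, 1, 1)); wc[, , 1, 1] <- w[, , c]
    xc <- x[, , c, , drop = FALSE]
    want <- naive_conv2d(xc, wc, numeric(0), c(1, 1), c(1, 1, 1, 1))
    expect_lt(max(abs(got[, , c, 1] - want[, , 1, 1])), 1e-10)
  }
})

test_that("pooling kernels match direct oracles", {
  x <- random_image_batch(6, 6, 2, n = 2, seed = 7) - 0.5
  mp <- endofuse:::cpp_maxpool_fwd(x, dim(x), 3, 3, 2, 2, 1, 1, 1, 1)
  ap <- endofuse:::cpp_avgpool_fwd(x, dim(x), 2, 2, 2, 2)
  for (n in 1:2) for (c in 1:2) {
    padded <- matrix(0, 8, 8); padded[2:7, 2:7] <- x[, , c, n]
    for (i in 1:3) for (j in 1:3) {
      win <- padded[(2 * i - 1):(2 * i + 1), (2 * j - 1):(2 * j + 1)]
      expect_equal(mp[i, j, c, n], max(win))
    }
    for (i in 1:3) for (j in 1:3) {
      win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n]
      expect_equal(ap[i, j, c, n], mean(win))
    }
  }
})

test_that("backpropagated gradients match finite differences on a small head graph", {
  # miniature analogue of the real head: conv -> selu -> avgpool ->
  # alpha-dropout-free path -> batchnorm -> selu -> conv -> add(Wq) ->
  # gap -> dense -> softmax, all trainable
  g <- withr::with_seed(11, {
    g <- endofuse:::lg_new(list(branch = c(6L, 6L, 3L)))
    g <- endofuse:::add_conv(g, "c1", "branch", 4, 3, padding = "valid",
                             use_bias = TRUE, init = "lecun")
    g <- endofuse:::add_act(g, "a1", "c1", "selu")
    g <- endofuse:::add_pool(g, "p1", "a1", "avgpool", 2)
    g <- endofuse:::add_bn(g, "bn1", "p1")
    g <- endofuse:::add_act(g, "a2", "bn1", "selu")
    g <- endofuse:::add_conv(g, "c2", "a2", 4, 3, padding = "same",
                             use_bias = FALSE, init = "lecun")
    g <- endofuse:::add_conv(g, "wq", "p1", 4, 1, use_bias = TRUE, init = "lecun")
    g <- endofuse:::lg_add(g, "addn", "add", c("wq", "c2"))
    g <- endofuse:::lg_add(g, "gap", "gap", "addn")
    g <- endofuse:::add_dense(g, "dense", "gap", 3)
    endofuse:::lg_add(g, "sm", "softmax", "dense")
  })
  x <- random_image_batch(6, 6, 3, n = 4, seed = 12)
  y <- one_hot(c(0L, 1L, 2L, 1L), 3)

  # training-mode forward is deterministic here (no dropout nodes), so the
  # finite-difference oracle evaluates exactly the function backprop sees,
  # including the dependence of the batch statistics on upstream weights
  loss_for <- function(graph) {
    p <- endofuse:::forward_pass(graph, list(branch = x), training = TRUE)$out
    cce_loss(y, p, clip = 1e-12)
  }
  fwd <- endofuse:::forward_pass(g, list(branch = x), training = TRUE, keep_all = TRUE)
  dz <- (fwd$out - y) / 4
  grads <- endofuse:::backward_pass(g, fwd$values, fwd$cache, "dense", dz)

  for (nm in c("c1", "c2", "wq", "dense")) {
    for (p in names(grads[[nm]])) {
      # eps balances truncation against the float32 working precision of
      # the convolution kernels
      gn <- numeric_grad(function(v) {
        gg <- g; gg$nodes[[nm]]$params[[p]] <- v
        loss_for(gg)
      }, g$nodes[[nm]]$params[[p]], eps = 1e-3)
      ga <- grads[[nm]][[p]]
      expect_lt(max(abs(ga - gn)) / (max(abs(gn)) + 1e-8), 2e-3,
                label = sprintf("gradient mismatch at %s/%s", nm, p))
    }
  }
})

test_that("batch-norm training mode standardizes per channel and its gradient checks out", {
  g <- withr::with_seed(21, {
    g <- endofuse:::lg_new(list(x = c(4L, 4L, 3L)))
    endofuse:::add_bn(g, "bn", "x")
  })
  x <- random_image_batch(4, 4, 3, n = 5, seed = 22) * 3 + 1
  fwd <- endofuse:::forward_pass(g, list(x = x), training = TRUE, keep_all = TRUE)
  out <- fwd$out
  for (c in 1:3) {
    v <- as.numeric(out[, , c, ])
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(stats::var(v) * (length(v) - 1) / length(v), 1, tolerance = 1e-2)
  }
  # gradient of sum(out * r) w.r.t. gamma/beta via finite differences
  r <- withr::with_seed(23, array(rnorm(length(out)), dim(out)))
  grads <- endofuse:::backward_pass(g, fwd$values, fwd$cache, "bn", r)
  for (p in c("gamma", "beta")) {
    gn <- numeric_grad(function(v) {
      gg <- g; gg$nodes$bn$params[[p]] <- v
      sum(endofuse:::forward_pass(gg, list(x = x), training = TRUE)$out * r)
    }, g$nodes$bn$params[[p]])
    expect_lt(max(abs(grads$bn[[p]] - gn)) / max(abs(gn)), 1e-4)
  }
})

test_that("parameter totals are additive over nodes and summaries agree", {
  g <- build_compressed_mobilenetv2(c(64, 64, 3), seed = 1)
  df <- tidy(g)
  expect_equal(sum(df$params), count_parameters(g))
  expect_equal(glance(g)$total_params, count_parameters(g))
  expect_true(all(df$kind %in% c("input", "conv", "dwconv", "bn", "act",
                                 "maxpool", "avgpool", "gap", "dense", "softmax",
                                 "add", "concat", "scale", "dropout", "alpha_dropout")))
})
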