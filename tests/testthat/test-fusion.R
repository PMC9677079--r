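# Shape equalization, fusion, the modified residual block, and full model
# assembly.

branch_shapes <- list(
  resnet50v2 = c(28L, 28L, 512L),
  mobilenetv2 = c(14L, 14L, 96L),
  efficientnetb0 = c(7L, 7L, 192L)
)

head_spec_for <- function(backbone) {
  row <- auxiliary_head_table()
  row <- row[row$backbone == backbone, ]
  auxiliary_head_spec(conv_filters = row$conv_filters, conv_kernel = row$conv_kernel,
                      conv_stride = row$conv_stride, pool_size = row$pool_size,
                      pool_stride = row$pool_stride, dropout_rate = row$dropout_rate)
}

test_that("each auxiliary head equalizes its branch to 7x7x192 (calculator and live pass)", {
  for (nm in names(branch_shapes)) {
    g <- build_auxiliary_head(head_spec_for(nm), branch_shapes[[nm]], seed = 1)
    expect_identical(g$nodes[[g$output_name]]$out_shape, c(7L, 7L, 192L), label = nm)
    x <- random_image_batch(branch_shapes[[nm]][1], branch_shapes[[nm]][2],
                            branch_shapes[[nm]][3], n = 2, seed = 2)
    out <- endofuse:::forward_pass(g, list(branch = x))$out
    expect_identical(dim(out), c(7L, 7L, 192L, 2L), label = nm)
    expect_true(all(is.finite(out)))
  }
  # published valid-padding arithmetic for the deepest branch:
  # (28 - 6) + 1 = 23, then floor((23 - 3) / 3) + 1 = 7
  g <- build_auxiliary_head(head_spec_for("resnet50v2"), c(28, 28, 512), seed = 1)
  expect_identical(g$nodes[["aux_conv"]]$out_shape, c(23L, 23L, 192L))
})

test_that("infeasible head arithmetic fails naming the offending dimension", {
  spec <- auxiliary_head_spec(conv_kernel = 8)
  expect_error(build_auxiliary_head(spec, c(5, 14, 96)), "height")
  expect_error(build_auxiliary_head(spec, c(14, 5, 96)), "width")
})

test_that("fusion concatenates channels over identical spatial grids", {
  b <- lapply(1:3, function(i) random_image_batch(7, 7, 192, n = 2, seed = i))
  fused <- fuse(b)
  expect_identical(dim(fused), c(7L, 7L, 576L, 2L))
  expect_identical(fused[, , 1:192, ], b[[1]])
  expect_identical(fused[, , 193:384, ], b[[2]])
  one <- random_image_batch(7, 7, 192, n = 1, seed = 9)
  expect_identical(fuse(list(one)), one)
  expect_error(fuse(list(one, random_image_batch(6, 6, 192, n = 1, seed = 1))),
               "mismatched spatial dims")
})

test_that("the modified residual block has the published structure and count", {
  g <- build_mresblock(c(7, 7, 576), width = 192, seed = 3)
  expect_identical(g$nodes[[g$output_name]]$out_shape, c(7L, 7L, 192L))
  # two BN -> SeLU -> Conv stages plus the 1x1 projection
  kinds <- vapply(g$nodes, function(n) n$kind, character(1))
  expect_identical(unname(kinds[c("mres_bn1", "mres_act1", "mres_conv1")]),
                   c("bn", "act", "conv"))
  expect_identical(unname(kinds[c("mres_bn2", "mres_act2", "mres_convn")]),
                   c("bn", "act", "conv"))
  expect_identical(g$nodes[["mres_wq"]]$hyper$kernel_shape[1:2], c(1L, 1L))
  # convolution scalars: 3x3x576x192 (bias-free; a BN follows) +
  # 3x3x192x192+192 + 1x1x576x192+192
  conv_params <- sum(vapply(c("mres_conv1", "mres_convn", "mres_wq"),
                            function(nm) sum(lengths(g$nodes[[nm]]$params)), numeric(1)))
  expect_equal(conv_params, 1438080)
  bn_trainable <- 2 * 576 + 2 * 192
  expect_equal(count_parameters(g, trainable_only = TRUE), 1438080 + bn_trainable)
})

test_that("zeroing the residual function reduces the block to its projection (bitwise)", {
  g <- build_mresblock(c(7, 7, 576), width = 192, seed = 4)
  g$nodes$mres_conv1$params$w[] <- 0
  g$nodes$mres_convn$params$w[] <- 0
  g$nodes$mres_convn$params$b[] <- 0
  x <- random_image_batch(7, 7, 576, n = 1, seed = 5)
  got <- endofuse:::forward_pass(g, list(fused = x))$out
  wq <- g$nodes$mres_wq
  want <- endofuse:::cpp_conv2d_fwd(x, dim(x), wq$params$w, dim(wq$params$w),
                                    wq$params$b, 1, 1, 0, 0, 0, 0)
  expect_identical(got, want)
})

test_that("the assembled model is softmax-normalized with the expected trainable split", {
  m <- assemble_model(num_classes = 4, seed = 6, calibrate = FALSE)
  x <- random_image_batch(224, 224, 3, n = 3, seed = 7)
  p <- endofuse:::model_forward(m, x)
  expect_identical(dim(p), c(3L, 4L))
  expect_true(all(is.finite(p)))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  # trainable = aux heads + MResBlock + classifier only
  aux <- (6 * 6 * 512 * 192 + 192) + (8 * 8 * 96 * 192 + 192) + (1 * 1 * 192 * 192 + 192)
  mres <- 1438080 + 2 * 576 + 2 * 192
  clf <- 192 * 4 + 4
  expect_equal(count_parameters(m, trainable_only = TRUE), aux + mres + clf)
  expect_equal(count_parameters(m),
               sum(vapply(c(m$backbones, list(m$head)), count_parameters, numeric(1))))
  expect_error(assemble_model(num_classes = 1), "num_classes")
})

test_that("every trainable weight receives a finite, somewhere-nonzero gradient", {
  m <- assemble_model(num_classes = 4, seed = 8, calibrate = FALSE)
  feats <- lapply(branch_shapes[c("efficientnetb0", "mobilenetv2", "resnet50v2")],
                  function(s) random_image_batch(s[1], s[2], s[3], n = 2, seed = s[3]))
  names(feats) <- paste0(names(feats), "_branch")
  y <- one_hot(c(0L, 2L), 4)
  withr::with_seed(9, {
    fwd <- endofuse:::forward_pass(m$head, feats, training = TRUE, keep_all = TRUE)
    dz <- (fwd$out - y) / 2
    grads <- endofuse:::backward_pass(m$head, fwd$values, fwd$cache, "head_dense", dz)
  })
  trainable <- names(Filter(function(n) n$trainable, m$head$nodes))
  expect_setequal(names(grads), trainable)
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      expect_true(all(is.finite(grads[[nm]][[p]])), label = paste(nm, p))
      expect_true(any(grads[[nm]][[p]] != 0), label = paste(nm, p))
    }
  }
})

test_that("ablation variants rebuild the head accordingly", {
  m_plain <- assemble_model(seed = 10, use_mresblock = FALSE, activation = "relu",
                            dropout_kind = "none", calibrate = FALSE)
  kinds <- vapply(m_plain$head$nodes, function(n) n$kind, character(1))
  expect_false(any(grepl("^mres_", names(kinds))))
  expect_false(any(kinds %in% c("dropout", "alpha_dropout")))
  acts <- vapply(Filter(function(n) n$kind == "act", m_plain$head$nodes),
                 function(n) n$hyper$fun, character(1))
  expect_true(all(acts == "relu"))
  m_std <- assemble_model(seed = 10, dropout_kind = "standard", calibrate = FALSE)
  kinds_std <- vapply(m_std$head$nodes, function(n) n$kind, character(1))
  expect_true("dropout" %in% kinds_std && !"alpha_dropout" %in% kinds_std)
})
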