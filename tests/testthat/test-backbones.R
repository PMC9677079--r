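# Structural fidelity of the three truncated backbones: cut-point shapes,
# exact parameter totals (hand-derived from the reference layer
# definitions), freezing semantics, and the truncation-prefix property.

expected <- list(
  resnet50v2 = list(shape = c(28L, 28L, 512L), total = 1171456),
  mobilenetv2 = list(shape = c(14L, 14L, 96L), total = 558656),
  efficientnetb0 = list(shape = c(7L, 7L, 192L), total = 2912364)
)

test_that("cut-point shapes and parameter totals match the compression settings", {
  for (nm in names(expected)) {
    g <- build_backbone(nm, c(224, 224, 3), seed = 1)
    expect_identical(g$nodes[[g$output_name]]$out_shape, expected[[nm]]$shape,
                     label = nm)
    expect_equal(count_parameters(g), expected[[nm]]$total, label = nm)
  }
  # printed-precision agreement with the published table (floored prints)
  expect_true(count_parameters(build_backbone("resnet50v2", seed = 1)) / 1e6 >= 1.1)
  tb <- backbone_table()
  expect_identical(tb$features, c(192L, 96L, 512L))
  expect_identical(tb$cut_point, c("block6d_add", "block_12_add", "conv3_block3_out"))
})

test_that("cut-point names resolve to the graph output nodes", {
  expect_identical(build_backbone("resnet50v2", seed = 1)$output_name, "conv3_block3_out")
  expect_identical(build_backbone("mobilenetv2", seed = 1)$output_name, "block_12_add")
  expect_identical(build_backbone("efficientnetb0", seed = 1)$output_name, "block6d_add")
})

test_that("live forward pass reproduces every recorded node shape (shape oracle)", {
  g <- build_compressed_resnetv2(c(224, 224, 3), seed = 2)
  x <- random_image_batch(224, 224, 3, 1, seed = 3)
  fwd <- endofuse:::forward_pass(g, list(input = x), keep_all = TRUE)
  for (nm in names(g$nodes)) {
    v <- get(nm, fwd$values)
    got <- if (is.matrix(v)) ncol(v) else dim(v)[seq_along(g$nodes[[nm]]$out_shape)]
    expect_identical(as.integer(got), g$nodes[[nm]]$out_shape, label = nm)
  }
})

test_that("all three backbones produce their cut-point shapes in a live pass", {
  x <- random_image_batch(224, 224, 3, 1, seed = 4)
  for (nm in names(expected)) {
    g <- build_backbone(nm, seed = 5)
    out <- endofuse:::forward_pass(g, list(input = x))$out
    expect_identical(dim(out)[1:3], expected[[nm]]$shape, label = nm)
    expect_true(all(is.finite(out)), label = nm)
  }
})

test_that("stride stack propagates smaller inputs and rejects impossible ones", {
  g <- build_compressed_resnetv2(c(32, 32, 3), seed = 1)
  expect_identical(g$nodes[[g$output_name]]$out_shape, c(4L, 4L, 512L))
  expect_error(build_compressed_resnetv2(c(8, 8, 3), seed = 1), "too small")
  expect_error(build_compressed_resnetv2(c(224, 224, 4)), "H, W, 3")
})

test_that("parameter counting follows the layer definitions", {
  g0 <- endofuse:::lg_new(list(input = c(7L, 7L, 192L)))
  expect_identical(count_parameters(g0), 0) # no layers yet
  g1 <- endofuse:::add_conv(g0, "c", "input", 192, 1, use_bias = TRUE)
  expect_equal(count_parameters(g1), 1 * 1 * 192 * 192 + 192) # 37,056
  expect_equal(count_parameters(g1), 37056)
  # depthwise: k^2 * C kernel scalars (+ C bias when present)
  gm <- build_compressed_mobilenetv2(seed = 1)
  dw <- gm$nodes[["block_1_depthwise"]]
  expect_equal(length(dw$params$w), 3 * 3 * 96)
  # batch-norm: 2 trainable + 2 moving scalars per channel
  bn <- gm$nodes[["bn_Conv1"]]
  expect_equal(sum(lengths(bn$params)) + sum(lengths(bn$buffers)), 4 * 32)
})

test_that("freezing removes trainable parameters without deleting weights", {
  g <- build_compressed_resnetv2(seed = 1)
  total_before <- count_parameters(g)
  gf <- freeze(g)
  expect_identical(count_parameters(gf, trainable_only = TRUE), 0)
  expect_identical(count_parameters(gf), total_before)
  expect_true(all(vapply(gf$nodes, function(n)
    n$kind != "bn" || isTRUE(n$hyper$frozen), logical(1))))
})

test_that("relu6 clamps to [0, 6]", {
  x <- seq(-10, 10, by = 0.25)
  y <- endofuse:::act_fun(x, "relu6")
  expect_true(all(y >= 0 & y <= 6))
  expect_identical(endofuse:::act_fun(8, "relu6"), 6)
  expect_identical(endofuse:::act_fun(0, "swish"), 0)
})

test_that("the compressed graphs are prefixes of the full architecture manifests", {
  ded <- c(efficientnetb0 = 1L, mobilenetv2 = 4L, resnet50v2 = 2L)
  for (nm in names(ded)) {
    units <- attr(build_backbone(nm, seed = 1), "units")
    full <- backbone_manifest(nm)
    expect_identical(units, full[seq_along(units)], label = nm)
    expect_identical(length(full) - length(units), ded[[nm]], label = nm)
  }
})
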