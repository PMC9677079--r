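#' Compression settings of the three fused backbones
#'
#' One row per backbone: the layer name at which the pretrained feature
#' extractor is truncated (everything after it is discarded), the number of
#' feature maps the cut-point emits, the parameter total of the truncated
#' network as printed at its reference precision, the training status, and
#' the number of architectural units removed.
#'
#' @return A tibble with columns `name`, `cut_point`, `features`,
#'   `params_printed`, `frozen`, `blocks_deducted`.
#' @export
backbone_table <- function() {
  tibble::tibble(
    name = c("efficientnetb0", "mobilenetv2", "resnet50v2"),
    cut_point = c("block6d_add", "block_12_add", "conv3_block3_out"),
    features = c(192L, 96L, 512L),
    params_printed = c("2.9M", "558K", "1.1M"),
    frozen = TRUE,
    blocks_deducted = c(1L, 4L, 2L)
  )
}

check_input_shape <- function(input_shape) {
  if (length(input_shape) != 3 || input_shape[3] != 3) {
    abort("input_shape must be c(H, W, 3)")
  }
  if (any(input_shape[1:2] < 32)) {
    abort(sprintf(
      "input shape %s is too small for the stride stack: the reference architectures downsample by 32, so spatial dims must be at least 32",
      paste(input_shape, collapse = "x")))
  }
  as.integer(input_shape)
}

#' Build a compressed backbone
#'
#' Dispatches to one of the three truncated feature extractors.
#'
#' @param name One of `"resnet50v2"`, `"mobilenetv2"`, `"efficientnetb0"`.
#' @param input_shape Integer vector `c(H, W, 3)`.  The default 224 x 224
#'   is the resolution at which the three cut-points emit the published
#'   28^2 x 512 / 14^2 x 96 / 7^2 x 192 feature shapes.
#' @param seed Optional integer seed for the random (He-normal) weight
#'   initialization; counts and shapes are weight-independent.
#' @return A `layer_graph` ending at the backbone's cut-point.
#' @export
build_backbone <- function(name, input_shape = c(224, 224, 3), seed = NULL) {
  fn <- switch(match.arg(name, backbone_table()$name),
    resnet50v2 = build_compressed_resnetv2,
    mobilenetv2 = build_compressed_mobilenetv2,
    efficientnetb0 = build_compressed_efficientnetb0
  )
  fn(input_shape, seed = seed)
}

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# ---- ResNet50V2 -------------------------------------------------------------

#' Compressed ResNet50V2 feature extractor
#'
#' The pre-activation ResNet50V2 architecture truncated immediately after
#' the residual addition named `conv3_block3_out`: the 7x7/2 entry
#' convolution, 3x3/2 max-pool, the three bottleneck blocks of stage
#' `conv2` (the last with stride 2), and the first three bottleneck blocks
#' of stage `conv3`.  At 224 x 224 x 3 input the output is 28 x 28 x 512
#' and the parameter total is 1,171,456 (printed as 1.1M).
#'
#' @inheritParams build_backbone
#' @return A `layer_graph` whose output node is `conv3_block3_out`.
#' @export
build_compressed_resnetv2 <- function(input_shape = c(224, 224, 3), seed = NULL) {
  input_shape <- check_input_shape(input_shape)
  with_opt_seed(seed, {
    g <- lg_new(list(input = input_shape))
    g <- add_conv(g, "conv1_conv", "input", 64, 7, stride = 2,
                  pad = c(3, 3, 3, 3), use_bias = TRUE, init = "he")
    g <- add_pool(g, "pool1_pool", "conv1_conv", "maxpool", 3, stride = 2,
                  pad = c(1, 1, 1, 1))
    res <- resnet_stack(g, "pool1_pool", 64, blocks = 3, stride_last = 2, stage = "conv2")
    res <- resnet_stack(res$g, res$x, 128, blocks = 3, stride_last = 1, stage = "conv3")
    g <- res$g
    attr(g, "units") <- c("conv1", "conv2", "conv3")
    attr(g, "arch") <- "resnet50v2"
    g
  })
}

# A stack of pre-activation bottleneck blocks.  In the reference
# architecture downsampling happens in the *last* block of a stage; the
# truncated conv3 stage keeps only its first three (stride-1) blocks.
resnet_stack <- function(g, x, filters, blocks, stride_last, stage) {
  for (b in seq_len(blocks)) {
    nm <- sprintf("%s_block%d", stage, b)
    stride <- if (b == blocks) stride_last else 1L
    conv_shortcut <- b == 1L
    res <- resnet_block_v2(g, x, filters, stride, conv_shortcut, nm)
    g <- res$g; x <- res$x
  }
  list(g = g, x = x)
}

resnet_block_v2 <- function(g, x, filters, stride, conv_shortcut, nm) {
  g <- add_bn(g, paste0(nm, "_preact_bn"), x, eps = 1.001e-5)
  g <- add_act(g, paste0(nm, "_preact_relu"), paste0(nm, "_preact_bn"), "relu")
  preact <- paste0(nm, "_preact_relu")
  if (conv_shortcut) {
    g <- add_conv(g, paste0(nm, "_0_conv"), preact, 4 * filters, 1, stride = stride,
                  use_bias = TRUE, init = "he")
    shortcut <- paste0(nm, "_0_conv")
  } else if (stride > 1) {
    g <- add_pool(g, paste0(nm, "_0_pool"), x, "maxpool", 1, stride = stride)
    shortcut <- paste0(nm, "_0_pool")
  } else {
    shortcut <- x
  }
  g <- add_conv(g, paste0(nm, "_1_conv"), preact, filters, 1, use_bias = FALSE, init = "he")
  g <- add_bn(g, paste0(nm, "_1_bn"), paste0(nm, "_1_conv"), eps = 1.001e-5)
  g <- add_act(g, paste0(nm, "_1_relu"), paste0(nm, "_1_bn"), "relu")
  g <- add_conv(g, paste0(nm, "_2_conv"), paste0(nm, "_1_relu"), filters, 3,
                stride = stride, pad = c(1, 1, 1, 1), use_bias = FALSE, init = "he")
  g <- add_bn(g, paste0(nm, "_2_bn"), paste0(nm, "_2_conv"), eps = 1.001e-5)
  g <- add_act(g, paste0(nm, "_2_relu"), paste0(nm, "_2_bn"), "relu")
  g <- add_conv(g, paste0(nm, "_3_conv"), paste0(nm, "_2_relu"), 4 * filters, 1,
                use_bias = TRUE, init = "he")
  g <- lg_add(g, paste0(nm, "_out"), "add", c(shortcut, paste0(nm, "_3_conv")))
  list(g = g, x = paste0(nm, "_out"))
}

# ---- MobileNetV2 ------------------------------------------------------------

#' Compressed MobileNetV2 feature extractor
#'
#' The MobileNetV2 inverted-residual architecture truncated after the
#' residual addition of the 12th bottleneck block (`block_12_add`): the
#' 3x3/2 stem convolution, the expansion-free first bottleneck, and
#' bottlenecks 1-12 (expansion factor 6, ReLU6 clamping, depthwise +
#' pointwise convolutions).  At 224 x 224 x 3 input the output is
#' 14 x 14 x 96 and the parameter total is 558,656 (printed as 558K).
#'
#' @inheritParams build_backbone
#' @return A `layer_graph` whose output node is `block_12_add`.
#' @export
build_compressed_mobilenetv2 <- function(input_shape = c(224, 224, 3), seed = NULL) {
  input_shape <- check_input_shape(input_shape)
  with_opt_seed(seed, {
    g <- lg_new(list(input = input_shape))
    g <- add_conv(g, "Conv1", "input", 32, 3, stride = 2, padding = "same",
                  use_bias = FALSE, init = "he")
    g <- add_bn(g, "bn_Conv1", "Conv1")
    g <- add_act(g, "Conv1_relu", "bn_Conv1", "relu6")
    # first bottleneck has no expansion
    g <- add_dwconv(g, "expanded_conv_depthwise", "Conv1_relu", 3, stride = 1)
    g <- add_bn(g, "expanded_conv_depthwise_BN", "expanded_conv_depthwise")
    g <- add_act(g, "expanded_conv_depthwise_relu", "expanded_conv_depthwise_BN", "relu6")
    g <- add_conv(g, "expanded_conv_project", "expanded_conv_depthwise_relu", 16, 1,
                  use_bias = FALSE, init = "he")
    g <- add_bn(g, "expanded_conv_project_BN", "expanded_conv_project")
    x <- "expanded_conv_project_BN"
    cfg <- list( # (out channels, stride) for bottlenecks 1..12, expansion 6
      c(24, 2), c(24, 1), c(32, 2), c(32, 1), c(32, 1), c(64, 2),
      c(64, 1), c(64, 1), c(64, 1), c(96, 1), c(96, 1), c(96, 1)
    )
    for (i in seq_along(cfg)) {
      res <- mobilenet_block(g, x, cfg[[i]][1], cfg[[i]][2], i)
      g <- res$g; x <- res$x
    }
    attr(g, "units") <- c("Conv1", "expanded_conv", paste0("block_", 1:12))
    attr(g, "arch") <- "mobilenetv2"
    g
  })
}

mobilenet_block <- function(g, x, out_c, stride, i) {
  nm <- paste0("block_", i)
  in_c <- tail(g$nodes[[x]]$out_shape, 1)
  g <- add_conv(g, paste0(nm, "_expand"), x, 6 * in_c, 1, use_bias = FALSE, init = "he")
  g <- add_bn(g, paste0(nm, "_expand_BN"), paste0(nm, "_expand"))
  g <- add_act(g, paste0(nm, "_expand_relu"), paste0(nm, "_expand_BN"), "relu6")
  g <- add_dwconv(g, paste0(nm, "_depthwise"), paste0(nm, "_expand_relu"), 3, stride = stride)
  g <- add_bn(g, paste0(nm, "_depthwise_BN"), paste0(nm, "_depthwise"))
  g <- add_act(g, paste0(nm, "_depthwise_relu"), paste0(nm, "_depthwise_BN"), "relu6")
  g <- add_conv(g, paste0(nm, "_project"), paste0(nm, "_depthwise_relu"), out_c, 1,
                use_bias = FALSE, init = "he")
  g <- add_bn(g, paste0(nm, "_project_BN"), paste0(nm, "_project"))
  out <- paste0(nm, "_project_BN")
  if (stride == 1 && in_c == out_c) {
    g <- lg_add(g, paste0(nm, "_add"), "add", c(x, out))
    out <- paste0(nm, "_add")
  }
  list(g = g, x = out)
}

# ---- EfficientNetB0 ---------------------------------------------------------

#' Compressed EfficientNetB0 feature extractor
#'
#' The EfficientNetB0 MBConv architecture truncated after the final
#' residual addition of stage 6 (`block6d_add`): the 3x3/2 stem, then the
#' mobile inverted-bottleneck blocks of stages 1-6, each with
#' squeeze-and-excitation channel gating (global average pooling, a
#' Swish-activated reduction and a sigmoid-gated expansion), Swish
#' activations throughout, and per-block stochastic-depth dropout on the
#' residual branches.  At 224 x 224 x 3 input the output is 7 x 7 x 192
#' and the parameter total is 2,912,364 (printed as 2.9M).
#'
#' @inheritParams build_backbone
#' @return A `layer_graph` whose output node is `block6d_add`.
#' @export
build_compressed_efficientnetb0 <- function(input_shape = c(224, 224, 3), seed = NULL) {
  input_shape <- check_input_shape(input_shape)
  with_opt_seed(seed, {
    g <- lg_new(list(input = input_shape))
    g <- add_conv(g, "stem_conv", "input", 32, 3, stride = 2, padding = "same",
                  use_bias = FALSE, init = "he")
    g <- add_bn(g, "stem_bn", "stem_conv")
    g <- add_act(g, "stem_activation", "stem_bn", "swish")
    x <- "stem_activation"
    # (out channels, kernel, stride, expansion) per block; letters index
    # repeats within a stage.  16 blocks in the full model; we keep 1..15.
    stages <- list(
      block1a = c(16, 3, 1, 1),
      block2a = c(24, 3, 2, 6), block2b = c(24, 3, 1, 6),
      block3a = c(40, 5, 2, 6), block3b = c(40, 5, 1, 6),
      block4a = c(80, 3, 2, 6), block4b = c(80, 3, 1, 6), block4c = c(80, 3, 1, 6),
      block5a = c(112, 5, 1, 6), block5b = c(112, 5, 1, 6), block5c = c(112, 5, 1, 6),
      block6a = c(192, 5, 2, 6), block6b = c(192, 5, 1, 6), block6c = c(192, 5, 1, 6),
      block6d = c(192, 5, 1, 6)
    )
    for (i in seq_along(stages)) {
      p <- stages[[i]]
      res <- efficientnet_block(g, x, names(stages)[i], out_c = p[1], kernel = p[2],
                                stride = p[3], expand = p[4],
                                drop_rate = 0.2 * (i - 1) / 16)
      g <- res$g; x <- res$x
    }
    attr(g, "units") <- paste0("block", 1:6)
    attr(g, "arch") <- "efficientnetb0"
    g
  })
}

efficientnet_block <- function(g, x, nm, out_c, kernel, stride, expand, drop_rate) {
  in_c <- tail(g$nodes[[x]]$out_shape, 1)
  if (expand != 1) {
    g <- add_conv(g, paste0(nm, "_expand_conv"), x, expand * in_c, 1,
                  use_bias = FALSE, init = "he")
    g <- add_bn(g, paste0(nm, "_expand_bn"), paste0(nm, "_expand_conv"))
    g <- add_act(g, paste0(nm, "_expand_activation"), paste0(nm, "_expand_bn"), "swish")
    h <- paste0(nm, "_expand_activation")
  } else {
    h <- x
  }
  g <- add_dwconv(g, paste0(nm, "_dwconv"), h, kernel, stride = stride)
  g <- add_bn(g, paste0(nm, "_bn"), paste0(nm, "_dwconv"))
  g <- add_act(g, paste0(nm, "_activation"), paste0(nm, "_bn"), "swish")
  act <- paste0(nm, "_activation")
  # squeeze-and-excitation: GAP -> reduce (Swish) -> expand (sigmoid) -> gate
  se_c <- max(1L, in_c %/% 4L)
  mid_c <- tail(g$nodes[[act]]$out_shape, 1)
  g <- lg_add(g, paste0(nm, "_se_squeeze"), "gap", act)
  g <- add_dense(g, paste0(nm, "_se_reduce"), paste0(nm, "_se_squeeze"), se_c, init = "he")
  g <- add_act(g, paste0(nm, "_se_reduce_swish"), paste0(nm, "_se_reduce"), "swish")
  g <- add_dense(g, paste0(nm, "_se_expand"), paste0(nm, "_se_reduce_swish"), mid_c, init = "he")
  g <- add_act(g, paste0(nm, "_se_expand_sigmoid"), paste0(nm, "_se_expand"), "sigmoid")
  g <- lg_add(g, paste0(nm, "_se_excite"), "scale",
              c(act, paste0(nm, "_se_expand_sigmoid")))
  g <- add_conv(g, paste0(nm, "_project_conv"), paste0(nm, "_se_excite"), out_c, 1,
                use_bias = FALSE, init = "he")
  g <- add_bn(g, paste0(nm, "_project_bn"), paste0(nm, "_project_conv"))
  out <- paste0(nm, "_project_bn")
  if (stride == 1 && in_c == out_c) {
    # stochastic-depth dropout on the residual branch (inference no-op)
    g <- lg_add(g, paste0(nm, "_drop"), "dropout", out, hyper = list(rate = drop_rate))
    g <- lg_add(g, paste0(nm, "_add"), "add", c(x, paste0(nm, "_drop")))
    out <- paste0(nm, "_add")
  }
  list(g = g, x = out)
}

# ---- manifests and the truncation property ----------------------------------

#' Layer-sequence manifest of a full reference backbone
#'
#' Returns the ordered architectural units of the *uncompressed* reference
#' architecture (no weights instantiated), at the granularity the
#' compression settings count: stages for ResNet50V2 and EfficientNetB0,
#' bottleneck blocks for MobileNetV2.  A compressed backbone's unit list
#' (attribute `"units"` of the built graph) is a strict prefix of this
#' manifest, and the difference in length equals the published number of
#' deducted units.
#'
#' @param name Backbone name as in [backbone_table()].
#' @return Character vector of unit names, in order.
#' @export
backbone_manifest <- function(name) {
  switch(match.arg(name, backbone_table()$name),
    resnet50v2 = c("conv1", "conv2", "conv3", "conv4", "conv5"),
    mobilenetv2 = c("Conv1", "expanded_conv", paste0("block_", 1:16)),
    efficientnetb0 = paste0("block", 1:7)
  )
}

#' Calibrate a backbone's batch-norm statistics before freezing
#'
#' A pretrained backbone carries batch-norm running statistics that
#' describe real activations, so freezing it yields well-scaled features.
#' A randomly initialized backbone frozen with the (0, 1) placeholder
#' statistics does not: activations grow unnormalized through the depth
#' and per-channel scales diverge by orders of magnitude, which
#' ill-conditions everything trained on top.  This routine runs a probe
#' batch through the graph and sets every batch-norm's moving mean and
#' variance to the actual moments of its input, layer by layer (each
#' layer's probe activations already reflect the calibrated layers below
#' it) — restoring the well-scaled regime the architecture assumes.
#'
#' @param graph A `layer_graph` with an `input` node.
#' @param images Optional probe images `[H, W, 3, N]`; by default a
#'   deterministic uniform-noise probe is used.
#' @param n_probe Number of noise probe images when `images` is `NULL`.
#' @param seed Seed for the noise probe.
#' @return The graph with calibrated batch-norm buffers.
#' @export
calibrate_backbone <- function(graph, images = NULL, n_probe = 4, seed = 1) {
  in_shape <- graph$nodes[[graph$input_names[[1]]]]$out_shape
  if (is.null(images)) {
    images <- withr::with_seed(seed,
      array(runif(prod(in_shape) * n_probe), c(in_shape, n_probe)))
  }
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  values <- new.env(parent = emptyenv())
  ncons <- new.env(parent = emptyenv())
  for (node in graph$nodes) for (nm in node$inputs) {
    assign(nm, (mget(nm, ncons, ifnotfound = 0L)[[1]]) + 1L, ncons)
  }
  assign(graph$input_names[[1]], images, values)
  for (node in graph$nodes) {
    if (node$kind == "input") next
    xs <- lapply(node$inputs, function(nm) get(nm, values))
    if (node$kind == "bn") {
      x <- xs[[1]]
      d <- dim(x); C <- d[3]
      m <- matrix(x, d[1] * d[2], C * d[4])
      mu <- rowMeans(matrix(colMeans(m), C, d[4]))
      m2 <- rowMeans(matrix(colMeans(m * m), C, d[4]))
      graph$nodes[[node$name]]$buffers$mean <- mu
      graph$nodes[[node$name]]$buffers$var <- pmax(m2 - mu^2, 0)
      node <- graph$nodes[[node$name]]
    }
    res <- layer_forward(node, xs, training = FALSE)
    assign(node$name, res$out, values)
    for (nm in node$inputs) {
      k <- get(nm, ncons) - 1L
      assign(nm, k, ncons)
      if (k == 0L) assign(nm, NULL, values)
    }
  }
  graph
}

#' Load backbone weights from file (optional hook)
#'
#' Reads an RDS file containing a named list `layer -> list(param -> array)`
#' and copies matching arrays into the graph.  Shapes must agree.  The test
#' suite never requires pretrained weights; parameter counts and shapes are
#' weight-independent.
#'
#' @param graph A `layer_graph`.
#' @param path Path to an RDS file.
#' @return The graph with weights replaced.
#' @export
load_backbone_weights <- function(graph, path) {
  wts <- readRDS(path)
  for (nm in names(wts)) {
    if (!nm %in% names(graph$nodes)) abort(paste0("no such layer: ", nm))
    for (p in names(wts[[nm]])) {
      cur <- graph$nodes[[nm]]$params[[p]]
      if (is.null(cur)) abort(sprintf("layer '%s' has no parameter '%s'", nm, p))
      new <- wts[[nm]][[p]]
      if (!identical(dim(cur) %||% length(cur), dim(new) %||% length(new))) {
        abort(sprintf("shape mismatch for %s/%s", nm, p))
      }
      graph$nodes[[nm]]$params[[p]] <- new
    }
  }
  graph
}
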