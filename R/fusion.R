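#' Auxiliary-head specifications for shape equalization
#'
#' The three cut-point feature maps (28^2 x 512, 14^2 x 96, 7^2 x 192) are
#' incompatible for layer-wise fusion.  Each branch therefore gets a small
#' head — Conv (f = 192, valid padding, SeLU activation, LeCun-normal
#' initialization) followed by valid average pooling and alpha dropout
#' (rate 0.2) — whose kernel/pool arithmetic maps every branch to exactly
#' 7^2 x 192.
#'
#' @return A tibble, one row per backbone, with the conv kernel `k`,
#'   stride `s`, pool size `p`, pool stride, and dropout rate.
#' @export
auxiliary_head_table <- function() {
  tibble::tibble(
    backbone = c("efficientnetb0", "mobilenetv2", "resnet50v2"),
    conv_filters = 192L,
    conv_kernel = c(1L, 8L, 6L),
    conv_stride = 1L,
    conv_padding = "valid",
    activation = "selu",
    initializer = "lecun",
    pool_size = c(1L, 1L, 3L),
    pool_stride = c(1L, 1L, 3L),
    pool_padding = "valid",
    dropout_rate = 0.2
  )
}

#' Create an auxiliary-head specification
#'
#' @param conv_filters,conv_kernel,conv_stride Convolution filters / kernel
#'   size / stride (valid padding).
#' @param pool_size,pool_stride Average-pool window and stride (valid
#'   padding).
#' @param dropout_rate Alpha-dropout rate.
#' @param activation `"selu"` (default) or `"relu"` (ablation variants).
#' @param initializer `"lecun"` (default, paired with SeLU) or `"he"`.
#' @param dropout_kind `"alpha"`, `"standard"` or `"none"`.
#' @return An object of class `aux_head_spec`.
#' @export
auxiliary_head_spec <- function(conv_filters = 192, conv_kernel, conv_stride = 1,
                                pool_size = 1, pool_stride = pool_size,
                                dropout_rate = 0.2, activation = c("selu", "relu"),
                                initializer = c("lecun", "he"),
                                dropout_kind = c("alpha", "standard", "none")) {
  structure(list(
    conv_filters = as.integer(conv_filters), conv_kernel = as.integer(conv_kernel),
    conv_stride = as.integer(conv_stride), pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride), dropout_rate = dropout_rate,
    activation = match.arg(activation), initializer = match.arg(initializer),
    dropout_kind = match.arg(dropout_kind)
  ), class = "aux_head_spec")
}

# Append the Conv -> AveragePool -> dropout stack to graph `g` after node
# `input`; returns the graph and the name of the head's output node.
append_aux_head <- function(g, input, spec, prefix) {
  g <- add_conv(g, paste0(prefix, "_conv"), input, spec$conv_filters, spec$conv_kernel,
                stride = spec$conv_stride, padding = "valid", use_bias = TRUE,
                init = spec$initializer)
  g <- add_act(g, paste0(prefix, "_act"), paste0(prefix, "_conv"), spec$activation)
  g <- add_pool(g, paste0(prefix, "_pool"), paste0(prefix, "_act"), "avgpool",
                spec$pool_size, stride = spec$pool_stride)
  out <- paste0(prefix, "_pool")
  if (spec$dropout_kind != "none" && spec$dropout_rate > 0) {
    kind <- if (spec$dropout_kind == "alpha") "alpha_dropout" else "dropout"
    g <- lg_add(g, paste0(prefix, "_drop"), kind, out, hyper = list(rate = spec$dropout_rate))
    out <- paste0(prefix, "_drop")
  }
  list(g = g, x = out)
}

#' Build an auxiliary shape-equalizing head
#'
#' Constructs the Conv(f, k, s, SeLU, LeCun-normal) -> AveragePool(p, valid)
#' -> alpha-dropout stack as a standalone graph for a given branch input
#' shape.  Output spatial size follows exact valid-padding arithmetic,
#' `floor((n - k) / s) + 1` per stage.
#'
#' @param spec An [auxiliary_head_spec()].
#' @param input_shape Branch cut-point shape `c(H, W, C)`.
#' @param seed Optional seed for weight initialization.
#' @return A `layer_graph` mapping the branch shape to the equalized shape.
#' @export
build_auxiliary_head <- function(spec, input_shape, seed = NULL) {
  stopifnot(inherits(spec, "aux_head_spec"))
  with_opt_seed(seed, {
    g <- lg_new(list(branch = as.integer(input_shape)))
    append_aux_head(g, "branch", spec, "aux")$g
  })
}

#' Fuse branch feature maps by channel-wise concatenation
#'
#' All branches must share identical spatial dimensions; channels are
#' stacked, so three 7 x 7 x 192 branches fuse to 7 x 7 x 576.  A single
#' branch is returned unchanged.
#'
#' @param branches List of feature arrays, `[H, W, C]` or `[H, W, C, N]`.
#' @return The fused array.
#' @export
fuse <- function(branches) {
  if (!is.list(branches) || length(branches) == 0) abort("fuse: need a non-empty list")
  branches <- lapply(branches, function(b) {
    if (length(dim(b)) == 3) dim(b) <- c(dim(b), 1L)
    b
  })
  dims <- lapply(branches, dim)
  sp <- vapply(dims, function(d) paste(d[1], d[2], sep = "x"), character(1))
  if (length(unique(sp)) > 1) {
    abort(paste0("fuse: mismatched spatial dims: ",
                 paste(vapply(dims, function(d) paste(d[1:3], collapse = "x"), character(1)),
                       collapse = ", ")))
  }
  if (any(vapply(dims, function(d) d[4], integer(1)) != dims[[1]][4])) {
    abort("fuse: mismatched batch sizes")
  }
  if (length(branches) == 1) return(branches[[1]])
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(vapply(dims, function(d) d[3], integer(1))), d1[4]))
  at <- 0L
  for (b in branches) {
    cz <- dim(b)[3]
    out[, , (at + 1):(at + cz), ] <- b
    at <- at + cz
  }
  out
}

# Append the modified residual block to graph `g` after `input`:
# y = (BN -> SeLU -> Conv_W1 -> BN -> SeLU -> Conv_Wn)(x) + Wq x.
# W1 is bias-free (a BN follows it); Wn and the 1x1 projection Wq keep
# biases.  All convs stride 1, same padding, LeCun-normal.
append_mresblock <- function(g, input, width = 192, activation = "selu",
                             init = "lecun", prefix = "mres") {
  g <- add_bn(g, paste0(prefix, "_bn1"), input)
  g <- add_act(g, paste0(prefix, "_act1"), paste0(prefix, "_bn1"), activation)
  g <- add_conv(g, paste0(prefix, "_conv1"), paste0(prefix, "_act1"), width, 3,
                padding = "same", use_bias = FALSE, init = init)
  g <- add_bn(g, paste0(prefix, "_bn2"), paste0(prefix, "_conv1"))
  g <- add_act(g, paste0(prefix, "_act2"), paste0(prefix, "_bn2"), activation)
  g <- add_conv(g, paste0(prefix, "_convn"), paste0(prefix, "_act2"), width, 3,
                padding = "same", use_bias = TRUE, init = init)
  g <- add_conv(g, paste0(prefix, "_wq"), input, width, 1,
                padding = "same", use_bias = TRUE, init = init)
  g <- lg_add(g, paste0(prefix, "_add"), "add",
              c(paste0(prefix, "_wq"), paste0(prefix, "_convn")))
  list(g = g, x = paste0(prefix, "_add"))
}

#' Build a modified residual block
#'
#' The fused-feature refinement block `y = F(x, {W_i}) + W_q x`, where `F`
#' is two pre-activation stages (BN -> SeLU -> Conv) and `W_q` is a 1 x 1
#' projection that equalizes channel counts so the addition is well formed.
#' Spatial dimensions are preserved (stride 1, same padding); the first
#' conv carries no bias (a batch-norm follows it).
#'
#' @param input_shape Fused feature shape `c(H, W, C_in)`.
#' @param width Channels of the `W_1`/`W_n` convolutions and of the output.
#' @param seed Optional seed for weight initialization.
#' @return A `layer_graph` mapping `H x W x C_in` to `H x W x width`.
#' @export
build_mresblock <- function(input_shape, width = 192, seed = NULL) {
  with_opt_seed(seed, {
    g <- lg_new(list(fused = as.integer(input_shape)))
    append_mresblock(g, "fused", width = width)$g
  })
}

#' Assemble the fused classification model
#'
#' Builds the full architecture: the three frozen compressed backbones,
#' one auxiliary shape-equalizing head per branch, channel-wise fusion,
#' the modified residual block, and a classifier head (global average
#' pooling -> alpha dropout 0.2 -> dense softmax).
#'
#' @param num_classes Number of classes (>= 2); 4 for the GI-tract task.
#' @param input_shape Image shape `c(H, W, 3)`.  The published auxiliary
#'   head arithmetic equalizes the three branches only at 224 x 224.
#' @param seed Seed controlling all weight initialization.
#' @param use_mresblock Include the modified residual block (ablation flag).
#' @param activation `"selu"` (with LeCun-normal initialization) or
#'   `"relu"` (with He-normal) for the trainable layers (ablation flag).
#' @param dropout_kind `"alpha"`, `"standard"`, or `"none"` (ablation flag).
#' @param residual_width Channel width of the residual block.
#' @param fusion `"concat"` (default) or `"add"`; the additive variant
#'   averages nothing and requires equal channel counts, provided for the
#'   literal summation reading of the fusion equation.
#' @param calibrate Calibrate the frozen backbones' batch-norm statistics
#'   on a probe batch (see [calibrate_backbone()]); disable only for
#'   purely structural inspection.
#' @param backbones Optional prebuilt (frozen, calibrated) backbone list
#'   to reuse, e.g. across ablation variants.
#' @return An object of class `fused_model` with elements `backbones`
#'   (three frozen `layer_graph`s), `head` (the trainable graph from the
#'   three branch features to class probabilities), `num_classes`,
#'   `input_shape`, and `options`.
#' @export
assemble_model <- function(num_classes = 4, input_shape = c(224, 224, 3), seed = NULL,
                           use_mresblock = TRUE, activation = c("selu", "relu"),
                           dropout_kind = c("alpha", "standard", "none"),
                           residual_width = 192, fusion = c("concat", "add"),
                           calibrate = TRUE, backbones = NULL) {
  if (num_classes < 2) abort("assemble_model: num_classes must be >= 2")
  activation <- match.arg(activation)
  dropout_kind <- match.arg(dropout_kind)
  fusion <- match.arg(fusion)
  init <- if (activation == "selu") "lecun" else "he"
  seed <- seed %||% 42L
  order <- backbone_table()$name
  if (is.null(backbones)) {
    backbones <- lapply(seq_along(order), function(i) {
      b <- build_backbone(order[i], input_shape, seed = seed + i)
      # with random weights the batch-norm statistics must be calibrated
      # before freezing so the cut-point features are well scaled, as they
      # would be coming from a pretrained network
      if (calibrate) b <- calibrate_backbone(b, seed = seed + 50L + i)
      freeze(b)
    })
    names(backbones) <- order
  }
  branch_shapes <- lapply(backbones, function(b) b$nodes[[b$output_name]]$out_shape)

  head <- with_opt_seed(seed + 100L, {
    g <- lg_new(stats::setNames(branch_shapes, paste0(order, "_branch")))
    spec_tbl <- auxiliary_head_table()
    outs <- character(length(order))
    for (i in seq_along(order)) {
      row <- spec_tbl[spec_tbl$backbone == order[i], ]
      spec <- auxiliary_head_spec(
        conv_filters = row$conv_filters, conv_kernel = row$conv_kernel,
        conv_stride = row$conv_stride, pool_size = row$pool_size,
        pool_stride = row$pool_stride, dropout_rate = row$dropout_rate,
        activation = activation, initializer = init, dropout_kind = dropout_kind
      )
      res <- append_aux_head(g, paste0(order[i], "_branch"), spec, paste0("aux_", order[i]))
      g <- res$g
      outs[i] <- res$x
    }
    eq <- lapply(outs, function(o) g$nodes[[o]]$out_shape)
    for (s in eq) {
      if (!identical(as.integer(s), as.integer(eq[[1]]))) {
        abort(sprintf("auxiliary heads did not equalize shapes at this input resolution: %s",
                      paste(vapply(eq, function(z) paste(z, collapse = "x"), ""), collapse = " vs ")))
      }
    }
    g <- lg_add(g, "fusion", if (fusion == "concat") "concat" else "add", outs)
    x <- "fusion"
    if (use_mresblock) {
      res <- append_mresblock(g, x, width = residual_width, activation = activation,
                              init = init)
      g <- res$g
      x <- res$x
    }
    g <- lg_add(g, "head_gap", "gap", x)
    if (dropout_kind != "none") {
      kind <- if (dropout_kind == "alpha") "alpha_dropout" else "dropout"
      g <- lg_add(g, "head_drop", kind, "head_gap", hyper = list(rate = 0.2))
      x <- "head_drop"
    } else x <- "head_gap"
    g <- add_dense(g, "head_dense", x, num_classes, init = "small")
    lg_add(g, "head_softmax", "softmax", "head_dense")
  })

  structure(list(
    backbones = backbones, head = head,
    num_classes = as.integer(num_classes), input_shape = as.integer(input_shape),
    options = list(use_mresblock = use_mresblock, activation = activation,
                   dropout_kind = dropout_kind, residual_width = residual_width,
                   fusion = fusion, seed = seed)
  ), class = "fused_model")
}

# Branch features for a batch of images: named list of 4D arrays, in the
# order the head graph's input nodes expect.
backbone_features <- function(model, x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  feats <- lapply(model$backbones, function(b) forward_pass(b, list(input = x))$out)
  stats::setNames(feats, paste0(names(model$backbones), "_branch"))
}

# Full forward pass: images [H,W,C,N] in [0,1] -> class probabilities N x m.
model_forward <- function(model, x, training = FALSE) {
  feats <- backbone_features(model, x)
  forward_pass(model$head, feats, training = training)$out
}

#' Predict class probabilities
#'
#' @param object A `fused_model`.
#' @param newdata A `[H, W, 3, N]` array (or single image, or list of
#'   images) with values in `[0, 1]`.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return An `N x num_classes` matrix of softmax probabilities.
#' @export
predict.fused_model <- function(object, newdata, batch_size = 8, ...) {
  imgs <- as_image_list(newdata)
  n <- length(imgs)
  out <- matrix(0, n, object$num_classes)
  for (ix in make_batches(n, batch_size)) {
    xb <- stack_images(imgs[ix])
    out[ix, ] <- model_forward(object, xb)
  }
  out
}

as_image_list <- function(x) {
  if (is.list(x)) return(x)
  if (length(dim(x)) == 3) return(list(x))
  if (length(dim(x)) == 4) return(lapply(seq_len(dim(x)[4]), function(i) x[, , , i]))
  abort("expected an image array or list of images")
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' @export
print.fused_model <- function(x, ...) {
  cat(sprintf("<fused_model> %d classes, input %s\n", x$num_classes,
              paste(x$input_shape, collapse = "x")))
  cat(sprintf("  backbones (frozen): %s\n", paste(names(x$backbones), collapse = ", ")))
  cat(sprintf("  options: mresblock=%s, activation=%s, dropout=%s, fusion=%s\n",
              x$options$use_mresblock, x$options$activation, x$options$dropout_kind,
              x$options$fusion))
  cat(sprintf("  params: %s total, %s trainable\n",
              format(count_parameters(x), big.mark = ","),
              format(count_parameters(x, trainable_only = TRUE), big.mark = ",")))
  invisible(x)
}

#' One-row cost summary of a fused model
#'
#' @param x A `fused_model`.
#' @param ... Unused.
#' @return A tibble with parameter totals and the FLOPs estimate
#'   (2 x MACs convention; conv and dense kernels only).
#' @export
glance.fused_model <- function(x, ...) {
  tibble::tibble(
    num_classes = x$num_classes,
    total_params = count_parameters(x),
    trainable_params = count_parameters(x, trainable_only = TRUE),
    frozen_params = count_parameters(x) - count_parameters(x, trainable_only = TRUE) -
      sum(vapply(c(x$backbones, list(x$head)), function(g)
        sum(vapply(g$nodes, function(n) sum(vapply(n$buffers, length, numeric(1))),
                   numeric(1))), numeric(1))),
    flops = count_flops(x)
  )
}

#' Per-layer summary of a fused model
#'
#' @param x A `fused_model`.
#' @param ... Unused.
#' @return A tibble over all four constituent graphs with a `component`
#'   column.
#' @export
tidy.fused_model <- function(x, ...) {
  parts <- c(x$backbones, list(head = x$head))
  dplyr::bind_rows(lapply(stats::setNames(names(parts), names(parts)), function(nm) {
    dplyr::mutate(tidy(parts[[nm]]), component = nm, .before = 1)
  }))
}

#' Model summary report
#'
#' Per-layer name, kind, output shape and parameter count for every
#' component, plus totals and the FLOPs estimate; optionally serialized to
#' JSON.
#'
#' @param model A `fused_model`.
#' @param json_path Optional path; if given, the report is written as JSON.
#' @return (Invisibly) a list with `layers` (tibble) and `totals` (tibble).
#' @export
model_summary <- function(model, json_path = NULL) {
  layers <- tidy(model)
  totals <- glance(model)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      layers = layers, totals = totals,
      selu_constants = unclass(selu_params()),
      flops_convention = "2*MACs, conv and dense kernels only; biases, batch-norm and activations excluded"
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cat(sprintf("fused model: %s total params (%s trainable), ~%.2f GFLOPs/image\n",
              format(totals$total_params, big.mark = ","),
              format(totals$trainable_params, big.mark = ","), totals$flops / 1e9))
  invisible(list(layers = layers, totals = totals))
}
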