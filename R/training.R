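#' Training configuration
#'
#' Defaults are the published hyper-parameters: batch size 8, 25 epochs,
#' Adam at learning rate 1e-5, pixel rescaling by 1/255, and the plateau
#' schedule (halve on 2 non-improving epochs, floor 1e-6).  Adam's
#' beta1/beta2/epsilon stay at their canonical defaults.
#'
#' @param batch_size Images per gradient step.
#' @param epochs Training epochs.
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Initial learning rate.
#' @param rescale Pixel rescale factor applied by [preprocess()].
#' @param augment Apply random label-preserving augmentation to the
#'   training split (never to validation/test).
#' @param seed Seed for shuffling, dropout and augmentation.
#' @param lr_factor,lr_patience,lr_floor Plateau-schedule settings.
#' @param monitor Metric watched by the schedule and checkpointing:
#'   `"val_accuracy"` (default, standard practice) or `"accuracy"`;
#'   falls back to training accuracy when no validation split is given.
#' @param clip Probability clip applied before logarithms in the loss.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param restore_best Restore the best-monitored weights after training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8, epochs = 25, optimizer = "adam",
                         learning_rate = 1e-5, rescale = 1 / 255, augment = TRUE,
                         seed = 42, lr_factor = 0.5, lr_patience = 2, lr_floor = 1e-6,
                         monitor = c("val_accuracy", "accuracy"), clip = 1e-7,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7, restore_best = TRUE) {
  if (optimizer != "adam") abort("train_config: only the adam optimizer is implemented")
  structure(list(
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    optimizer = optimizer, learning_rate = learning_rate, rescale = rescale,
    augment = isTRUE(augment), seed = as.integer(seed), lr_factor = lr_factor,
    lr_patience = as.integer(lr_patience), lr_floor = lr_floor,
    monitor = match.arg(monitor), clip = clip, beta1 = beta1, beta2 = beta2,
    eps = eps, restore_best = isTRUE(restore_best)
  ), class = "train_config")
}

# ---- plateau learning-rate schedule -----------------------------------------

#' Reduce-on-plateau learning-rate schedule
#'
#' State for the halving rule `LR_new = LR * factor`: if the monitored
#' metric has not strictly improved for `patience` consecutive epochs, the
#' learning rate is halved (never below `floor`) and the counter resets.
#'
#' @param initial_lr Starting learning rate.
#' @param factor Multiplier on plateau (0.5).
#' @param patience Non-improving epochs tolerated before reduction (2).
#' @param floor Lower limit for the learning rate (1e-6).
#' @return An object of class `lr_schedule`.
#' @export
plateau_schedule <- function(initial_lr = 1e-5, factor = 0.5, patience = 2,
                             floor = 1e-6) {
  stopifnot(initial_lr > 0, factor > 0, factor < 1, patience >= 1, floor > 0)
  structure(list(
    current_lr = max(initial_lr, floor), factor = factor,
    patience = as.integer(patience), floor = floor,
    best_metric = -Inf, epochs_since_improvement = 0L
  ), class = "lr_schedule")
}

#' Advance the plateau schedule by one epoch
#'
#' Strict improvement (`metric > best`) updates the best value and resets
#' the counter, leaving the learning rate unchanged.  Otherwise the counter
#' increments; when it reaches `patience` the learning rate becomes
#' `max(lr * factor, floor)` and the counter resets.
#'
#' @param state An `lr_schedule`.
#' @param epoch_metric The epoch's monitored metric (finite).
#' @return The updated `lr_schedule`.
#' @export
schedule_step <- function(state, epoch_metric) {
  stopifnot(inherits(state, "lr_schedule"), is.finite(epoch_metric))
  if (epoch_metric > state$best_metric) {
    state$best_metric <- epoch_metric
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    if (state$epochs_since_improvement >= state$patience) {
      state$current_lr <- max(state$current_lr * state$factor, state$floor)
      state$epochs_since_improvement <- 0L
    }
  }
  state
}

# ---- loss -------------------------------------------------------------------

#' One-hot encode integer labels
#'
#' @param labels Integer labels in `[0, m)`.
#' @param m Number of classes.
#' @return An `N x m` indicator matrix.
#' @export
one_hot <- function(labels, m) {
  if (any(labels < 0 | labels >= m)) abort("one_hot: label out of range")
  y <- matrix(0, length(labels), m)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Categorical cross-entropy loss
#'
#' Mean over observations of `-sum_c Y_{o,c} log P_{o,c}`.  Probabilities
#' are clipped to `[clip, 1]` before the logarithm for numerical safety.
#'
#' @param y_true One-hot `N x m` matrix (one 1 per row).
#' @param y_pred `N x m` probability matrix (rows sum to 1 within 1e-6).
#' @param clip Lower probability clip.
#' @return Non-negative scalar loss.
#' @export
cce_loss <- function(y_true, y_pred, clip = 1e-7) {
  if (!is.matrix(y_true)) y_true <- matrix(y_true, nrow = 1)
  if (!is.matrix(y_pred)) y_pred <- matrix(y_pred, nrow = 1)
  if (!identical(dim(y_true), dim(y_pred))) {
    abort(sprintf("cce_loss: shape mismatch (%s vs %s)",
                  paste(dim(y_true), collapse = "x"), paste(dim(y_pred), collapse = "x")))
  }
  if (!all(y_true %in% c(0, 1)) || any(rowSums(y_true) != 1)) {
    abort("cce_loss: y_true rows must one-hot encode a class")
  }
  if (any(y_pred < -1e-9 | y_pred > 1 + 1e-9)) abort("cce_loss: probabilities outside [0, 1]")
  if (any(abs(rowSums(y_pred) - 1) > 1e-6)) abort("cce_loss: probability rows must sum to 1")
  mean(-rowSums(y_true * log(pmin(pmax(y_pred, clip), 1))))
}

# ---- preprocessing and augmentation -----------------------------------------

#' Preprocess a raw image
#'
#' Rescales 8-bit pixel values by `rescale` (default 1/255, giving values
#' in `[0, 1]`) and, if needed, resizes bilinearly to `image_size`.
#'
#' @param image `H x W x 3` numeric array with values in `[0, 255]`.
#' @param image_size Target `c(H, W)` (`NULL` keeps the input size).
#' @param rescale Pixel scale factor.
#' @return `H x W x 3` array of rescaled values.
#' @export
preprocess <- function(image, image_size = NULL, rescale = 1 / 255) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    abort(sprintf("preprocess: expected an H x W x 3 image, got %s", paste(d, collapse = "x")))
  }
  if (min(image) < 0 || max(image) > 255) abort("preprocess: pixel values outside [0, 255]")
  out <- image * rescale
  if (!is.null(image_size) && !all(d[1:2] == image_size)) {
    out <- resize_bilinear(out, image_size[1], image_size[2])
  }
  out
}

resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  # align-corners-free sampling of source coordinates
  ys <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1]); wy <- pmin(pmax(ys - y0, 0), 1)
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2]); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    a <- ch[y0, x0] * (1 - wy) + ch[y1, x0] * wy
    b <- ch[y0, x1] * (1 - wy) + ch[y1, x1] * wy
    out[, , c] <- a * (1 - matrix(wx, out_h, out_w, byrow = TRUE)) +
      b * matrix(wx, out_h, out_w, byrow = TRUE)
  }
  out
}

#' Deterministic label-preserving image transform
#'
#' Applies, in order: horizontal flip, vertical flip, rotation about the
#' image centre, and translation, using nearest-neighbour resampling with
#' edge clamping.  With all arguments at their defaults this is the
#' identity, pixel for pixel.
#'
#' @param image `H x W x 3` array.
#' @param hflip,vflip Mirror horizontally (columns) / vertically (rows).
#' @param angle Rotation in degrees.
#' @param shift Length-2 fraction of height/width to translate.
#' @return Transformed image, same shape.
#' @export
augment_image <- function(image, hflip = FALSE, vflip = FALSE, angle = 0,
                          shift = c(0, 0)) {
  d <- dim(image)
  out <- image
  if (hflip) out <- out[, d[2]:1, , drop = FALSE]
  if (vflip) out <- out[d[1]:1, , , drop = FALSE]
  if (angle != 0 || any(shift != 0)) {
    th <- angle * pi / 180
    cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
    yy <- matrix(seq_len(d[1]), d[1], d[2]) - cy
    xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
    # inverse map: rotate by -th then undo the shift
    sy <- shift[1] * d[1]; sx <- shift[2] * d[2]
    src_y <- cos(th) * (yy - sy) + sin(th) * (xx - sx) + cy
    src_x <- -sin(th) * (yy - sy) + cos(th) * (xx - sx) + cx
    iy <- pmin(pmax(round(src_y), 1), d[1])
    ix <- pmin(pmax(round(src_x), 1), d[2])
    idx <- cbind(as.vector(iy), as.vector(ix))
    res <- out
    for (c in seq_len(d[3])) {
      ch <- out[, , c]
      res[, , c] <- matrix(ch[idx], d[1], d[2])
    }
    out <- res
  }
  out
}

# Randomized augmentation: flips with probability 1/2 each, rotation
# within +/-15 degrees, shifts within +/-10%.  Draws from the current RNG
# stream, so a fixed seed reproduces the transform sequence exactly.
random_augment <- function(image, max_angle = 15, max_shift = 0.1) {
  augment_image(image,
                hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
                angle = runif(1, -max_angle, max_angle),
                shift = runif(2, -max_shift, max_shift))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

# grads: named list node -> named list param -> gradient array.
# The compiled step updates the moment buffers in place (they are owned
# exclusively by `opt`) and returns a fresh weight tensor, which keeps
# checkpointed weight copies intact while avoiding the allocation churn a
# vectorized R update would generate on multi-million-parameter tensors.
adam_update <- function(head, opt, grads, lr, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      key <- paste0(nm, "/", p)
      g <- grads[[nm]][[p]]
      if (is.null(opt$m[[key]])) {
        opt$m[[key]] <- numeric(length(g))
        opt$v[[key]] <- numeric(length(g))
      }
      head$nodes[[nm]]$params[[p]] <- cpp_adam_step(
        head$nodes[[nm]]$params[[p]], g, opt$m[[key]], opt$v[[key]],
        lr, cfg$beta1, cfg$beta2, bc1, bc2, cfg$eps)
    }
  }
  list(head = head, opt = opt)
}

# ---- batching helpers -------------------------------------------------------

#' Split `n` items into consecutive batches
#'
#' @param n Number of items.
#' @param batch_size Batch size.
#' @return List of index vectors; `ceiling(n / batch_size)` batches.
#' @export
make_batches <- function(n, batch_size) {
  if (n < 1) abort("make_batches: empty input")
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

stack_features <- function(feat_list) {
  # feat_list: list over images of named lists of [H,W,C] arrays, or of
  # float32-packed raw vectors carrying a "dims" attribute
  nms <- names(feat_list[[1]])
  out <- lapply(nms, function(nm) {
    f1 <- feat_list[[1]][[nm]]
    if (is.raw(f1)) {
      cpp_stack_f32(lapply(feat_list, `[[`, nm), attr(f1, "dims"))
    } else {
      d <- dim(f1)[1:3]
      a <- array(0, c(d, length(feat_list)))
      for (i in seq_along(feat_list)) a[, , , i] <- feat_list[[i]][[nm]]
      a
    }
  })
  stats::setNames(out, nms)
}

# ---- training loop ----------------------------------------------------------

#' Train the fused model
#'
#' Runs mini-batch Adam on the categorical cross-entropy, with the plateau
#' learning-rate schedule stepped once per epoch and best-epoch weight
#' checkpointing.  Augmentation, when enabled, is applied to the training
#' split only.  When every backbone is frozen and augmentation is off, the
#' branch features of each image are precomputed once and reused across
#' epochs (mathematically identical, far cheaper).
#'
#' @param model A `fused_model` from [assemble_model()].
#' @param data A list with `$train` and optionally `$validation`, each an
#'   image split as returned by [load_split()] (images in `[0, 1]` at the
#'   model's input size).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @param features Optional precomputed branch features (as produced by
#'   [precompute_features()]) for `train`/`validation`; useful when several
#'   models share identical frozen backbones.
#' @return An object of class `endofuse_fit`: the trained model, the
#'   per-epoch `history` tibble (epoch, loss, accuracy, val_loss,
#'   val_accuracy, lr), the config, and the best epoch.
#' @export
train <- function(model, data, config = train_config(), verbose = FALSE,
                  features = NULL) {
  stopifnot(inherits(model, "fused_model"))
  tr <- data$train
  if (is.null(tr) || length(tr$images) == 0) abort("train: empty training split")
  va <- data$validation
  if (!is.null(va) && length(va$images) == 0) abort("train: empty validation split")
  m <- model$num_classes
  set.seed(config$seed)

  frozen_cache <- !config$augment &&
    all(vapply(model$backbones, function(b)
      count_parameters(b, trainable_only = TRUE) == 0, logical(1)))

  tr_feats <- features$train %||% (if (frozen_cache) precompute_features(model, tr$images))
  va_feats <- if (!is.null(va)) {
    features$validation %||% precompute_features(model, va$images)
  }

  head <- model$head
  opt <- adam_init()
  sched <- plateau_schedule(config$learning_rate, config$lr_factor,
                            config$lr_patience, config$lr_floor)
  monitor <- if (is.null(va) && config$monitor == "val_accuracy") "accuracy" else config$monitor
  best <- -Inf; best_params <- NULL; best_epoch <- NA_integer_
  hist <- vector("list", config$epochs)
  n <- length(tr$images)

  head_infer <- function(head, feats_list, labels, batch_size) {
    loss <- 0; correct <- 0
    for (ix in make_batches(length(feats_list), batch_size)) {
      fb <- stack_features(feats_list[ix])
      p <- forward_pass(head, fb, training = FALSE)$out
      y <- one_hot(labels[ix], m)
      loss <- loss + cce_loss(y, p, config$clip) * length(ix)
      correct <- correct + sum(max.col(p) == labels[ix] + 1L)
    }
    c(loss / length(feats_list), correct / length(feats_list))
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- sched$current_lr
    idx <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (ix in make_batches(n, config$batch_size)) {
      b <- idx[ix]
      fb <- if (frozen_cache) {
        stack_features(tr_feats[b])
      } else {
        imgs <- lapply(tr$images[b], function(im)
          if (config$augment) random_augment(im) else im)
        backbone_features(model, stack_images(imgs))
      }
      y <- one_hot(tr$labels[b], m)
      fwd <- forward_pass(head, fb, training = TRUE, keep_all = TRUE)
      p <- fwd$out
      ep_loss <- ep_loss + cce_loss(y, p, config$clip) * length(b)
      ep_correct <- ep_correct + sum(max.col(p) == tr$labels[b] + 1L)
      dz <- (p - y) / length(b)
      grads <- backward_pass(head, fwd$values, fwd$cache, "head_dense", dz)
      upd <- adam_update(head, opt, grads, lr, config)
      head <- upd$head; opt <- upd$opt
      # training-mode batch norms update running stats
      head <- bn_update_stats(head, fwd$cache)
    }
    tr_loss <- ep_loss / n; tr_acc <- ep_correct / n
    # buffers must describe the inference distribution before they are
    # used for validation metrics; without a validation split the
    # re-estimation can wait until training ends
    if (frozen_cache && !is.null(va)) {
      head <- recalibrate_bn(head, tr_feats, config$batch_size)
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(va)) {
      vm <- head_infer(head, va_feats, va$labels, config$batch_size)
      val_loss <- vm[1]; val_acc <- vm[2]
    }
    metric <- if (monitor == "val_accuracy") val_acc else tr_acc
    if (is.finite(metric) && metric > best) {
      best <- metric; best_epoch <- epoch
      best_params <- lapply(head$nodes, function(nd)
        if (nd$trainable) list(params = nd$params, buffers = nd$buffers))
    }
    sched <- schedule_step(sched, metric)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = tr_loss, accuracy = tr_acc,
                                    val_loss = val_loss, val_accuracy = val_acc, lr = lr)
    if (verbose) {
      cat(sprintf("epoch %2d  loss %.4f acc %.4f  val_loss %s val_acc %s  lr %g\n",
                  epoch, tr_loss, tr_acc,
                  ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                  ifelse(is.na(val_acc), "-", sprintf("%.4f", val_acc)), lr))
    }
  }
  if (config$restore_best && !is.null(best_params)) {
    for (nm in names(best_params)) {
      if (!is.null(best_params[[nm]])) {
        head$nodes[[nm]]$params <- best_params[[nm]]$params
        head$nodes[[nm]]$buffers <- best_params[[nm]]$buffers
      }
    }
  }
  if (frozen_cache) {
    if (is.null(va)) head <- recalibrate_bn(head, tr_feats, config$batch_size)
  } else {
    # augmented path: calibrate the final weights on clean images
    sub <- tr$images[seq_len(min(64, n))]
    model$head <- head
    head <- recalibrate_bn(head, precompute_features(model, sub), config$batch_size)
  }
  model$head <- head
  history <- dplyr::bind_rows(hist)
  class(history) <- c("endofuse_history", class(history))
  structure(list(model = model, history = history, config = config,
                 best_epoch = best_epoch, monitor = monitor),
            class = "endofuse_fit")
}

#' Precompute frozen-backbone branch features
#'
#' Runs the three frozen backbones once per image and returns the per-image
#' branch feature maps keyed by the head graph's input names.  Reusable
#' across training runs whose models share backbone weights.
#'
#' @param model A `fused_model`.
#' @param images List of `H x W x 3` arrays in `[0, 1]`.
#' @param compact Store each map as float32-packed bytes (halves the
#'   cache's resident size; the convolution kernels are float32 anyway).
#' @param chunk Images per backbone forward pass.
#' @return A list (one element per image) of named feature lists.
#' @export
precompute_features <- function(model, images, compact = TRUE, chunk = 8) {
  out <- vector("list", length(images))
  for (ix in make_batches(length(images), chunk)) {
    fb <- backbone_features(model, stack_images(images[ix]))
    for (j in seq_along(ix)) {
      out[[ix[j]]] <- lapply(fb, function(a) {
        d <- dim(a)[1:3]
        s <- a[, , , j]
        if (compact) {
          r <- cpp_pack_f32(s)
          attr(r, "dims") <- d
          r
        } else {
          dim(s) <- d
          s
        }
      })
    }
  }
  out
}

# Re-estimate the head's batch-norm running statistics under the
# *inference-time* distribution: forward passes with batch-statistics
# normalization but dropout disabled.  Needed because the architecture
# places (alpha) dropout upstream of the fusion batch-norms, so statistics
# gathered from dropout-active training steps describe a differently
# scaled distribution than inference sees.  Classic batch-norm
# re-estimation; a bounded subsample keeps it cheap.
recalibrate_bn <- function(head, feats_list, batch_size, max_images = 64) {
  bn_nodes <- names(Filter(function(n)
    n$kind == "bn" && n$trainable && !isTRUE(n$hyper$frozen), head$nodes))
  if (length(bn_nodes) == 0) return(head)
  idx <- seq_len(min(max_images, length(feats_list)))
  mu_acc <- m2_acc <- stats::setNames(vector("list", length(bn_nodes)), bn_nodes)
  k <- 0
  for (ix in make_batches(length(idx), batch_size)) {
    fwd <- forward_pass(head, stack_features(feats_list[idx[ix]]),
                        training = TRUE, keep_all = TRUE, drop_active = FALSE)
    for (nm in bn_nodes) {
      ext <- get(nm, fwd$cache)
      mu_acc[[nm]] <- (mu_acc[[nm]] %||% 0) + ext$mu
      m2_acc[[nm]] <- (m2_acc[[nm]] %||% 0) + ext$var + ext$mu^2
    }
    k <- k + 1
  }
  for (nm in bn_nodes) {
    mu <- mu_acc[[nm]] / k
    head$nodes[[nm]]$buffers$mean <- mu
    head$nodes[[nm]]$buffers$var <- pmax(m2_acc[[nm]] / k - mu^2, 0)
  }
  head
}

# Copy fresh running statistics out of the caches after a training step.
bn_update_stats <- function(head, cache) {
  for (nm in names(head$nodes)) {
    nd <- head$nodes[[nm]]
    if (nd$kind != "bn" || !nd$trainable || isTRUE(nd$hyper$frozen)) next
    ext <- mget(nm, cache, ifnotfound = list(NULL))[[1]]
    if (is.null(ext) || is.null(ext$mu)) next
    mom <- nd$hyper$momentum
    head$nodes[[nm]]$buffers$mean <- mom * nd$buffers$mean + (1 - mom) * ext$mu
    head$nodes[[nm]]$buffers$var <- mom * nd$buffers$var + (1 - mom) * ext$var
  }
  head
}

#' @export
predict.endofuse_fit <- function(object, newdata, batch_size = NULL, ...) {
  predict(object$model, newdata, batch_size = batch_size %||% object$config$batch_size)
}

#' @export
print.endofuse_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<endofuse_fit> %d epochs; final loss %.4f, accuracy %.4f", nrow(h),
              h$loss[nrow(h)], h$accuracy[nrow(h)]))
  if (!all(is.na(h$val_accuracy))) {
    cat(sprintf("; best %s %.4f (epoch %d)", x$monitor,
                max(if (x$monitor == "val_accuracy") h$val_accuracy else h$accuracy,
                    na.rm = TRUE), x$best_epoch))
  }
  cat("\n")
  invisible(x)
}

#' One-row summary of a training run
#'
#' @param x An `endofuse_fit`.
#' @param ... Unused.
#' @return A tibble with final/best metrics and the final learning rate.
#' @export
glance.endofuse_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h), final_loss = h$loss[nrow(h)], final_accuracy = h$accuracy[nrow(h)],
    best_epoch = x$best_epoch,
    best_val_accuracy = if (all(is.na(h$val_accuracy))) NA_real_ else max(h$val_accuracy, na.rm = TRUE),
    final_lr = h$lr[nrow(h)]
  )
}

#' Plot a training history
#'
#' Loss, accuracy and learning-rate traces by epoch, one facet per
#' quantity.
#'
#' @param object An `endofuse_history` tibble (the `$history` of a fit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.endofuse_history <- function(object, ...) {
  df <- tidyr::pivot_longer(as.data.frame(object), -"epoch",
                            names_to = "quantity", values_to = "value")
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ ifelse(.data$quantity == "lr", "learning rate",
                                 ifelse(grepl("loss", .data$quantity), "loss", "accuracy")),
                        scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
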