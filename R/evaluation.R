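#' Confusion counts from predicted and true labels
#'
#' Builds the `m x m` confusion matrix (rows = true class, columns =
#' predicted class) and the per-class one-vs-rest TP/TN/FP/FN tallies that
#' the performance metrics are computed from.
#'
#' @param y_true,y_pred Integer labels in `[0, m)`, equal length, non-empty.
#' @param m Number of classes.
#' @param class_names Optional class names (length `m`).
#' @return An object of class `confusion_counts`: list with `table`
#'   (`m x m` matrix), `per_class` (tibble of TP/TN/FP/FN), `N`, `m`.
#' @export
confusion_matrix <- function(y_true, y_pred, m, class_names = NULL) {
  if (length(y_true) == 0) abort("confusion_matrix: empty input")
  if (length(y_true) != length(y_pred)) abort("confusion_matrix: length mismatch")
  if (any(y_true < 0 | y_true >= m) || any(y_pred < 0 | y_pred >= m)) {
    abort(sprintf("confusion_matrix: labels must lie in [0, %d)", m))
  }
  class_names <- class_names %||% as.character(seq_len(m) - 1L)
  tab <- matrix(0L, m, m, dimnames = list(true = class_names, pred = class_names))
  for (i in seq_along(y_true)) {
    tab[y_true[i] + 1L, y_pred[i] + 1L] <- tab[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  N <- length(y_true)
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  tn <- N - tp - fp - fn
  structure(list(
    table = tab,
    per_class = tibble::tibble(class = class_names, tp = as.integer(tp),
                               tn = as.integer(tn), fp = as.integer(fp),
                               fn = as.integer(fn), support = as.integer(rowSums(tab))),
    N = N, m = as.integer(m)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Per-class counts and metrics in long form
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return Tibble with per-class TP/TN/FP/FN, one-vs-rest accuracy,
#'   precision, recall and F1.
#' @export
tidy.confusion_counts <- function(x, ...) {
  pc <- x$per_class
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  dplyr::mutate(pc,
    accuracy_ovr = (pc$tp + pc$tn) / x$N,
    precision = safe_div(pc$tp, pc$tp + pc$fp),
    recall = safe_div(pc$tp, pc$tp + pc$fn),
    f1 = ifelse(.data$precision + .data$recall > 0,
                2 * .data$precision * .data$recall / (.data$precision + .data$recall), 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Multi-class accuracy is the fraction of correct predictions
#' (`sum(TP) / N`).  Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`
#' and their harmonic mean F1 are averaged either weighted by class
#' support (default — on balanced data weighted recall equals accuracy) or
#' unweighted (macro).  A class with a zero denominator scores 0 and
#' raises a warning.
#'
#' @param counts A [confusion_matrix()] result.
#' @param averaging `"weighted"` or `"macro"`.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `averaging`; per-class detail in attribute `"per_class"`.
#' @export
classification_metrics <- function(counts, averaging = c("weighted", "macro")) {
  stopifnot(inherits(counts, "confusion_counts"))
  averaging <- match.arg(averaging)
  if (counts$N == 0) abort("classification_metrics: no observations")
  pc <- tidy(counts)
  if (any(pc$tp + pc$fp == 0) || any(pc$tp + pc$fn == 0)) {
    warn("classification_metrics: some classes have zero-denominator precision or recall; scored 0")
  }
  w <- if (averaging == "weighted") pc$support / counts$N else rep(1 / counts$m, counts$m)
  out <- tibble::tibble(
    accuracy = sum(pc$tp) / counts$N,
    precision = sum(w * pc$precision),
    recall = sum(w * pc$recall),
    f1 = sum(w * pc$f1),
    averaging = averaging
  )
  attr(out, "per_class") <- pc
  out
}

#' Confusion-matrix heatmap
#'
#' @param object A `confusion_counts`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_counts <- function(object, ...) {
  df <- as.data.frame(as.table(object$table))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted model on an image split
#'
#' @param object A `fused_model` or `endofuse_fit`.
#' @param split An `image_split`.
#' @param averaging Metric averaging mode.
#' @param batch_size Images per forward pass.
#' @param features Optional precomputed branch features for the split.
#' @return A list with `metrics` (one-row tibble), `counts`
#'   (`confusion_counts`) and `probs`.
#' @export
evaluate_split <- function(object, split, averaging = "weighted", batch_size = 8,
                           features = NULL) {
  model <- if (inherits(object, "endofuse_fit")) object$model else object
  probs <- if (is.null(features)) {
    predict(model, split$images, batch_size = batch_size)
  } else {
    out <- matrix(0, length(features), model$num_classes)
    for (ix in make_batches(length(features), batch_size)) {
      out[ix, ] <- forward_pass(model$head, stack_features(features[ix]))$out
    }
    out
  }
  pred <- max.col(probs) - 1L
  counts <- confusion_matrix(split$labels, pred, model$num_classes,
                             class_names = split$class_names)
  list(metrics = classification_metrics(counts, averaging), counts = counts,
       probs = probs)
}

# ---- ablation ---------------------------------------------------------------

#' The six ablation variants
#'
#' The published ablation crosses the presence of the modified residual
#' block (with its SeLU self-normalization) with the dropout kind in the
#' trainable layers: alpha dropout, standard dropout, or none.  Variants
#' without the residual block also revert SeLU/LeCun-normal to
#' ReLU/He-normal.
#'
#' @return A tibble with `variant`, `use_mresblock`, `use_selu`,
#'   `dropout_kind`.
#' @export
ablation_variants <- function() {
  tibble::tibble(
    variant = c("mres_selu_alpha", "mres_selu_standard", "mres_selu_none",
                "plain_alpha", "plain_standard", "plain_none"),
    use_mresblock = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    use_selu = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dropout_kind = c("alpha", "standard", "none", "alpha", "standard", "none")
  )
}

#' Run the ablation grid
#'
#' Trains and evaluates one model per variant on the given data with a
#' shared seed; the three frozen backbones (and, when augmentation is off,
#' their cached branch features) are shared across variants, so rows
#' differ only in the trainable layers under test.
#'
#' @param data List with `$train`, optional `$validation`, and `$test`
#'   image splits.
#' @param config A [train_config()].
#' @param variants Tibble as from [ablation_variants()].
#' @param input_shape Model input shape.
#' @param seed Seed shared across variants (backbone init and training).
#' @param csv_path Optional path for the results CSV.
#' @param verbose Print per-variant progress.
#' @param features Optional precomputed branch features (named list with
#'   `train`, optionally `validation` and `test`) matching the data and
#'   the backbones a model built with this `seed` would carry.
#' @return A tibble: variant flags plus accuracy/precision/recall/F1 on
#'   the test split (and on validation when present), one row per variant.
#' @export
run_ablation <- function(data, config = train_config(), variants = ablation_variants(),
                         input_shape = c(224, 224, 3), seed = 42, csv_path = NULL,
                         verbose = FALSE, features = NULL) {
  stopifnot(all(c("use_mresblock", "use_selu", "dropout_kind") %in% names(variants)))
  if (is.null(data$train) || is.null(data$test)) abort("run_ablation: need train and test splits")
  rows <- vector("list", nrow(variants))
  shared_feats <- features
  shared_backbones <- NULL
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    model <- assemble_model(
      num_classes = length(data$train$class_names), input_shape = input_shape,
      seed = seed, use_mresblock = v$use_mresblock,
      activation = if (v$use_selu) "selu" else "relu",
      dropout_kind = v$dropout_kind,
      backbones = shared_backbones
    )
    # the frozen backbones are identical across variants (same seed):
    # build them once and compute each image's branch features once
    shared_backbones <- model$backbones
    if (is.null(shared_feats) && !config$augment) {
      shared_feats <- list(
        train = precompute_features(model, data$train$images),
        validation = if (!is.null(data$validation))
          precompute_features(model, data$validation$images),
        test = precompute_features(model, data$test$images)
      )
    }
    fit <- train(model, data, config, features = shared_feats)
    ev_test <- evaluate_split(fit, data$test, batch_size = config$batch_size,
                              features = shared_feats$test)
    row <- dplyr::bind_cols(v, dplyr::rename_with(
      dplyr::select(ev_test$metrics, -"averaging"), ~ paste0("test_", .x)))
    if (!is.null(data$validation)) {
      ev_val <- evaluate_split(fit, data$validation, batch_size = config$batch_size,
                               features = shared_feats$validation)
      row <- dplyr::bind_cols(row, dplyr::rename_with(
        dplyr::select(ev_val$metrics, -"averaging"), ~ paste0("val_", .x)))
    }
    rows[[i]] <- row
    if (verbose) {
      cat(sprintf("variant %-18s test accuracy %.3f\n", v$variant, ev_test$metrics$accuracy))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(csv_path)) write.csv(out, csv_path, row.names = FALSE)
  out
}
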