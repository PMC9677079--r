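#' Dataset layout of the curated endoscopy corpus
#'
#' Four classes (normal mucosa, ulcer, polyps, esophagitis) with 800
#' training, 500 validation and 200 test images per class: split totals
#' 3,200 / 2,000 / 800, grand total 6,000.  Images live under
#' `root/split/class/`.  Class-to-label mapping is alphabetical and is
#' recorded in the generated manifest.
#'
#' @param classes Ordered class names.
#' @param train,validation,test Per-class image counts.
#' @param image_size Image `c(H, W)`; 224 matches the model input.
#' @return An object of class `dataset_layout`.
#' @export
dataset_layout <- function(classes = c("normal", "ulcer", "polyps", "esophagitis"),
                           train = 800, validation = 500, test = 200,
                           image_size = c(224, 224)) {
  structure(list(
    classes = classes,
    counts = c(train = as.integer(train), validation = as.integer(validation),
               test = as.integer(test)),
    image_size = as.integer(image_size)
  ), class = "dataset_layout")
}

#' Planned per-split, per-class counts
#'
#' Applies the scale factor used for fast desk-scale runs: counts are
#' floored, with a minimum of 2 images per class per split.
#'
#' @param layout A [dataset_layout()].
#' @param scale Proportional rescaling of all counts, in `(0, 1]`.
#' @return A tibble with `split`, `class`, `label`, `n`.
#' @export
dataset_plan <- function(layout = dataset_layout(), scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  lab <- match(layout$classes, sort(layout$classes)) - 1L # alphabetical labels
  tidyr::expand_grid(split = names(layout$counts), class = layout$classes) |>
    dplyr::mutate(
      label = lab[match(.data$class, layout$classes)],
      n = pmax(2L, as.integer(floor(layout$counts[.data$split] * scale)))
    )
}

# Deterministic per-image seed, keyed by (seed, split, class, index) so that
# no image can be shared across splits (leakage-free by construction).
image_seed <- function(seed, split, label, i) {
  s <- (as.double(seed) * 7919 + match(split, c("train", "validation", "test")) * 1299709 +
          as.double(label) * 104729 + as.double(i) * 31)
  as.integer(s %% 2147483647)
}

# One synthetic endoscopy-like image: mucosa-textured background plus a
# class-specific signature with jittered position/size/intensity.
synth_image <- function(class, size) {
  H <- size[1]; W <- size[2]
  coarse <- function(nc, amp) {
    g <- matrix(rnorm(nc * nc), nc, nc)
    resize_bilinear(array(g, c(nc, nc, 1)), H, W)[, , 1] * amp
  }
  t1 <- coarse(8, 0.045); t2 <- coarse(12, 0.03)
  r <- 0.62 + t1 + 0.5 * t2
  g <- 0.33 + 0.8 * t2
  b <- 0.30 + 0.5 * t2 - 0.3 * t1
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (class == "polyps") {
    # bright raised blob
    cy <- runif(1, 0.35, 0.65) * H; cx <- runif(1, 0.35, 0.65) * W
    ry <- runif(1, 0.16, 0.26) * H; rx <- runif(1, 0.16, 0.26) * W
    th <- runif(1, 0, pi)
    u <- (cos(th) * (yy - cy) + sin(th) * (xx - cx)) / ry
    v <- (-sin(th) * (yy - cy) + cos(th) * (xx - cx)) / rx
    bump <- exp(-(u^2 + v^2))
    amp <- runif(1, 0.3, 0.42)
    r <- r + amp * bump; g <- g + amp * 0.85 * bump; b <- b + amp * 0.55 * bump
  } else if (class == "ulcer") {
    # pale crater with a dark rim
    cy <- runif(1, 0.38, 0.62) * H; cx <- runif(1, 0.38, 0.62) * W
    rad <- runif(1, 0.13, 0.21) * min(H, W)
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    core <- pmax(0, 1 - (d / rad)^2)
    rim <- exp(-((d - 1.2 * rad) / (0.25 * rad))^2)
    pale <- runif(1, 0.35, 0.48)
    r <- r + pale * core - 0.35 * rim
    g <- g + 1.3 * pale * core - 0.35 * rim
    b <- b + 1.5 * pale * core - 0.3 * rim
  } else if (class == "esophagitis") {
    # red longitudinal streaks of inflamed mucosa
    k <- sample(5:7, 1)
    streak <- matrix(0, H, W)
    for (i in seq_len(k)) {
      x0 <- runif(1, 0.1, 0.9) * W
      wdt <- runif(1, 0.02, 0.04) * W
      wob <- runif(1, 0, 5) * sin(2 * pi * yy[, 1] / H * runif(1, 0.5, 2))
      dist <- abs(sweep(xx, 1, wob, "-") - x0)
      streak <- streak + exp(-(dist / wdt)^2)
    }
    amp <- runif(1, 0.3, 0.42)
    r <- r + amp * pmin(streak, 1); g <- g - 0.35 * amp * pmin(streak, 1)
    b <- b - 0.15 * amp * pmin(streak, 1)
  }
  out <- array(0, c(H, W, 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out <- out + rnorm(length(out), sd = 0.015)
  pmin(pmax(out, 0), 1)
}

#' Generate the synthetic endoscopy dataset
#'
#' Writes PNG images under `root/split/class/` following the layout, each
#' class carrying a distinct, learnable signature on a mucosa-like
#' textured background: a bright raised blob (polyps), a pale patch with a
#' dark rim (ulcer), bright longitudinal streaks (esophagitis), or plain
#' texture (normal), with random position/size/intensity jitter.  Images
#' are deterministic given `seed`: each image's RNG stream is keyed by
#' (seed, split, class, index), so splits can never share an image.
#' A `manifest.csv` (path, split, class, label, seed) is written at the
#' root.
#'
#' @param root Writable output directory.
#' @param layout A [dataset_layout()].
#' @param seed Master seed.
#' @param scale Count rescaling in `(0, 1]`, see [dataset_plan()].
#' @return (Invisibly) the manifest tibble.
#' @export
generate_dataset <- function(root, layout = dataset_layout(), seed = 1, scale = 1) {
  plan <- dataset_plan(layout, scale)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) abort(paste0("generate_dataset: cannot create ", root))
  if (file.access(root, 2) != 0) abort(paste0("generate_dataset: unwritable path ", root))
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    split <- plan$split[i]; cls <- plan$class[i]; label <- plan$label[i]
    dir.create(file.path(root, split, cls), recursive = TRUE, showWarnings = FALSE)
    files <- character(plan$n[i])
    for (j in seq_len(plan$n[i])) {
      img <- withr::with_seed(image_seed(seed, split, label, j),
                              synth_image(cls, layout$image_size))
      files[j] <- file.path(split, cls, sprintf("%s_%04d.png", cls, j))
      png::writePNG(img, file.path(root, files[j]))
    }
    rows[[i]] <- tibble::tibble(path = files, split = split, class = cls,
                                label = label, seed = seed)
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load one split of an image dataset
#'
#' Reads every PNG under `root/split/class/`, assigns integer labels by
#' alphabetical class order (matching the generated manifest), and
#' optionally resizes.
#'
#' @param root Dataset root (directory-of-folders convention).
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @param image_size Optional `c(H, W)` to resize to.
#' @return An object of class `image_split`: list with `images` (list of
#'   `H x W x 3` arrays in `[0, 1]`), `labels` (0-based integers),
#'   `class_names`, `files`.
#' @export
load_split <- function(root, split, image_size = NULL) {
  sdir <- file.path(root, split)
  if (!dir.exists(sdir)) abort(paste0("load_split: missing split directory: ", sdir))
  classes <- sort(list.dirs(sdir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) abort(paste0("load_split: no class directories under ", sdir))
  images <- list(); labels <- integer(); files <- character()
  for (ci in seq_along(classes)) {
    fs <- sort(list.files(file.path(sdir, classes[ci]), pattern = "\\.png$",
                          full.names = TRUE))
    if (length(fs) == 0) abort(paste0("load_split: class '", classes[ci],
                                      "' has no images in split '", split, "'"))
    for (f in fs) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      if (!is.null(image_size) && !all(dim(img)[1:2] == image_size)) {
        img <- resize_bilinear(img, image_size[1], image_size[2])
      }
      images[[length(images) + 1]] <- img
      labels <- c(labels, ci - 1L)
      files <- c(files, f)
    }
  }
  structure(list(images = images, labels = labels, class_names = classes,
                 files = files),
            class = "image_split")
}

#' @export
print.image_split <- function(x, ...) {
  cat(sprintf("<image_split> %d images, %d classes (%s)\n", length(x$images),
              length(x$class_names), paste(x$class_names, collapse = ", ")))
  invisible(x)
}
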