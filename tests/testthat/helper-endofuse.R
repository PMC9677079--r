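# Shared fixtures. Synthetic data is generated programmatically into the
# session temp dir and cached so several test files can reuse one tree.

.fixture_env <- new.env()

fixture_dataset <- function(scale, seed = 101) {
  key <- sprintf("ds_%g_%d", scale, seed)
  if (is.null(.fixture_env[[key]])) {
    root <- file.path(tempdir(), key)
    if (!dir.exists(root)) {
      generate_dataset(root, dataset_layout(), seed = seed, scale = scale)
    }
    .fixture_env[[key]] <- root
  }
  .fixture_env[[key]]
}

random_image_batch <- function(h, w, c = 3, n = 1, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * c * n), c(h, w, c, n)))
}

# Model, splits and precomputed branch features shared by the heavy
# end-to-end tests (one backbone set; computed once, cleared afterwards).
acceptance_fixture <- function() {
  if (is.null(.fixture_env$accf)) {
    root <- fixture_dataset(0.05) # 40 train / 10 test images per class
    tr <- load_split(root, "train")
    te <- load_split(root, "test")
    m <- assemble_model(num_classes = 4, seed = 77)
    ftr <- precompute_features(m, tr$images)
    fte <- precompute_features(m, te$images)
    # free the pixel data: the tests below consume only cached features
    tr$images <- vector("list", length(tr$labels))
    te$images <- vector("list", length(te$labels))
    gc(verbose = FALSE)
    .fixture_env$accf <- list(model = m, tr = tr, te = te, ftr = ftr, fte = fte)
  }
  .fixture_env$accf
}

clear_acceptance_fixture <- function() {
  .fixture_env$accf <- NULL
  invisible(gc(verbose = FALSE))
}

# Naive direct convolution used as an independent oracle for the compiled
# im2col/GEMM kernel (double precision, explicit loops).
naive_conv2d <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; F <- dim(w)[4]
  Ho <- (H + pad[1] + pad[2] - kh) %/% stride[1] + 1
  Wo <- (W + pad[3] + pad[4] - kw) %/% stride[2] + 1
  y <- array(0, c(Ho, Wo, F, N))
  for (n in 1:N) for (f in 1:F) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- if (length(b)) b[f] else 0
    for (c in 1:C) for (kj in 1:kw) for (ki in 1:kh) {
      hi <- (ho - 1) * stride[1] - pad[1] + ki
      wi <- (wo - 1) * stride[2] - pad[3] + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[hi, wi, c, n] * w[ki, kj, c, f]
      }
    }
    y[ho, wo, f, n] <- acc
  }
  y
}

# Central finite difference of a scalar-valued function of one graph
# parameter, used to verify backpropagated gradients.
numeric_grad <- function(fn, value, eps = 1e-5) {
  g <- array(0, dim(value) %||% length(value))
  for (i in seq_along(value)) {
    vp <- value; vp[i] <- vp[i] + eps
    vm <- value; vm[i] <- vm[i] - eps
    g[i] <- (fn(vp) - fn(vm)) / (2 * eps)
  }
  g
}

`%||%` <- rlang::`%||%`
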