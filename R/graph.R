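#' @title Layer graphs
#' @description
#' A `layer_graph` is the package's universal model representation: an
#' ordered, named, acyclic graph of layer nodes, each carrying its kind,
#' hyper-parameters, weights, and inferred output shape.  Nodes are stored
#' in topological (construction) order.  Feature maps flow through the
#' graph as `[H, W, C, N]` arrays (batch last); global pooling collapses a
#' map to an `N x C` matrix, which dense layers then consume.
#' @name layer_graph
NULL

# ---- construction -----------------------------------------------------------

lg_new <- function(input_shapes, input_names = names(input_shapes)) {
  if (is.null(input_names)) input_names <- "input"
  if (!is.list(input_shapes)) input_shapes <- list(input_shapes)
  names(input_shapes) <- input_names
  nodes <- list()
  for (nm in input_names) {
    nodes[[nm]] <- list(name = nm, kind = "input", inputs = character(),
                        hyper = list(), params = list(), buffers = list(),
                        trainable = FALSE, out_shape = as.integer(input_shapes[[nm]]))
  }
  structure(list(nodes = nodes, input_names = input_names, output_name = input_names[[1]]),
            class = "layer_graph")
}

lg_add <- function(g, name, kind, inputs, hyper = list(), params = list(),
                   buffers = list(), trainable = length(params) > 0) {
  if (name %in% names(g$nodes)) abort(paste0("duplicate layer name: ", name))
  missing_in <- setdiff(inputs, names(g$nodes))
  if (length(missing_in)) abort(paste0("unknown input node(s): ", paste(missing_in, collapse = ", ")))
  in_shapes <- lapply(inputs, function(nm) g$nodes[[nm]]$out_shape)
  out_shape <- shape_infer(kind, in_shapes, hyper, name)
  g$nodes[[name]] <- list(name = name, kind = kind, inputs = inputs, hyper = hyper,
                          params = params, buffers = buffers, trainable = trainable,
                          out_shape = as.integer(out_shape))
  g$output_name <- name
  g
}

# TensorFlow-style "same" padding amounts for one dimension.
pad_same <- function(n, k, s) {
  out <- ceiling(n / s)
  total <- max((out - 1) * s + k - n, 0)
  c(total %/% 2, total - total %/% 2)
}

conv_out <- function(n, k, s, p0, p1, name, dimname) {
  out <- (n + p0 + p1 - k) %/% s + 1
  if (out < 1) {
    abort(sprintf(
      "layer '%s': %s dimension %d is too small for kernel %d / stride %d (input shape unsupported)",
      name, dimname, n, k, s))
  }
  out
}

shape_infer <- function(kind, in_shapes, hyper, name) {
  s1 <- in_shapes[[1]]
  switch(kind,
    conv = {
      w <- hyper$kernel_shape # c(kh, kw, Cin, F)
      if (s1[3] != w[3]) abort(sprintf("layer '%s': expects %d channels, got %d", name, w[3], s1[3]))
      p <- hyper$pad
      c(conv_out(s1[1], w[1], hyper$stride[1], p[1], p[2], name, "height"),
        conv_out(s1[2], w[2], hyper$stride[2], p[3], p[4], name, "width"),
        w[4])
    },
    dwconv = {
      w <- hyper$kernel_shape # c(kh, kw, C)
      if (s1[3] != w[3]) abort(sprintf("layer '%s': expects %d channels, got %d", name, w[3], s1[3]))
      p <- hyper$pad
      c(conv_out(s1[1], w[1], hyper$stride[1], p[1], p[2], name, "height"),
        conv_out(s1[2], w[2], hyper$stride[2], p[3], p[4], name, "width"),
        s1[3])
    },
    maxpool = ,
    avgpool = {
      p <- hyper$pad %||% c(0L, 0L, 0L, 0L)
      c(conv_out(s1[1], hyper$pool[1], hyper$stride[1], p[1], p[2], name, "height"),
        conv_out(s1[2], hyper$pool[2], hyper$stride[2], p[3], p[4], name, "width"),
        s1[3])
    },
    bn = ,
    act = ,
    dropout = ,
    alpha_dropout = s1,
    gap = s1[3],
    dense = hyper$units,
    softmax = s1,
    add = {
      for (s in in_shapes) {
        if (!identical(as.integer(s), as.integer(s1))) {
          abort(sprintf("layer '%s': addition requires identical shapes, got %s vs %s",
                        name, paste(s1, collapse = "x"), paste(s, collapse = "x")))
        }
      }
      s1
    },
    concat = {
      for (s in in_shapes) {
        if (length(s) != 3 || any(s[1:2] != s1[1:2])) {
          abort(sprintf("layer '%s': concatenation requires matching spatial dims, got %s",
                        name, paste(vapply(in_shapes, function(z) paste(z, collapse = "x"), ""),
                                    collapse = ", ")))
        }
      }
      c(s1[1], s1[2], sum(vapply(in_shapes, function(s) s[3], integer(1))))
    },
    scale = s1,
    abort(paste0("unknown layer kind: ", kind))
  )
}

# ---- weight initialization --------------------------------------------------

init_conv_w <- function(kh, kw, cin, f, init = c("he", "lecun", "glorot")) {
  init <- match.arg(init)
  fan_in <- kh * kw * cin
  shape <- c(kh, kw, cin, f)
  switch(init,
    he = he_normal_init(fan_in, shape),
    lecun = lecun_normal_init(fan_in, shape),
    glorot = array(rnorm(prod(shape), sd = sqrt(2 / (fan_in + kh * kw * f))), shape)
  )
}

# ---- convenience node builders (used by the backbone/head constructors) -----

add_conv <- function(g, name, input, filters, kernel, stride = 1L,
                     padding = c("valid", "same"), pad = NULL, use_bias = TRUE,
                     init = "he", trainable = TRUE) {
  padding <- match.arg(padding)
  in_shape <- g$nodes[[input]]$out_shape
  kernel <- rep(as.integer(kernel), length.out = 2)
  stride <- rep(as.integer(stride), length.out = 2)
  if (is.null(pad)) {
    pad <- if (padding == "same") {
      c(pad_same(in_shape[1], kernel[1], stride[1]), pad_same(in_shape[2], kernel[2], stride[2]))
    } else c(0L, 0L, 0L, 0L)
  }
  w <- init_conv_w(kernel[1], kernel[2], in_shape[3], filters, init)
  params <- list(w = w)
  if (use_bias) params$b <- numeric(filters)
  lg_add(g, name, "conv", input,
         hyper = list(kernel_shape = dim(w), stride = stride, pad = as.integer(pad),
                      use_bias = use_bias),
         params = params, trainable = trainable)
}

add_dwconv <- function(g, name, input, kernel, stride = 1L,
                       padding = c("same", "valid"), use_bias = FALSE) {
  padding <- match.arg(padding)
  in_shape <- g$nodes[[input]]$out_shape
  kernel <- rep(as.integer(kernel), length.out = 2)
  stride <- rep(as.integer(stride), length.out = 2)
  pad <- if (padding == "same") {
    c(pad_same(in_shape[1], kernel[1], stride[1]), pad_same(in_shape[2], kernel[2], stride[2]))
  } else c(0L, 0L, 0L, 0L)
  w <- array(rnorm(kernel[1] * kernel[2] * in_shape[3],
                   sd = sqrt(2 / (kernel[1] * kernel[2]))),
             c(kernel[1], kernel[2], in_shape[3]))
  params <- list(w = w)
  if (use_bias) params$b <- numeric(in_shape[3])
  lg_add(g, name, "dwconv", input,
         hyper = list(kernel_shape = dim(w), stride = stride, pad = as.integer(pad),
                      use_bias = use_bias),
         params = params)
}

add_bn <- function(g, name, input, eps = 1e-3, trainable = TRUE) {
  c_in <- tail(g$nodes[[input]]$out_shape, 1)
  # momentum 0.9: running statistics must converge within the short
  # training runs this package targets (frozen backbones never update
  # theirs, so this only governs the trainable head)
  lg_add(g, name, "bn", input,
         hyper = list(eps = eps, momentum = 0.9, frozen = FALSE),
         params = list(gamma = rep(1, c_in), beta = numeric(c_in)),
         buffers = list(mean = numeric(c_in), var = rep(1, c_in)),
         trainable = trainable)
}

add_act <- function(g, name, input, fun) {
  lg_add(g, name, "act", input, hyper = list(fun = fun))
}

add_pool <- function(g, name, input, kind, pool, stride = pool, pad = c(0L, 0L, 0L, 0L)) {
  lg_add(g, name, kind, input,
         hyper = list(pool = rep(as.integer(pool), 2), stride = rep(as.integer(stride), 2),
                      pad = as.integer(pad)))
}

add_dense <- function(g, name, input, units, use_bias = TRUE, init = "lecun") {
  c_in <- g$nodes[[input]]$out_shape
  stopifnot(length(c_in) == 1)
  w <- switch(init,
    lecun = lecun_normal_init(c_in, c(c_in, units)),
    he = he_normal_init(c_in, c(c_in, units)),
    glorot = matrix(rnorm(c_in * units, sd = sqrt(2 / (c_in + units))), c_in, units),
    # near-zero: classification layers on features of unknown scale start
    # with an almost-uniform softmax instead of a saturated one
    small = matrix(rnorm(c_in * units, sd = 1e-4), c_in, units)
  )
  params <- list(w = w)
  if (use_bias) params$b <- numeric(units)
  lg_add(g, name, "dense", input, hyper = list(units = as.integer(units), use_bias = use_bias),
         params = params)
}

# ---- activations ------------------------------------------------------------

act_fun <- function(x, fun) {
  switch(fun,
    relu = pmax(x, 0),
    relu6 = pmin(pmax(x, 0), 6),
    swish = x / (1 + exp(-x)),
    sigmoid = 1 / (1 + exp(-x)),
    selu = selu(x),
    linear = x,
    abort(paste0("unknown activation: ", fun))
  )
}

act_grad <- function(x, fun) {
  switch(fun,
    relu = (x > 0) + 0,
    relu6 = (x > 0 & x < 6) + 0,
    selu = selu_grad(x),
    linear = array(1, dim(x) %||% length(x)),
    abort(paste0("no gradient implemented for activation: ", fun))
  )
}

# ---- forward execution ------------------------------------------------------

#' Run a layer graph forward
#'
#' @param graph A `layer_graph`.
#' @param inputs Named list of input arrays `[H, W, C, N]`, one per input
#'   node (a single unnamed array is accepted for single-input graphs).
#' @param training Logical; enables dropout and batch-statistics mode for
#'   trainable batch-norm layers.
#' @param keep_all Keep every node's output (required before a backward
#'   pass); when `FALSE`, intermediate outputs are freed as soon as all
#'   their consumers have run, which keeps the memory footprint of deep
#'   backbone forward passes small.
#' @return A list with `out` (the output node's value) and, when
#'   `keep_all = TRUE`, `values` and `cache` for backpropagation.
#' @keywords internal
forward_pass <- function(graph, inputs, training = FALSE, keep_all = FALSE,
                         drop_active = training) {
  if (!is.list(inputs)) inputs <- stats::setNames(list(inputs), graph$input_names[[1]])
  values <- new.env(parent = emptyenv())
  cache <- if (keep_all) new.env(parent = emptyenv()) else NULL
  # consumer counts for memory freeing
  ncons <- new.env(parent = emptyenv())
  for (node in graph$nodes) for (nm in node$inputs) {
    assign(nm, (mget(nm, ncons, ifnotfound = 0L)[[1]]) + 1L, ncons)
  }
  for (nm in graph$input_names) {
    x <- inputs[[nm]]
    if (is.null(x)) abort(paste0("missing input: ", nm))
    shp <- graph$nodes[[nm]]$out_shape
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
    if (!identical(as.integer(dim(x)[1:3]), shp)) {
      abort(sprintf("input '%s': expected shape %s, got %s", nm,
                    paste(shp, collapse = "x"), paste(dim(x)[1:3], collapse = "x")))
    }
    assign(nm, x, values)
  }
  for (node in graph$nodes) {
    if (node$kind == "input") next
    xs <- lapply(node$inputs, function(nm) get(nm, values))
    res <- layer_forward(node, xs, training = training, want_cache = keep_all,
                         drop_active = drop_active)
    assign(node$name, res$out, values)
    if (keep_all && !is.null(res$extra)) assign(node$name, res$extra, cache)
    if (!keep_all) {
      for (nm in node$inputs) {
        k <- get(nm, ncons) - 1L
        assign(nm, k, ncons)
        if (k == 0L && nm != graph$output_name) assign(nm, NULL, values)
      }
    }
  }
  list(out = get(graph$output_name, values), values = values, cache = cache)
}

layer_forward <- function(node, xs, training = FALSE, want_cache = FALSE,
                          drop_active = training) {
  x <- xs[[1]]
  h <- node$hyper
  out <- NULL; extra <- NULL
  switch(node$kind,
    conv = {
      out <- cpp_conv2d_fwd(x, dim(x), node$params$w, dim(node$params$w),
                            node$params$b %||% numeric(0),
                            h$stride[1], h$stride[2], h$pad[1], h$pad[2], h$pad[3], h$pad[4])
    },
    dwconv = {
      out <- cpp_dwconv_fwd(x, dim(x), node$params$w, dim(node$params$w),
                            node$params$b %||% numeric(0),
                            h$stride[1], h$stride[2], h$pad[1], h$pad[2], h$pad[3], h$pad[4])
    },
    bn = {
      eps <- h$eps
      if (training && node$trainable && !isTRUE(h$frozen)) {
        d <- dim(x); C <- d[3]; N <- d[4]
        m <- matrix(x, d[1] * d[2], C * N)
        mu_cn <- colMeans(m)
        mu <- rowMeans(matrix(mu_cn, C, N))
        m2_cn <- colMeans(m * m)
        m2 <- rowMeans(matrix(m2_cn, C, N))
        v <- pmax(m2 - mu^2, 0)
        sc <- node$params$gamma / sqrt(v + eps)
        out <- cpp_chan_affine(x, d, sc, node$params$beta - mu * sc)
        extra <- list(mu = mu, var = v, n_eff = d[1] * d[2] * N)
      } else {
        sc <- node$params$gamma / sqrt(node$buffers$var + eps)
        out <- cpp_chan_affine(x, dim(x), sc, node$params$beta - node$buffers$mean * sc)
      }
    },
    act = out <- act_fun(x, h$fun),
    maxpool = {
      p <- h$pad
      out <- cpp_maxpool_fwd(x, dim(x), h$pool[1], h$pool[2], h$stride[1], h$stride[2],
                             p[1], p[2], p[3], p[4])
    },
    avgpool = {
      out <- cpp_avgpool_fwd(x, dim(x), h$pool[1], h$pool[2], h$stride[1], h$stride[2])
    },
    gap = {
      d <- dim(x)
      out <- t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
    },
    dense = {
      out <- x %*% node$params$w
      if (!is.null(node$params$b)) out <- sweep(out, 2, node$params$b, "+")
    },
    softmax = {
      z <- x - apply(x, 1, max)
      e <- exp(z)
      out <- e / rowSums(e)
    },
    add = {
      out <- xs[[1]]
      for (i in seq_along(xs)[-1]) out <- out + xs[[i]]
    },
    concat = {
      d1 <- dim(xs[[1]])
      cs <- vapply(xs, function(z) dim(z)[3], integer(1))
      out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
      at <- 0L
      for (z in xs) {
        cz <- dim(z)[3]
        out[, , (at + 1):(at + cz), ] <- z
        at <- at + cz
      }
    },
    scale = {
      s <- xs[[2]] # N x C gates
      d <- dim(x)
      out <- cpp_chan_affine(x, d, as.numeric(t(s)), numeric(d[3] * d[4]))
    },
    dropout = {
      if (training && drop_active && h$rate > 0) {
        keep <- runif(length(x)) >= h$rate
        out <- x * keep / (1 - h$rate)
        dim(out) <- dim(x) %||% NULL
        extra <- list(keep = keep)
      } else out <- x
    },
    alpha_dropout = {
      if (training && drop_active && h$rate > 0) {
        res <- alpha_dropout_train(x, h$rate)
        out <- res$out
        extra <- list(keep = res$keep, a = res$a)
      } else out <- x
    },
    abort(paste0("no forward rule for kind: ", node$kind))
  )
  if (want_cache) extra <- c(extra %||% list(), list(x = if (node$kind %in%
    c("conv", "bn", "act", "avgpool", "gap", "dense") ) x else NULL))
  list(out = out, extra = extra)
}

# ---- backward execution -----------------------------------------------------

# Backpropagate d_out (gradient w.r.t. node `from`'s output) through the
# graph, returning per-node parameter gradients.  Only the layer kinds that
# appear in trainable head graphs have backward rules; frozen backbones are
# never backpropagated through.
backward_pass <- function(graph, values, cache, from, d_out) {
  grads <- list()
  dvals <- new.env(parent = emptyenv())
  assign(from, d_out, dvals)
  node_names <- names(graph$nodes)
  start <- match(from, node_names)
  for (i in seq(start, 1)) {
    node <- graph$nodes[[i]]
    if (node$kind == "input") next
    nm <- node$name
    dy <- mget(nm, dvals, ifnotfound = list(NULL))[[1]]
    if (is.null(dy)) next
    assign(nm, NULL, dvals)
    ext <- if (!is.null(cache)) mget(nm, cache, ifnotfound = list(NULL))[[1]] else NULL
    # no input gradient needed when every feeding node is a graph input
    need_dx <- any(vapply(node$inputs, function(s) graph$nodes[[s]]$kind != "input",
                          logical(1)))
    res <- layer_backward(node, dy, ext, values, need_dx = need_dx)
    if (!is.null(res$pgrads)) grads[[nm]] <- res$pgrads
    for (j in seq_along(node$inputs)) {
      src <- node$inputs[[j]]
      if (graph$nodes[[src]]$kind == "input") next
      dj <- res$dx[[j]]
      if (is.null(dj)) next
      prev <- mget(src, dvals, ifnotfound = list(NULL))[[1]]
      assign(src, if (is.null(prev)) dj else prev + dj, dvals)
    }
  }
  grads
}

layer_backward <- function(node, dy, ext, values, need_dx = TRUE) {
  h <- node$hyper
  x <- ext$x
  switch(node$kind,
    conv = {
      r <- cpp_conv2d_bwd(x, dim(x), node$params$w, dim(node$params$w), dy,
                          !is.null(node$params$b),
                          h$stride[1], h$stride[2], h$pad[1], h$pad[2], h$pad[3], h$pad[4],
                          need_dx)
      pg <- list(w = r$dw)
      if (!is.null(node$params$b)) pg$b <- as.numeric(r$db)
      list(dx = list(if (need_dx) r$dx), pgrads = pg)
    },
    avgpool = {
      d <- dim(x)
      list(dx = list(cpp_avgpool_bwd(dy, dim(dy), d[1], d[2],
                                     h$pool[1], h$pool[2], h$stride[1], h$stride[2])))
    },
    gap = {
      d <- dim(x)
      # dy is N x C; broadcast back over H*W and divide by H*W
      g <- array(0, d)
      hw <- d[1] * d[2]
      gm <- t(dy) / hw                        # C x N
      list(dx = list(cpp_chan_affine(array(1, d), d, as.numeric(gm), numeric(d[3] * d[4]))))
    },
    dense = {
      pg <- list(w = t(x) %*% dy)
      if (!is.null(node$params$b)) pg$b <- colSums(dy)
      list(dx = list(dy %*% t(node$params$w)), pgrads = pg)
    },
    act = list(dx = list(dy * act_grad(x, h$fun))),
    bn = {
      if (is.null(ext$mu)) abort("bn backward requires a training-mode forward pass")
      d <- dim(x); C <- d[3]; N <- d[4]; n_eff <- ext$n_eff
      istd <- 1 / sqrt(ext$var + h$eps)
      xhat <- cpp_chan_affine(x, d, istd, -ext$mu * istd)
      # sum over H, W and batch for each channel
      per_chan <- function(a) rowSums(matrix(colSums(matrix(a, d[1] * d[2], C * N)), C, N))
      s_dy <- per_chan(dy)
      s_dyx <- per_chan(dy * xhat)
      dgamma <- s_dyx
      dbeta <- s_dy
      g <- node$params$gamma
      # dx = gamma*istd/n * (n*dy - sum(dy) - xhat * sum(dy*xhat))
      t1 <- cpp_chan_affine(dy, d, rep(n_eff, C), -s_dy)
      t2 <- cpp_chan_affine(xhat, d, s_dyx, numeric(C))
      dx <- cpp_chan_affine(t1 - t2, d, g * istd / n_eff, numeric(C))
      list(dx = list(dx), pgrads = list(gamma = dgamma, beta = dbeta))
    },
    add = list(dx = rep(list(dy), length(node$inputs))),
    concat = {
      splits <- list()
      at <- 0L
      for (j in seq_along(node$inputs)) {
        cz <- values_shape_channels(values, node$inputs[[j]])
        splits[[j]] <- dy[, , (at + 1):(at + cz), , drop = FALSE]
        at <- at + cz
      }
      list(dx = splits)
    },
    dropout = {
      g <- dy * ext$keep / (1 - h$rate)
      dim(g) <- dim(dy)
      list(dx = list(g))
    },
    alpha_dropout = {
      g <- dy * ext$keep * ext$a
      dim(g) <- dim(dy)
      list(dx = list(g))
    },
    abort(paste0("no backward rule for kind: ", node$kind))
  )
}

values_shape_channels <- function(values, nm) {
  dim(get(nm, values))[3]
}

# ---- counting, freezing, summaries ------------------------------------------

#' Count parameters of a layer graph
#'
#' Counts every weight scalar in the graph: convolution kernels and biases,
#' dense weights, batch-norm scale/shift, and (unless `trainable_only`)
#' batch-norm moving statistics, so that the total matches the on-disk
#' parameter count reported by mainstream frameworks (4 scalars per
#' batch-norm channel).
#'
#' @param graph A `layer_graph` (or an assembled fused model).
#' @param trainable_only Count only weights of trainable layers (moving
#'   statistics are always excluded here).
#' @return Integer scalar.
#' @export
count_parameters <- function(graph, trainable_only = FALSE) {
  if (inherits(graph, "fused_model")) {
    return(sum(vapply(c(graph$backbones, list(graph$head)), count_parameters,
                      numeric(1), trainable_only = trainable_only)))
  }
  stopifnot(inherits(graph, "layer_graph"))
  tot <- 0
  for (node in graph$nodes) {
    if (is.null(node$out_shape)) abort("count_parameters: graph has unshaped nodes")
    np <- sum(vapply(node$params, length, numeric(1)))
    if (trainable_only) {
      if (node$trainable) tot <- tot + np
    } else {
      tot <- tot + np + sum(vapply(node$buffers, length, numeric(1)))
    }
  }
  tot
}

#' Freeze a layer graph
#'
#' Marks every node non-trainable.  Batch-norm layers additionally switch
#' to inference mode permanently: their moving statistics are used for
#' normalization and never updated, the standard transfer-learning
#' treatment of a frozen backbone.
#'
#' @param graph A `layer_graph`.
#' @return The frozen graph.
#' @export
freeze <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  for (nm in names(graph$nodes)) {
    graph$nodes[[nm]]$trainable <- FALSE
    if (graph$nodes[[nm]]$kind == "bn") graph$nodes[[nm]]$hyper$frozen <- TRUE
  }
  graph
}

#' Estimate FLOPs of a layer graph
#'
#' Multiply-accumulate based estimate using the 2 x MACs convention:
#' convolution and dense layers only, kernel multiplies only (biases,
#' batch-norm and activations excluded).
#'
#' @param graph A `layer_graph` or fused model.
#' @return Numeric scalar (FLOPs for one image).
#' @export
count_flops <- function(graph) {
  if (inherits(graph, "fused_model")) {
    return(sum(vapply(c(graph$backbones, list(graph$head)), count_flops, numeric(1))))
  }
  stopifnot(inherits(graph, "layer_graph"))
  tot <- 0
  for (node in graph$nodes) {
    s <- node$out_shape
    tot <- tot + switch(node$kind,
      conv = { k <- node$hyper$kernel_shape; 2 * prod(k) * s[1] * s[2] },
      dwconv = { k <- node$hyper$kernel_shape; 2 * prod(k) * s[1] * s[2] },
      dense = 2 * length(node$params$w),
      0)
  }
  tot
}

#' Tidy per-layer summary of a graph
#'
#' @param x A `layer_graph`.
#' @param ... Unused.
#' @return A tibble with one row per layer: `name`, `kind`, `output_shape`,
#'   `params`, `trainable`.
#' @export
tidy.layer_graph <- function(x, ...) {
  tibble::tibble(
    name = names(x$nodes),
    kind = vapply(x$nodes, function(n) n$kind, character(1)),
    output_shape = vapply(x$nodes, function(n) paste(n$out_shape, collapse = "x"), character(1)),
    params = vapply(x$nodes, function(n)
      sum(vapply(n$params, length, numeric(1))) + sum(vapply(n$buffers, length, numeric(1))),
      numeric(1)),
    trainable = vapply(x$nodes, function(n) n$trainable, logical(1))
  )
}

#' One-row summary of a graph
#'
#' @param x A `layer_graph`.
#' @param ... Unused.
#' @return A tibble with layer/parameter totals and the output shape.
#' @export
glance.layer_graph <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$nodes),
    total_params = count_parameters(x),
    trainable_params = count_parameters(x, trainable_only = TRUE),
    flops = count_flops(x),
    output_shape = paste(x$nodes[[x$output_name]]$out_shape, collapse = "x")
  )
}

#' @export
print.layer_graph <- function(x, ...) {
  out_node <- x$nodes[[x$output_name]]
  cat(sprintf("<layer_graph> %d layers, output %s, %s params (%s trainable)\n",
              length(x$nodes), paste(out_node$out_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ","),
              format(count_parameters(x, trainable_only = TRUE), big.mark = ",")))
  invisible(x)
}

#' @export
summary.layer_graph <- function(object, ...) {
  df <- tidy(object)
  print(df, n = nrow(df))
  cat(sprintf("Total params: %s | Trainable: %s | FLOPs/image: %s\n",
              format(count_parameters(object), big.mark = ","),
              format(count_parameters(object, trainable_only = TRUE), big.mark = ","),
              format(count_flops(object), big.mark = ",")))
  invisible(df)
}
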