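#' Self-normalizing activation constants
#'
#' The scaled exponential linear unit (SeLU) depends on two constants,
#' `alpha` and `lambda`, chosen so that a network of dense layers with
#' LeCun-normal weights drives activations toward zero mean and unit
#' variance.  The defaults are the full-precision self-normalization
#' constants; the commonly printed 4-decimal values (alpha = 1.6733,
#' lambda = 1.0507) are rounded forms of these.
#'
#' The derived constant `alpha_prime = -lambda * alpha` is the saturation
#' value of SeLU as `x -> -Inf`; alpha dropout replaces dropped units with
#' it rather than with zero.
#'
#' @param alpha Positive scalar, the exponential-branch scale (> 1).
#' @param lambda Positive scalar, the overall output scale (> 1).
#' @return An object of class `selu_params`: a list with `alpha`, `lambda`
#'   and the derived `alpha_prime`.
#' @examples
#' p <- selu_params()
#' p$alpha_prime # == -p$lambda * p$alpha
#' @export
selu_params <- function(alpha = 1.6732632423543772, lambda = 1.0507009873554805) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(lambda), length(lambda) == 1, is.finite(lambda))
  structure(
    list(alpha = alpha, lambda = lambda, alpha_prime = -lambda * alpha),
    class = "selu_params"
  )
}

#' @export
print.selu_params <- function(x, ...) {
  cat(sprintf("<selu_params> alpha = %.10f, lambda = %.10f, alpha' = %.10f\n",
              x$alpha, x$lambda, x$alpha_prime))
  invisible(x)
}

#' Scaled exponential linear unit
#'
#' `selu(x)` equals `lambda * x` for `x > 0` and `lambda * alpha * (exp(x) - 1)`
#' for `x <= 0`; it is continuous and strictly increasing, with range
#' `(alpha_prime, Inf)`.
#'
#' @param x Numeric vector or array (finite values).
#' @param params A [selu_params()] object.
#' @return Numeric object of the same shape as `x`.
#' @examples
#' selu(0)                       # 0
#' selu(1, selu_params(1.6733, 1.0507)) # lambda * 1
#' @export
selu <- function(x, params = selu_params()) {
  stopifnot(inherits(params, "selu_params"))
  if (anyNA(x) || any(!is.finite(x))) {
    abort("selu: input contains non-finite values")
  }
  pos <- x > 0
  out <- params$lambda * params$alpha * (exp(pmin(x, 0)) - 1)
  out[pos] <- params$lambda * x[pos]
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Derivative of selu at its pre-activation value (used by backprop).
selu_grad <- function(x, params = selu_params()) {
  g <- params$lambda * params$alpha * exp(pmin(x, 0))
  g[x > 0] <- params$lambda
  if (!is.null(dim(x))) dim(g) <- dim(x)
  g
}

#' SeLU saturation value
#'
#' The limit of `selu(x)` as `x -> -Inf` equals `-lambda * alpha`, written
#' `alpha_prime`.  This is the value alpha dropout substitutes for dropped
#' units.
#'
#' @inheritParams selu
#' @return A scalar, `-lambda * alpha`.
#' @export
selu_saturation <- function(params = selu_params()) {
  params$alpha_prime
}

#' Alpha dropout
#'
#' Dropout variant matched to SeLU: with probability `rate` a unit is set to
#' the SeLU saturation value `alpha_prime` (not zero), and the result is
#' affinely rescaled so that, for standard-normal input, the output keeps
#' zero mean and unit variance in expectation.  With `training = FALSE` the
#' input is returned unchanged.
#'
#' The correction coefficients are the closed form
#' `a = (q + alpha_prime^2 * q * (1 - q))^(-1/2)` and
#' `b = -a * (1 - q) * alpha_prime`, with `q = 1 - rate` the keep
#' probability.
#'
#' @param x Numeric vector or array.
#' @param rate Fraction of units dropped, in `[0, 1)`.  Default 0.2, the
#'   auxiliary-head setting.
#' @param training Apply dropout (`TRUE`) or act as the identity (`FALSE`).
#' @param params A [selu_params()] object.
#' @param seed Optional integer; if supplied the drop mask is drawn under
#'   this seed without disturbing the global RNG stream.
#' @return Numeric object of the same shape as `x`.
#' @export
alpha_dropout <- function(x, rate = 0.2, training = TRUE,
                          params = selu_params(), seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    abort("alpha_dropout: `rate` must lie in [0, 1)")
  }
  if (!training || rate == 0) {
    return(x)
  }
  q <- 1 - rate
  ap <- params$alpha_prime
  a <- (q + ap^2 * q * (1 - q))^(-0.5)
  b <- -a * (1 - q) * ap
  draw <- function() runif(length(x)) >= rate
  keep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- a * ifelse(keep, x, ap) + b
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Alpha-dropout forward that also returns what backprop needs.
alpha_dropout_train <- function(x, rate, params = selu_params()) {
  q <- 1 - rate
  ap <- params$alpha_prime
  a <- (q + ap^2 * q * (1 - q))^(-0.5)
  keep <- (runif(length(x)) >= rate) + 0
  out <- a * (x * keep + ap * (1 - keep)) - a * (1 - q) * ap
  if (!is.null(dim(x))) dim(out) <- dim(x)
  list(out = out, keep = keep, a = a)
}

#' Standard (zero-substituting) dropout
#'
#' Inverted dropout: units are zeroed with probability `rate` and survivors
#' are scaled by `1 / (1 - rate)`.  Provided for the ablation variants that
#' replace alpha dropout with the conventional kind.
#'
#' @inheritParams alpha_dropout
#' @return Numeric object of the same shape as `x`.
#' @export
standard_dropout <- function(x, rate = 0.2, training = TRUE, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    abort("standard_dropout: `rate` must lie in [0, 1)")
  }
  if (!training || rate == 0) {
    return(x)
  }
  draw <- function() runif(length(x)) >= rate
  keep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- x * keep / (1 - rate)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' LeCun-normal initializer
#'
#' Draws weights with mean 0 and standard deviation `1 / sqrt(fan_in)`.  By
#' default draws come from a truncated normal (cut at two standard
#' deviations, variance-corrected so the realized standard deviation is
#' still `1 / sqrt(fan_in)`), the variant common in self-normalizing
#' network implementations; set `truncated = FALSE` for the plain normal.
#'
#' @param fan_in Positive integer, number of input units feeding a weight.
#' @param shape Integer vector giving the dimensions of the returned array;
#'   defaults to `fan_in` draws.
#' @param truncated Use the two-sigma truncated variant (default `TRUE`).
#' @return Numeric array of dimension `shape`.
#' @export
lecun_normal_init <- function(fan_in, shape = fan_in, truncated = TRUE) {
  if (!is.numeric(fan_in) || length(fan_in) != 1 || fan_in < 1) {
    abort("lecun_normal_init: `fan_in` must be a positive integer")
  }
  n <- prod(shape)
  sd_target <- 1 / sqrt(fan_in)
  if (truncated) {
    # Inverse-CDF sampling of N(0,1) truncated to [-2, 2]; its sd is
    # 0.8796257 so rescale to hit the target exactly.
    p <- runif(n, pnorm(-2), pnorm(2))
    z <- qnorm(p)
    z <- z / 0.8796256610342398
  } else {
    z <- rnorm(n)
  }
  out <- z * sd_target
  if (length(shape) > 1) dim(out) <- shape
  out
}

# He-normal initializer (ReLU-family backbones and ablation variants).
he_normal_init <- function(fan_in, shape = fan_in) {
  out <- rnorm(prod(shape), sd = sqrt(2 / fan_in))
  if (length(shape) > 1) dim(out) <- shape
  out
}
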