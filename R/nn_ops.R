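#' Output size of a strided convolution or pooling stage
#'
#' With explicit symmetric zero padding of `padding` pixels per side the
#' output size is \eqn{1 + \lfloor (2N + H_I - H_F) / M \rfloor}; with
#' `"same"` padding it is \eqn{\lceil H_I / M \rceil} (the padding needed to
#' achieve that is distributed as evenly as possible, extra pixel after).
#'
#' @param input_size input extent in pixels (vectorized).
#' @param kernel filter extent in pixels.
#' @param stride step in pixels.
#' @param padding `"same"` or a non-negative integer pad per side.
#' @return integer output extent(s).
#' @export
conv_out_shape <- function(input_size, kernel, stride = 1, padding = "same") {
  stopifnot(all(input_size >= 1), kernel >= 1, stride >= 1)
  if (identical(padding, "same")) {
    out <- as.integer(ceiling(input_size / stride))
  } else {
    stopifnot(is.numeric(padding), padding >= 0)
    out <- as.integer(1 + floor((2 * padding + input_size - kernel) / stride))
  }
  if (any(out < 1)) {
    msnet_error("NonPositiveOutput", "layer geometry yields an empty output")
  }
  out
}

# per-dimension (before, after) zero padding realizing "same" output size
same_pads <- function(input_size, kernel, stride) {
  out <- ceiling(input_size / stride)
  total <- max((out - 1) * stride + kernel - input_size, 0)
  c(total %/% 2, total - total %/% 2)
}

conv_pads <- function(h, w, kernel, stride, padding) {
  if (identical(padding, "same")) {
    c(same_pads(h, kernel, stride), same_pads(w, kernel, stride))
  } else {
    c(padding, padding, padding, padding)
  }
}

# promote matrix / 3-d input to H x W x C x N, remembering how to demote
promote4d <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) {
    list(x = array(x, c(dim(as.matrix(x)), 1, 1)), ndim = 2)
  } else if (length(d) == 3) {
    list(x = array(x, c(d, 1)), ndim = 3)
  } else if (length(d) == 4) {
    list(x = x, ndim = 4)
  } else {
    msnet_error("ShapeMismatch", "expected a 2-d, 3-d or 4-d activation map")
  }
}

demote <- function(y, ndim) {
  d <- dim(y)
  if (ndim == 2 && d[3] == 1 && d[4] == 1) return(matrix(y, d[1], d[2]))
  if (ndim == 3 && d[4] == 1) return(array(y, d[1:3]))
  y
}

#' 2-D convolution (cross-correlation convention)
#'
#' Sliding dot-product of `filters` over `x` with stride `stride` and zero
#' padding per `padding`. The filter channel depth must equal the input
#' depth. Accepts a plain matrix (one channel, one image), an H x W x C
#' array, or an H x W x C x N batch; the output has one channel per filter.
#'
#' @param x input map.
#' @param filters a KH x KW x C x Z array (or KH x KW x C for one filter,
#'   or a matrix for one single-channel filter).
#' @param bias numeric vector of length Z (default zeros).
#' @param stride step in pixels.
#' @param padding `"same"` or integer pixels per side.
#' @return activation map with `conv_out_shape` spatial dims and Z channels,
#'   shaped like the input (matrix in, matrix out when Z = 1).
#' @export
conv2d <- function(x, filters, bias = NULL, stride = 1, padding = "same") {
  px <- promote4d(x)
  if (is.matrix(filters)) filters <- array(filters, c(dim(filters), 1, 1))
  if (length(dim(filters)) == 3) filters <- array(filters, c(dim(filters), 1))
  if (dim(filters)[3] != dim(px$x)[3]) {
    msnet_error("ChannelMismatch", sprintf(
      "filter depth %d != input depth %d", dim(filters)[3], dim(px$x)[3]))
  }
  z <- dim(filters)[4]
  if (is.null(bias)) bias <- numeric(z)
  d <- dim(px$x)
  # validate geometry through the shape formula before calling the kernel
  conv_out_shape(d[1], dim(filters)[1], stride, padding)
  conv_out_shape(d[2], dim(filters)[2], stride, padding)
  pads <- conv_pads(d[1], d[2], dim(filters)[1], stride, padding)
  y <- conv2d_forward_cpp(px$x, filters, bias, stride,
                          pads[1], pads[2], pads[3], pads[4])
  demote(y, px$ndim)
}

#' Rectified linear unit
#' @param x numeric vector, matrix or array.
#' @return elementwise `max(0, x)`, same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Batch-normalization state
#'
#' Per-channel learnable scale/offset plus running moments for inference.
#' `epsilon` guards the variance denominator (default 1e-5); `momentum` is
#' the fraction of the new batch moment blended into the running moment
#' after each training-mode call.
#'
#' @param channels number of channels (features).
#' @param gamma,beta initial scale and offset (recycled to `channels`).
#' @param epsilon small positive stabilizer.
#' @param momentum running-moment update rate in (0, 1).
#' @return an object of class `bn_state`.
#' @export
bn_state <- function(channels, gamma = 1, beta = 0, epsilon = 1e-5,
                     momentum = 0.1) {
  stopifnot(channels >= 1, epsilon > 0, momentum > 0, momentum < 1)
  structure(
    list(gamma = rep_len(gamma, channels), beta = rep_len(beta, channels),
         epsilon = epsilon, momentum = momentum,
         running_mean = numeric(channels), running_var = rep(1, channels),
         initialized = FALSE),
    class = "bn_state"
  )
}

# core batch-norm on an m x C matrix (rows = batch members incl. spatial
# positions, columns = channels); returns output, updated state and the
# cache the backward pass needs
bn_core <- function(xm, state, mode, want_cache = FALSE) {
  if (mode == "train") {
    m <- nrow(xm)
    if (m < 2) msnet_error("BatchTooSmall", "batch normalization needs m >= 2")
    mu <- colMeans(xm)
    centered <- sweep(xm, 2, mu)
    v <- colMeans(centered^2)            # population variance over the batch
    inv_std <- 1 / sqrt(v + state$epsilon)
    xhat <- sweep(centered, 2, inv_std, `*`)
    mom <- state$momentum
    if (state$initialized) {
      state$running_mean <- (1 - mom) * state$running_mean + mom * mu
      state$running_var <- (1 - mom) * state$running_var + mom * v
    } else {
      state$running_mean <- mu
      state$running_var <- v
      state$initialized <- TRUE
    }
  } else {
    if (!state$initialized) {
      msnet_error("UninitializedMoments",
        "inference-mode batch norm requires trained running moments")
    }
    inv_std <- 1 / sqrt(state$running_var + state$epsilon)
    xhat <- sweep(sweep(xm, 2, state$running_mean), 2, inv_std, `*`)
  }
  y <- sweep(sweep(xhat, 2, state$gamma, `*`), 2, state$beta, `+`)
  out <- list(y = y, state = state)
  if (want_cache) out$cache <- list(xhat = xhat, inv_std = inv_std)
  out
}

#' Batch normalization
#'
#' Standardizes each channel over a mini batch (training mode) or with the
#' stored running moments (inference mode), then applies the learnable
#' affine: \eqn{\tilde z = \gamma (z - \alpha) / \sqrt{\sigma^2 + \epsilon} + \beta}
#' where \eqn{\alpha} and \eqn{\sigma^2} are the batch mean and (population)
#' batch variance of the channel. Training mode updates the running moments
#' by exponential moving average.
#'
#' @param x a numeric vector (one channel, length-m batch), an m x C matrix
#'   (rows = batch members), or an H x W x C x N map batch.
#' @param state a [bn_state()] with `channels` matching `x`.
#' @param mode `"train"` or `"inference"`.
#' @return list with `out` (same shape as `x`) and the updated `state`.
#' @export
batch_norm <- function(x, state, mode = c("train", "inference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "bn_state"))
  d <- dim(x)
  if (is.null(d)) {
    res <- bn_core(matrix(x, ncol = 1), state, mode)
    return(list(out = as.vector(res$y), state = res$state))
  }
  if (length(d) == 2) {
    res <- bn_core(x, state, mode)
    return(list(out = res$y, state = res$state))
  }
  if (length(d) == 4) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
    res <- bn_core(xm, state, mode)
    y <- aperm(array(res$y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    return(list(out = y, state = res$state))
  }
  msnet_error("ShapeMismatch", "batch_norm expects a vector, matrix or 4-d map")
}

#' Inverted dropout
#'
#' In training mode each unit is zeroed independently with probability `p`
#' and the survivors are scaled by 1/(1-p), so the expected activation is
#' unchanged and inference is the identity.
#'
#' @param x numeric vector, matrix or array.
#' @param p drop probability in \[0, 1).
#' @param mode `"train"` or `"inference"`.
#' @return same shape as `x`.
#' @export
dropout <- function(x, p = 0.5, mode = c("train", "inference")) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p < 1)
  if (mode == "inference" || p == 0) return(x)
  keep <- (runif(length(x)) >= p) / (1 - p)
  x * array(keep, dim = dim(x) %||% length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic pooling (max or average) over a map
#'
#' Same-padding pooling with the given kernel and stride; each output value
#' is the maximum or the mean of the in-bounds elements of its region
#' (padding positions are excluded from the average denominator).
#'
#' @param x matrix, H x W x C array, or H x W x C x N batch.
#' @param kernel,stride pooling geometry (defaults 3 and 2).
#' @param mode `"max"` or `"average"`.
#' @return pooled map shaped like the input, spatial dims `ceiling(in/stride)`.
#' @export
pool_deterministic <- function(x, kernel = 3, stride = 2,
                               mode = c("max", "average")) {
  mode <- match.arg(mode)
  pool_map(x, kernel, stride, if (mode == "max") 0L else 1L)
}

#' Stochastic pooling over a map
#'
#' In `"sample"` mode (training) each region's output is one of its
#' activations, drawn from the multinomial with probabilities proportional
#' to the activations; in `"expect"` mode (inference) it is the
#' probability-weighted expectation of the region. Activations must be
#' non-negative (apply after ReLU); all-zero regions output 0.
#'
#' @param x matrix, H x W x C array, or H x W x C x N batch (non-negative).
#' @param kernel,stride pooling geometry (defaults 3 and 2).
#' @param variant `"sample"` (consumes R's RNG) or `"expect"`.
#' @return pooled map shaped like the input.
#' @export
stochastic_pool <- function(x, kernel = 3, stride = 2,
                            variant = c("sample", "expect")) {
  variant <- match.arg(variant)
  pool_map(x, kernel, stride, if (variant == "sample") 2L else 3L)
}

pool_map <- function(x, kernel, stride, mode_int) {
  px <- promote4d(x)
  d <- dim(px$x)
  pads_h <- same_pads(d[1], kernel, stride)
  pads_w <- same_pads(d[2], kernel, stride)
  res <- pool2d_forward_cpp(px$x, kernel, stride, pads_h[1], pads_w[1], mode_int)
  demote(res$y, px$ndim)
}

# region-level operators: the unit algebra of stochastic pooling ------------

region_vec <- function(region) {
  # scan order: left to right within a row, rows top to bottom
  v <- if (is.matrix(region)) as.vector(t(region)) else as.numeric(region)
  if (any(v < 0)) {
    msnet_error("NegativeActivation",
      "stochastic pooling requires non-negative activations")
  }
  v
}

#' Multinomial probabilities of a pooling region
#'
#' \eqn{p_i = \chi_i / \sum_k \chi_k} over the region's activations. An
#' all-zero region yields uniform probabilities by convention.
#'
#' @param region non-negative numeric vector or matrix.
#' @return probability vector in scan order (rows top to bottom, left to
#'   right within a row); sums to 1.
#' @export
stochastic_pool_probs <- function(region) {
  v <- region_vec(region)
  s <- sum(v)
  if (s == 0) rep(1 / length(v), length(v)) else v / s
}

#' Sample one activation from a pooling region
#'
#' Draws a location from the multinomial of [stochastic_pool_probs()] and
#' returns the activation there. All-zero regions return 0. Uses R's RNG.
#'
#' @param region non-negative numeric vector or matrix.
#' @return one element of `region` (or 0 for an all-zero region).
#' @export
stochastic_pool_sample <- function(region) {
  v <- region_vec(region)
  s <- sum(v)
  if (s == 0) return(0)
  u <- runif(1) * s
  v[which(cumsum(v) >= u)[1]]
}

#' Expectation of stochastic pooling over a region
#'
#' Probability-weighted mean \eqn{\sum_i p_i \chi_i}; the deterministic
#' inference-time stand-in for sampling. Lies between the region's min and
#' max, and is at least the plain average for non-negative activations.
#'
#' @param region non-negative numeric vector or matrix.
#' @return scalar expectation (0 for an all-zero region).
#' @export
stochastic_pool_expect <- function(region) {
  v <- region_vec(region)
  s <- sum(v)
  if (s == 0) return(0)
  sum(v * v) / s
}

#' Fully-connected layer forward pass
#'
#' `y = W x + b`. `x` may be a vector of length m or an m x N matrix whose
#' columns are batch members.
#'
#' @param x input vector or matrix.
#' @param weights n x m weight matrix.
#' @param bias length-n bias vector (default zeros).
#' @return length-n vector, or n x N matrix for batched input.
#' @export
fc_forward <- function(x, weights, bias = NULL) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (ncol(weights) != nrow(xm)) {
    msnet_error("DimensionMismatch", sprintf(
      "weights expect input of length %d, got %d", ncol(weights), nrow(xm)))
  }
  if (is.null(bias)) bias <- numeric(nrow(weights))
  y <- weights %*% xm + bias
  if (is.matrix(x)) y else as.vector(y)
}

#' Numerically stable softmax
#'
#' Converts scores to a probability distribution; invariant to adding a
#' constant to all scores. For a matrix, each column is treated as one
#' score vector.
#'
#' @param z numeric vector, or matrix with score vectors in columns.
#' @return probabilities of the same shape; each vector/column sums to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    e <- exp(sweep(z, 2, apply(z, 2, max)))
    return(sweep(e, 2, colSums(e), `/`))
  }
  e <- exp(z - max(z))
  e / sum(e)
}
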