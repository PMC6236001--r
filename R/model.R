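# layer spec constructors (internal): a config is an ordered list of these
layer_conv <- function(in_ch, out_ch, kernel = 3, stride = 1,
                       padding = "same", batch_norm = TRUE, name = "conv") {
  list(type = "conv", kernel = kernel, in_ch = in_ch, out_ch = out_ch,
       stride = stride, padding = padding, batch_norm = batch_norm, name = name)
}
layer_pool <- function(kernel = 3, stride = 2, name = "pool") {
  list(type = "pool", kernel = kernel, stride = stride, name = name)
}
layer_fc <- function(out_dim, name = "fc") {
  list(type = "fc", out_dim = out_dim, name = name)
}
layer_dropout <- function(p = 0.5, name = "dropout") {
  list(type = "dropout", p = p, name = name)
}

make_config <- function(layers, input_side, pooling_mode, input_channels = 1) {
  structure(
    list(input_side = as.integer(input_side),
         input_channels = as.integer(input_channels),
         pooling_mode = pooling_mode,
         layers = layers),
    class = "msnet_config"
  )
}

#' The 14-layer architecture
#'
#' Builds the reference configuration: 11 convolutional layers and 3
#' fully-connected layers (pooling, batch-norm, dropout and softmax are
#' uncounted sublayers, by the usual counting convention). All kernels are
#' 3x3 with "same" padding; the channel widths grow 8-8-16-16-16-32-32-32-
#' 64-64-64; four pooling stages (kernel 3, stride 2) plus the two stride-2
#' convolutions reduce a 256x256 input to 4x4x64 = 1024 flattened features,
#' followed by fully-connected layers of 20, 10 and 2 units with dropout 0.5
#' after the first two and a softmax output.
#'
#' @param pooling_mode `"stochastic"` (default), `"max"` or `"average"`.
#' @param input_side input image side in pixels (default 256).
#' @param batch_norm attach batch normalization to every conv layer.
#' @return an object of class `msnet_config`.
#' @export
default_config <- function(pooling_mode = c("stochastic", "max", "average"),
                           input_side = 256, batch_norm = TRUE) {
  pooling_mode <- match.arg(pooling_mode)
  widths <- list(
    c(1, 8, 2), c(8, 8, 2), c(8, 16, 1), c(16, 16, 1), c(16, 16, 1),
    c(16, 32, 1), c(32, 32, 1), c(32, 32, 1),
    c(32, 64, 1), c(64, 64, 1), c(64, 64, 1)
  )
  conv <- function(i) layer_conv(widths[[i]][1], widths[[i]][2],
                                 stride = widths[[i]][3],
                                 batch_norm = batch_norm,
                                 name = paste0("conv_", i))
  layers <- list(
    conv(1), layer_pool(name = "pool_1"),
    conv(2), layer_pool(name = "pool_2"),
    conv(3), conv(4), conv(5), layer_pool(name = "pool_3"),
    conv(6), conv(7), conv(8), conv(9), conv(10), conv(11),
    layer_pool(name = "pool_4"),
    list(type = "flatten", name = "flatten"),
    layer_fc(20, "fc_1"), layer_dropout(0.5, "do_1"),
    layer_fc(10, "fc_2"), layer_dropout(0.5, "do_2"),
    layer_fc(2, "fc_3"),
    list(type = "softmax", name = "softmax")
  )
  make_config(layers, input_side, pooling_mode)
}

#' A reduced variant architecture for small images
#'
#' Two stride-2 conv layers with pooling after each, then one hidden
#' fully-connected layer; useful for experiments on small synthetic images
#' (e.g. 64x64 or 32x32) where the full 14-layer network is oversized.
#'
#' @param pooling_mode `"stochastic"`, `"max"` or `"average"`.
#' @param input_side input image side in pixels.
#' @param widths channel widths of the two conv layers.
#' @param fc_dim hidden fully-connected width.
#' @param dropout_p dropout probability after the hidden layer (0 disables).
#' @param batch_norm attach batch normalization to the conv layers.
#' @return an object of class `msnet_config`.
#' @export
small_config <- function(pooling_mode = c("stochastic", "max", "average"),
                         input_side = 64, widths = c(8, 16), fc_dim = 16,
                         dropout_p = 0.5, batch_norm = TRUE) {
  pooling_mode <- match.arg(pooling_mode)
  layers <- list(
    layer_conv(1, widths[1], stride = 2, batch_norm = batch_norm, name = "conv_1"),
    layer_pool(name = "pool_1"),
    layer_conv(widths[1], widths[2], stride = 2, batch_norm = batch_norm,
               name = "conv_2"),
    layer_pool(name = "pool_2"),
    list(type = "flatten", name = "flatten"),
    layer_fc(fc_dim, "fc_1")
  )
  if (dropout_p > 0) layers <- c(layers, list(layer_dropout(dropout_p, "do_1")))
  layers <- c(layers, list(layer_fc(2, "fc_2"), list(type = "softmax", name = "softmax")))
  make_config(layers, input_side, pooling_mode)
}

#' Per-layer output shapes of an architecture
#'
#' Propagates the input shape through every layer with the convolution /
#' pooling shape arithmetic ("same" padding: `ceiling(in/stride)`), checking
#' that each conv layer's input channels match the running channel count.
#' The flatten row carries the flattened feature dimension that the first
#' fully-connected layer consumes.
#'
#' @param config an `msnet_config`.
#' @return data frame with columns `layer`, `height`, `width`, `channels`;
#'   the flatten/fc rows store the vector length in `channels` with
#'   height = width = 1. Attribute `flatten_dim` holds the flattened length.
#' @export
shape_trace <- function(config) {
  stopifnot(inherits(config, "msnet_config"))
  h <- config$input_side
  w <- config$input_side
  ch <- config$input_channels
  rows <- list(list(layer = "input", height = h, width = w, channels = ch))
  flatten_dim <- NA_integer_
  for (ly in config$layers) {
    if (ly$type == "conv") {
      if (ly$in_ch != ch) {
        msnet_error("InconsistentChaining", sprintf(
          "%s expects %d input channels but receives %d", ly$name, ly$in_ch, ch))
      }
      h <- conv_out_shape(h, ly$kernel, ly$stride, ly$padding)
      w <- conv_out_shape(w, ly$kernel, ly$stride, ly$padding)
      ch <- ly$out_ch
    } else if (ly$type == "pool") {
      h <- conv_out_shape(h, ly$kernel, ly$stride, "same")
      w <- conv_out_shape(w, ly$kernel, ly$stride, "same")
    } else if (ly$type == "flatten") {
      flatten_dim <- h * w * ch
      h <- 1; w <- 1; ch <- flatten_dim
    } else if (ly$type == "fc") {
      h <- 1; w <- 1; ch <- ly$out_dim
    }
    if (ly$type %in% c("conv", "pool", "flatten", "fc")) {
      rows[[length(rows) + 1]] <- list(layer = ly$name, height = h, width = w,
                                       channels = ch)
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  attr(out, "flatten_dim") <- flatten_dim
  out
}

#' Instantiate a network with seeded random initialization
#'
#' Convolution filters and fully-connected weights are drawn from zero-mean
#' Gaussians with He scaling (sd = sqrt(2 / fan-in), the standard choice for
#' ReLU networks); biases start at zero and batch-norm states at
#' gamma = 1, beta = 0. The same seed always produces identical parameters.
#'
#' @param config an `msnet_config`.
#' @param seed integer initialization seed.
#' @return an object of class `msnet_network`.
#' @export
build_network <- function(config, seed = 1L) {
  trace <- shape_trace(config)  # validates chaining before any allocation
  fc_in <- NA_integer_
  # walk the trace to learn each fc layer's input dimension
  dims <- trace$channels * trace$height * trace$width
  params <- vector("list", length(config$layers))
  withr::with_seed(seed, {
    cur <- 1L
    for (i in seq_along(config$layers)) {
      ly <- config$layers[[i]]
      if (ly$type == "conv") {
        fan_in <- ly$kernel * ly$kernel * ly$in_ch
        w <- array(rnorm(ly$kernel * ly$kernel * ly$in_ch * ly$out_ch,
                         sd = sqrt(2 / fan_in)),
                   c(ly$kernel, ly$kernel, ly$in_ch, ly$out_ch))
        bn <- NULL
        if (isTRUE(ly$batch_norm)) {
          bn <- bn_state(ly$out_ch)
          # start from the framework-default running moments (mean 0, var 1)
          # so an untrained network can already run in inference mode
          bn$initialized <- TRUE
        }
        params[[i]] <- list(w = w, b = numeric(ly$out_ch), bn = bn)
      } else if (ly$type == "fc") {
        in_dim <- dims[cur]
        w <- matrix(rnorm(ly$out_dim * in_dim, sd = sqrt(2 / in_dim)),
                    ly$out_dim, in_dim)
        params[[i]] <- list(w = w, b = numeric(ly$out_dim))
      }
      if (ly$type %in% c("conv", "pool", "flatten", "fc")) cur <- cur + 1L
    }
  })
  structure(
    list(config = config, params = params),
    class = "msnet_network"
  )
}

#' @export
print.msnet_network <- function(x, ...) {
  tr <- shape_trace(x$config)
  cat(sprintf("<msnet_network> %s pooling, input %dx%dx%d, %d parameters\n",
              x$config$pooling_mode, x$config$input_side, x$config$input_side,
              x$config$input_channels, parameter_count(x)))
  print(tr, row.names = FALSE)
  invisible(x)
}

#' Total number of learnable parameters
#' @param network an `msnet_network`.
#' @return integer count of weights, biases and batch-norm scale/offset pairs.
#' @export
parameter_count <- function(network) {
  n <- 0
  for (p in network$params) {
    if (is.null(p)) next
    n <- n + length(p$w) + length(p$b)
    if (!is.null(p$bn)) n <- n + length(p$bn$gamma) + length(p$bn$beta)
  }
  as.integer(n)
}

# stack a list of matrices (or an image_dataset) into an H x W x 1 x N batch
as_image_batch <- function(images) {
  if (inherits(images, "image_dataset")) images <- images$images
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4) return(images)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), c(h, w, 1, length(images)))
}

pool_mode_int <- function(pooling_mode, phase) {
  switch(pooling_mode,
    max = 0L,
    average = 1L,
    stochastic = if (phase == "train") 2L else 3L
  )
}

# full forward pass; when want_cache = TRUE also returns everything the
# backward pass needs and (train mode) the updated batch-norm states
forward_pass <- function(net, x, phase, want_cache = FALSE) {
  config <- net$config
  caches <- if (want_cache) vector("list", length(config$layers))
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    p <- net$params[[i]]
    if (ly$type == "conv") {
      d <- dim(x)
      pads <- conv_pads(d[1], d[2], ly$kernel, ly$stride, ly$padding)
      y <- conv2d_forward_cpp(x, p$w, p$b, ly$stride,
                              pads[1], pads[2], pads[3], pads[4])
      if (want_cache) caches[[i]] <- list(x = x, pads = pads)
      x <- y
      if (!is.null(p$bn)) {
        d <- dim(x)
        xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
        res <- bn_core(xm, p$bn, phase, want_cache = want_cache)
        if (phase == "train") net$params[[i]]$bn <- res$state
        x <- aperm(array(res$y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
        if (want_cache) caches[[i]]$bn <- c(res$cache, list(dims = d))
      }
      mask <- x > 0
      x[!mask] <- 0
      if (want_cache) caches[[i]]$relu_mask <- mask
    } else if (ly$type == "pool") {
      d <- dim(x)
      ph <- same_pads(d[1], ly$kernel, ly$stride)
      pw <- same_pads(d[2], ly$kernel, ly$stride)
      mode_int <- pool_mode_int(config$pooling_mode, phase)
      res <- pool2d_forward_cpp(x, ly$kernel, ly$stride, ph[1], pw[1], mode_int)
      if (want_cache) {
        caches[[i]] <- list(xdim = d, idx = res$idx, pads = c(ph[1], pw[1]),
                            mode_int = mode_int, kernel = ly$kernel,
                            stride = ly$stride)
      }
      x <- res$y
    } else if (ly$type == "flatten") {
      d <- dim(x)
      if (want_cache) caches[[i]] <- list(dims = d)
      x <- matrix(x, prod(d[1:3]), d[4])
    } else if (ly$type == "fc") {
      if (want_cache) caches[[i]] <- list(x = x)
      x <- p$w %*% x + p$b
    } else if (ly$type == "dropout") {
      if (phase == "train" && ly$p > 0) {
        keep <- matrix((runif(length(x)) >= ly$p) / (1 - ly$p),
                       nrow(x), ncol(x))
        if (want_cache) caches[[i]] <- list(mask = keep)
        x <- x * keep
      }
    } else if (ly$type == "softmax") {
      x <- softmax(x)
    }
  }
  list(probs = x, caches = caches, net = net)
}

# backward pass from d(loss)/d(logits); returns gradients parallel to params
backward_pass <- function(net, caches, dlogits) {
  config <- net$config
  grads <- vector("list", length(config$layers))
  dz <- dlogits
  for (i in rev(seq_along(config$layers))) {
    ly <- config$layers[[i]]
    p <- net$params[[i]]
    cc <- caches[[i]]
    if (ly$type == "softmax") {
      next  # folded into dlogits by the cross-entropy derivative
    } else if (ly$type == "fc") {
      grads[[i]] <- list(w = dz %*% t(cc$x), b = rowSums(dz))
      dz <- t(p$w) %*% dz
    } else if (ly$type == "dropout") {
      if (!is.null(cc)) dz <- dz * cc$mask
    } else if (ly$type == "flatten") {
      dz <- array(dz, cc$dims)
    } else if (ly$type == "pool") {
      dz <- pool2d_backward_cpp(dz, cc$xdim, cc$idx, cc$kernel, cc$stride,
                                cc$pads[1], cc$pads[2], cc$mode_int)
    } else if (ly$type == "conv") {
      dz <- dz * cc$relu_mask
      if (!is.null(p$bn)) {
        d <- cc$bn$dims
        dym <- matrix(aperm(dz, c(1, 2, 4, 3)), ncol = d[3])
        xhat <- cc$bn$xhat
        dgamma <- colSums(dym * xhat)
        dbeta <- colSums(dym)
        m <- nrow(dym)
        tmp <- sweep(dym, 2, dbeta / m) - sweep(xhat, 2, dgamma / m, `*`)
        dxm <- sweep(tmp, 2, p$bn$gamma * cc$bn$inv_std, `*`)
        dz <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
        grads[[i]] <- list(bn_gamma = dgamma, bn_beta = dbeta)
      }
      gb <- conv2d_backward_cpp(cc$x, p$w, dz, ly$stride, cc$pads[1], cc$pads[3])
      grads[[i]] <- c(grads[[i]], list(w = gb$dw, b = as.vector(gb$db)))
      dz <- gb$dx
    }
  }
  grads
}

#' Forward pass: class probabilities for a batch of images
#'
#' In inference mode the pass is fully deterministic: dropout is the
#' identity, batch normalization uses the stored running moments, and
#' stochastic pooling returns its probability-weighted expectation. In
#' training mode dropout masks and stochastic-pooling samples are drawn
#' from R's RNG and batch normalization uses the batch moments (note that a
#' training-mode call updates the network's running moments; this function
#' discards that update — it is applied only inside [train_network()]).
#'
#' @param network an `msnet_network`.
#' @param images an [image_dataset()], a list of matrices, a single matrix,
#'   or an H x W x 1 x N array, matching the configured input size.
#' @param mode `"inference"` (default) or `"train"`.
#' @return N x 2 matrix of class probabilities with columns `MS`, `HC`;
#'   rows sum to 1.
#' @export
net_forward <- function(network, images, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  x <- as_image_batch(images)
  if (dim(x)[1] != network$config$input_side ||
      dim(x)[2] != network$config$input_side) {
    msnet_error("ShapeMismatch", sprintf(
      "network expects %dx%d input, got %dx%d", network$config$input_side,
      network$config$input_side, dim(x)[1], dim(x)[2]))
  }
  probs <- t(forward_pass(network, x, mode)$probs)
  colnames(probs) <- c("MS", "HC")
  probs
}

#' Read an architecture from a YAML description
#'
#' The package ships its reference architecture as
#' `system.file("arch", "msnet14.yaml", package = "msnet")`; the format is a
#' list of layer entries (`conv`, `pool`, `flatten`, `fc`, `dropout`,
#' `softmax`) plus the input geometry and pooling mode.
#'
#' @param path YAML file path.
#' @return an `msnet_config`.
#' @export
read_arch_config <- function(path) {
  spec <- yaml::read_yaml(path)
  layers <- lapply(spec$layers, function(e) {
    switch(e$type,
      conv = layer_conv(e$in_channels, e$out_channels,
                        kernel = e$kernel %||% 3, stride = e$stride %||% 1,
                        batch_norm = e$batch_norm %||% TRUE,
                        name = e$name %||% "conv"),
      pool = layer_pool(kernel = e$kernel %||% 3, stride = e$stride %||% 2,
                        name = e$name %||% "pool"),
      flatten = list(type = "flatten", name = e$name %||% "flatten"),
      fc = layer_fc(e$out_dim, e$name %||% "fc"),
      dropout = layer_dropout(e$p %||% 0.5, e$name %||% "dropout"),
      softmax = list(type = "softmax", name = "softmax"),
      msnet_error("UnknownLayer", paste("unknown layer type:", e$type))
    )
  })
  make_config(layers, spec$input$side, spec$pooling %||% "stochastic",
              spec$input$channels %||% 1)
}

#' Print the shape trace of an architecture
#' @param config an `msnet_config`.
#' @return the shape-trace data frame, invisibly.
#' @export
describe_arch <- function(config) {
  tr <- shape_trace(config)
  cat(sprintf("pooling mode: %s\n", config$pooling_mode))
  print(tr, row.names = FALSE)
  cat(sprintf("flattened features: %d\n", attr(tr, "flatten_dim")))
  invisible(tr)
}
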