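#' Training configuration
#'
#' Mini-batch SGD with momentum and a step-decay learning-rate schedule:
#' start large and cut by `lr_drop_factor` every `lr_drop_period` epochs.
#'
#' @param initial_lr initial learning rate (> 0).
#' @param lr_drop_factor multiplicative decay in (0, 1).
#' @param lr_drop_period epochs between decays.
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size (>= 2; batch normalization needs more
#'   than one sample, and a trailing batch of one image is dropped).
#' @param momentum SGD momentum coefficient.
#' @param seed integer seed governing shuffling, dropout masks and
#'   stochastic-pooling draws.
#' @return an object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, lr_drop_factor = 0.1,
                         lr_drop_period = 10, epochs = 30, batch_size = 128,
                         momentum = 0.9, seed = 1L) {
  stopifnot(initial_lr > 0, lr_drop_factor > 0, lr_drop_factor < 1,
            lr_drop_period >= 1, epochs >= 1, batch_size >= 2,
            momentum >= 0, momentum < 1)
  structure(
    list(initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
         lr_drop_period = as.integer(lr_drop_period),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         momentum = momentum, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a given epoch under step decay
#'
#' @param epoch zero-based epoch index.
#' @param config a [train_config()].
#' @return `initial_lr * lr_drop_factor^floor(epoch / lr_drop_period)`.
#' @export
lr_at <- function(epoch, config) {
  stopifnot(epoch >= 0)
  config$initial_lr * config$lr_drop_factor^(epoch %/% config$lr_drop_period)
}

# apply one SGD-with-momentum update in place; velocities live on the network
sgd_update <- function(net, grads, velocity, lr, momentum) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (is.null(velocity[[i]])) velocity[[i]] <- lapply(g, function(x) x * 0)
    for (nm in names(g)) {
      velocity[[i]][[nm]] <- momentum * velocity[[i]][[nm]] + g[[nm]]
      upd <- lr * velocity[[i]][[nm]]
      if (nm == "w") {
        net$params[[i]]$w <- net$params[[i]]$w - upd
      } else if (nm == "b") {
        net$params[[i]]$b <- net$params[[i]]$b - upd
      } else if (nm == "bn_gamma") {
        net$params[[i]]$bn$gamma <- net$params[[i]]$bn$gamma - upd
      } else if (nm == "bn_beta") {
        net$params[[i]]$bn$beta <- net$params[[i]]$bn$beta - upd
      }
    }
  }
  list(net = net, velocity = velocity)
}

#' Train a network by mini-batch SGD with cross-entropy loss
#'
#' Shuffles each epoch, runs the forward pass in training mode (batch-norm
#' batch statistics with running-moment updates, dropout active, stochastic
#' pooling sampling) and backpropagates the softmax cross-entropy. The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param network an `msnet_network` (freshly built or partially trained).
#' @param train_set an [image_dataset()] containing both classes.
#' @param config a [train_config()].
#' @return list with `network` (trained) and `loss_trace` (mean cross-entropy
#'   per epoch).
#' @export
train_network <- function(network, train_set, config = train_config()) {
  stopifnot(inherits(train_set, "image_dataset"), inherits(config, "train_config"))
  n <- length(train_set)
  if (n == 0) msnet_error("EmptyTrainingSet", "training set is empty")
  cnt <- class_counts(train_set)
  if (any(cnt == 0)) {
    msnet_error("SingleClassTrainingSet", "training set must contain both classes")
  }
  x_all <- as_image_batch(train_set)
  if (dim(x_all)[1] != network$config$input_side) {
    msnet_error("ShapeMismatch", "training images do not match the network input size")
  }
  # one-hot targets, class order (MS, HC)
  y_all <- rbind(MS = as.numeric(train_set$label == "MS"),
                 HC = as.numeric(train_set$label == "HC"))
  loss_trace <- numeric(config$epochs)
  velocity <- vector("list", length(network$params))
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at(epoch, config)
      perm <- sample(n)
      losses <- c()
      weights <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        take <- perm[start:min(start + config$batch_size - 1L, n)]
        if (length(take) < 2) next  # batch norm needs m >= 2
        xb <- x_all[, , , take, drop = FALSE]
        yb <- y_all[, take, drop = FALSE]
        fw <- forward_pass(network, xb, "train", want_cache = TRUE)
        network <- fw$net  # batch-norm running moments
        probs <- fw$probs
        losses <- c(losses, -mean(log(pmax(colSums(probs * yb), 1e-12))))
        weights <- c(weights, length(take))
        dlogits <- (probs - yb) / length(take)
        grads <- backward_pass(network, fw$caches, dlogits)
        st <- sgd_update(network, grads, velocity, lr, config$momentum)
        network <- st$net
        velocity <- st$velocity
      }
      loss_trace[epoch + 1L] <- sum(losses * weights) / sum(weights)
    }
  })
  list(network = network, loss_trace = loss_trace)
}

#' Confusion matrix of a classifier on a labeled test set
#'
#' Runs a deterministic inference-mode forward pass, predicts the class with
#' the larger probability, and tabulates against the truth with MS as the
#' positive class.
#'
#' @param network an `msnet_network`.
#' @param test_set an [image_dataset()].
#' @param batch_size evaluation batch size (memory knob only).
#' @return an object of class `confusion_matrix` with fields TP, FP, TN, FN.
#' @export
evaluate_network <- function(network, test_set, batch_size = 128) {
  stopifnot(inherits(test_set, "image_dataset"))
  n <- length(test_set)
  if (n == 0) msnet_error("EmptyTestSet", "test set is empty")
  pred <- character(n)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    probs <- net_forward(network, dataset_subset(test_set, take), "inference")
    pred[take] <- ifelse(probs[, "MS"] >= probs[, "HC"], "MS", "HC")
  }
  truth <- as.character(test_set$label)
  confusion_matrix(
    TP = sum(pred == "MS" & truth == "MS"),
    FP = sum(pred == "MS" & truth == "HC"),
    TN = sum(pred == "HC" & truth == "HC"),
    FN = sum(pred == "HC" & truth == "MS")
  )
}

#' Construct a confusion matrix (MS = positive class)
#' @param TP,FP,TN,FN non-negative counts.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
              dimnames = list(truth = c("MS", "HC"), predicted = c("MS", "HC")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity, precision and accuracy (percent)
#'
#' sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP),
#' precision = 100 TP/(TP+FP), accuracy = 100 (TP+TN)/total, with MS as the
#' positive class. Values are returned at full precision; round only for
#' display.
#'
#' @param cm a [confusion_matrix()].
#' @return one-row data frame with the four metrics.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0 || cm$TP + cm$FP == 0) {
    msnet_error("UndefinedMetric", "a metric denominator is zero")
  }
  metrics_row(cm)
}

# metric arithmetic without the denominator guard; undefined entries are NA
metrics_row <- function(cm) {
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  data.frame(
    sensitivity = div(cm$TP, cm$TP + cm$FN),
    specificity = div(cm$TN, cm$TN + cm$FP),
    precision = div(cm$TP, cm$TP + cm$FP),
    accuracy = div(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN)
  )
}

#' Mean and sample standard deviation of per-run metrics
#'
#' @param rows data frame of per-run metrics (one column per metric).
#' @param digits rounding applied for display (default 2); the underlying
#'   statistics are computed at full precision.
#' @return data frame with columns `metric`, `mean`, `sd` (sample SD,
#'   n-1 denominator; 0 for a single run) and `display` (`"mean ± sd"`).
#' @export
summarize_runs <- function(rows, digits = 2) {
  rows <- rows[, intersect(c("sensitivity", "specificity", "precision",
                             "accuracy"), names(rows)), drop = FALSE]
  stopifnot(nrow(rows) >= 1)
  mu <- vapply(rows, mean, numeric(1), na.rm = TRUE)
  sdv <- if (nrow(rows) > 1) {
    vapply(rows, sd, numeric(1), na.rm = TRUE)
  } else {
    rep(0, ncol(rows))
  }
  data.frame(
    metric = names(rows),
    mean = mu,
    sd = sdv,
    display = sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                      round(mu, digits), round(sdv, digits)),
    row.names = NULL
  )
}

#' Repeated hold-out experiment
#'
#' Runs the complete published protocol `n_runs` times: re-draw the
#' hold-out split with a fresh derived seed, optionally augment the
#' training branch (never the test branch), build a freshly initialized
#' network, train it, and evaluate on the held-out test set. Per-run seeds
#' are derived deterministically from `seed`, so results are reproducible
#' while every run uses a distinct split and initialization.
#'
#' @param dataset an [image_dataset()] with both classes.
#' @param arch_config an `msnet_config`.
#' @param tr_config a [train_config()].
#' @param train_ms,train_hc,test_ms,test_hc per-class hold-out counts.
#' @param augment an [augment_config()] to expand each training branch, or
#'   NULL for no augmentation.
#' @param n_runs number of repetitions (>= 1).
#' @param seed master seed.
#' @return a `run_table`: data frame with one metrics row per run; the
#'   summary of [summarize_runs()] is attached as attribute `"summary"`.
#' @export
multirun <- function(dataset, arch_config, tr_config,
                     train_ms, train_hc, test_ms, test_hc,
                     augment = NULL, n_runs = 10, seed = 1L) {
  stopifnot(n_runs >= 1)
  run_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 3 * n_runs), ncol = 3))
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    split <- holdout_split(dataset, train_ms, train_hc, test_ms, test_hc,
                           seed = run_seeds[r, 1])
    train_branch <- split$train
    if (!is.null(augment)) {
      aug <- augment
      aug$seed <- run_seeds[r, 2]
      train_branch <- augment_training_set(train_branch, aug)
    }
    net <- build_network(arch_config, seed = run_seeds[r, 3])
    cfg <- tr_config
    cfg$seed <- run_seeds[r, 2]
    fit <- train_network(net, train_branch, cfg)
    cm <- evaluate_network(fit$network, split$test)
    # a degenerate run (single-class predictor) leaves precision undefined;
    # record NA rather than aborting the experiment
    rows[[r]] <- cbind(run = r, metrics_row(cm))
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_runs(out)
  class(out) <- c("run_table", class(out))
  out
}

#' Per-run benchmark metrics reported for the three pooling variants
#'
#' The ten hold-out runs previously reported for this 14-layer architecture
#' on the clinical MS/HC slice dataset, for stochastic (SP), max (MP) and
#' average (AP) pooling. Shipped as plain text in `inst/extdata`; used as
#' reference input for the exact signed-rank comparison of pooling variants
#' and for validating the summary statistics.
#'
#' @return data frame with columns `pooling` ("SP", "MP", "AP"), `run`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy` (percent).
#' @export
reference_pooling_runs <- function() {
  path <- system.file("extdata", "pooling_runs.csv", package = "msnet")
  read.csv(path, stringsAsFactors = FALSE)
}
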