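test_that("step-decay schedule drops the rate by the factor each period", {
  config <- train_config(initial_lr = 0.01, lr_drop_factor = 0.1,
                         lr_drop_period = 10)
  expect_equal(lr_at(0, config), 0.01)
  expect_equal(lr_at(9, config), 0.01)
  expect_equal(lr_at(10, config), 0.001)
  expect_equal(lr_at(25, config), 0.0001)
  rates <- vapply(0:40, lr_at, 1, config = config)
  expect_true(all(diff(rates) <= 0))
})

test_that("confusion metrics reproduce the benchmark run-1 row and edge cases", {
  # run-1 rates 98.77 / 98.19 on class sizes 326 / 331 imply these counts
  m <- compute_metrics(confusion_matrix(TP = 322, FN = 4, TN = 325, FP = 6))
  expect_equal(round(m$sensitivity, 2), 98.77)
  expect_equal(round(m$specificity, 2), 98.19)
  expect_equal(round(m$precision, 2), 98.17)
  expect_equal(round(m$accuracy, 2), 98.48)

  sym <- compute_metrics(confusion_matrix(5, 5, 5, 5))
  expect_equal(sym$accuracy, 50)
  perfect <- compute_metrics(confusion_matrix(10, 0, 12, 0))
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  precision = 100, accuracy = 100))
  expect_error(compute_metrics(confusion_matrix(0, 0, 5, 0)),
               class = "UndefinedMetric")
})

test_that("accuracy lies between sensitivity and specificity", {
  set.seed(17)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(1:50, 1), sample(0:50, 1),
                           sample(1:50, 1), sample(0:50, 1))
    m <- metrics <- compute_metrics(cm)
    expect_gte(m$accuracy, min(m$sensitivity, m$specificity) - 1e-9)
    expect_lte(m$accuracy, max(m$sensitivity, m$specificity) + 1e-9)
  }
})

test_that("evaluation tabulates predictions against truth with MS positive", {
  ds <- small_study(n = 6, side = 16)
  config <- small_config("max", input_side = 16, widths = c(3, 4), fc_dim = 4)
  net <- build_network(config, seed = 3)
  cm <- evaluate_network(net, ds)
  expect_equal(cm$TP + cm$FN, 6)  # MS row
  expect_equal(cm$TN + cm$FP, 6)  # HC row
  expect_error(evaluate_network(net, image_dataset(list(), character())),
               class = "EmptyTestSet")
})

test_that("training reduces the loss, is seed-reproducible and rejects bad input", {
  ds <- small_study(n = 30)
  config <- micro_config("stochastic")
  net <- build_network(config, seed = 2)
  tc <- train_config(epochs = 3, batch_size = 16, seed = 5)
  fit <- train_network(net, ds, tc)
  expect_length(fit$loss_trace, 3)
  expect_lt(fit$loss_trace[3], fit$loss_trace[1])

  fit2 <- train_network(build_network(config, seed = 2), ds, tc)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_identical(fit$network$params, fit2$network$params)

  one_class <- image_dataset(lapply(1:4, function(i) smooth_image(32)),
                             rep("MS", 4))
  expect_error(train_network(net, one_class, tc),
               class = "SingleClassTrainingSet")
  expect_error(train_network(net, image_dataset(list(), character()), tc),
               class = "EmptyTrainingSet")
})

test_that("run summaries report mean and sample standard deviation", {
  runs <- reference_pooling_runs()
  sp <- runs[runs$pooling == "SP", ]
  s <- summarize_runs(sp)
  acc <- s[s$metric == "accuracy", ]
  expect_equal(round(acc$mean, 2), 98.77)
  expect_equal(round(acc$sd, 2), 0.39)
  sens <- s[s$metric == "sensitivity", ]
  expect_equal(round(sens$mean, 2), 98.77)
  expect_equal(round(sens$sd, 2), 0.35)

  same <- data.frame(accuracy = rep(97.5, 4))
  expect_equal(summarize_runs(same)$sd, 0)
  single <- data.frame(accuracy = 99)
  expect_equal(summarize_runs(single)$sd, 0)
})

test_that("multirun re-splits per run and returns one metrics row per run", {
  ds <- small_study(n = 40)
  tab <- multirun(ds, micro_config("max"),
                  train_config(epochs = 2, batch_size = 16),
                  train_ms = 20, train_hc = 20, test_ms = 20, test_hc = 20,
                  n_runs = 3, seed = 9)
  expect_s3_class(tab, "run_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$run, 1:3)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100, na.rm = TRUE))
  expect_s3_class(attr(tab, "summary"), "data.frame")
  # reproducible under the master seed
  tab2 <- multirun(ds, micro_config("max"),
                   train_config(epochs = 2, batch_size = 16),
                   20, 20, 20, 20, n_runs = 3, seed = 9)
  expect_equal(tab$accuracy, tab2$accuracy)
})
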