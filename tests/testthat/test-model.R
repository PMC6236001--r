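test_that("the default architecture matches the published layer tables", {
  config <- default_config("stochastic")
  types <- vapply(config$layers, `[[`, "", "type")
  expect_equal(sum(types == "conv"), 11)
  expect_equal(sum(types == "fc"), 3)
  expect_equal(sum(types == "pool"), 4)
  expect_equal(sum(types == "dropout"), 2)
  fc_dims <- vapply(config$layers[types == "fc"], `[[`, 1, "out_dim")
  expect_equal(fc_dims, c(20, 10, 2))

  tr <- shape_trace(config)
  expect_equal(attr(tr, "flatten_dim"), 1024)
  conv_pool <- tr[grepl("^(conv|pool)", tr$layer), ]
  expect_equal(unique(conv_pool$height),
               c(128, 64, 32, 16, 8, 4))  # the six stride-2 stages
  expect_true(all(diff(tr$height) <= 0))
})

test_that("shape trace handles reduced inputs and rejects broken chains", {
  tr64 <- shape_trace(default_config("max", input_side = 64))
  expect_equal(attr(tr64, "flatten_dim"), 64)  # 1x1x64 endpoint
  final_pool <- tr64[tr64$layer == "pool_4", ]
  expect_equal(c(final_pool$height, final_pool$width, final_pool$channels),
               c(1, 1, 64))

  broken <- default_config("max")
  broken$layers[[3]]$in_ch <- 4
  expect_error(shape_trace(broken), class = "InconsistentChaining")
  expect_error(build_network(broken), class = "InconsistentChaining")

  # stride-1-only toy config keeps the spatial side
  toy <- small_config("max", input_side = 16)
  toy$layers <- list(toy$layers[[1]])
  toy$layers[[1]]$stride <- 1
  expect_equal(shape_trace(toy)$height, c(16, 16))
})

test_that("network building is seed-deterministic with the documented shapes", {
  config <- default_config("stochastic")
  n1 <- build_network(config, seed = 5)
  n2 <- build_network(config, seed = 5)
  expect_identical(n1$params, n2$params)
  n3 <- build_network(config, seed = 6)
  expect_false(identical(n1$params, n3$params))

  fc1 <- which(vapply(config$layers, `[[`, "", "type") == "fc")[1]
  expect_equal(dim(n1$params[[fc1]]$w), c(20, 1024))
  expect_equal(dim(n1$params[[1]]$w), c(3, 3, 1, 8))
  expect_equal(n1$params[[1]]$bn$gamma, rep(1, 8))
  expect_equal(n1$params[[1]]$bn$beta, rep(0, 8))
})

test_that("the default architecture has the frozen parameter count", {
  # regression constant, computed once from the layer tables:
  # conv 121,960 + batch-norm 704 + fully-connected 20,732
  expect_equal(parameter_count(build_network(default_config("max"), 1)), 143396L)
})

test_that("forward pass emits probability rows and is deterministic in inference", {
  config <- small_config("stochastic", input_side = 16, widths = c(3, 4),
                         fc_dim = 4)
  net <- build_network(config, seed = 9)
  imgs <- lapply(1:5, function(i) smooth_image(16))
  p1 <- net_forward(net, imgs)
  expect_equal(dim(p1), c(5, 2))
  expect_equal(unname(rowSums(p1)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p1 > 0))
  p2 <- net_forward(net, imgs)
  expect_identical(p1, p2)
  expect_error(net_forward(net, smooth_image(8)), class = "ShapeMismatch")
})

test_that("only stochastic pooling and dropout make training-mode forward stochastic", {
  imgs <- lapply(1:4, function(i) smooth_image(16))
  det <- small_config("max", input_side = 16, widths = c(3, 4), fc_dim = 4,
                      dropout_p = 0, batch_norm = FALSE)
  net <- build_network(det, seed = 1)
  set.seed(1); a <- net_forward(net, imgs, "train")
  set.seed(2); b <- net_forward(net, imgs, "train")
  expect_identical(a, b)
  # without batch norm there is no train/inference distinction left at all
  expect_equal(a, net_forward(net, imgs, "inference"))

  sto <- small_config("stochastic", input_side = 16, widths = c(3, 4),
                      fc_dim = 4, dropout_p = 0, batch_norm = FALSE)
  snet <- build_network(sto, seed = 1)
  set.seed(1); s1 <- net_forward(snet, imgs, "train")
  set.seed(2); s2 <- net_forward(snet, imgs, "train")
  expect_false(identical(s1, s2))
})

test_that("the YAML architecture file reproduces the built-in default", {
  path <- system.file("arch", "msnet14.yaml", package = "msnet")
  config <- read_arch_config(path)
  expect_equal(shape_trace(config), shape_trace(default_config("stochastic")))
  expect_equal(attr(shape_trace(config), "flatten_dim"), 1024)
  out <- capture.output(describe_arch(config))
  expect_true(any(grepl("flattened features: 1024", out)))
})
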