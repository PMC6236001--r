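test_that("convolution shape arithmetic follows the floor/ceil formulas", {
  expect_equal(conv_out_shape(5, 3, 1, 0), 3L)
  expect_equal(conv_out_shape(5, 3, 1, 1), 5L)
  expect_equal(conv_out_shape(256, 3, 2, "same"), 128L)
  expect_equal(conv_out_shape(7, 3, 2, "same"), 4L)
  expect_equal(conv_out_shape(c(256, 64, 7), 3, 2, "same"), c(128L, 32L, 4L))
  expect_error(conv_out_shape(2, 5, 1, 0), class = "NonPositiveOutput")
})

test_that("conv2d computes sliding dot products with padding and stride", {
  x <- matrix(runif(36), 6, 6)
  ident <- matrix(1, 1, 1)
  expect_equal(conv2d(x, ident, stride = 1), x)
  expect_equal(conv2d(matrix(0, 5, 5), matrix(runif(9), 3, 3)), matrix(0, 5, 5))
  # 3x3 all-ones filter on a constant image: interior pixels sum 9c
  cimg <- matrix(0.4, 5, 5)
  out <- conv2d(cimg, matrix(1, 3, 3), stride = 1, padding = "same")
  expect_equal(out[2:4, 2:4], matrix(9 * 0.4, 3, 3))
  # linearity
  a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
  f <- matrix(runif(9), 3, 3)
  expect_equal(conv2d(a + 2 * b, f), conv2d(a, f) + 2 * conv2d(b, f))
  # channel mismatch
  xc <- array(runif(5 * 5 * 2), c(5, 5, 2))
  expect_error(conv2d(xc, array(runif(27), c(3, 3, 3))),
               class = "ChannelMismatch")
})

test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  x <- matrix(rnorm(20), 4, 5)
  expect_true(all(relu(x) >= 0))
  expect_equal(relu(relu(x)), relu(x))
  expect_equal(relu(abs(x)), abs(x))
})

test_that("batch norm standardizes a mini batch and applies the affine", {
  st <- bn_state(1, epsilon = 1e-12)
  expect_equal(batch_norm(c(1, 3), st)$out, c(-1, 1), tolerance = 1e-6)
  st2 <- bn_state(1, gamma = 2, beta = 1, epsilon = 1e-12)
  expect_equal(batch_norm(c(1, 3), st2)$out, c(-1, 3), tolerance = 1e-6)
  # constant batch: zero numerator, output collapses to beta
  st3 <- bn_state(1, beta = 0.7)
  expect_equal(batch_norm(c(4, 4), st3)$out, c(0.7, 0.7))
  expect_error(batch_norm(c(1), bn_state(1)), class = "BatchTooSmall")
  expect_error(batch_norm(c(1, 2), bn_state(1), mode = "inference"),
               class = "UninitializedMoments")
})

test_that("train-mode batch norm output is standardized per channel pre-affine", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 3 * 16, mean = 5, sd = 4), c(8, 8, 3, 16))
  st <- bn_state(3)
  out <- batch_norm(x, st)$out
  for (ch in 1:3) {
    v <- as.vector(out[, , ch, ])
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(var(v) * (length(v) - 1) / length(v), 1, tolerance = 1e-4)
  }
  # running moments approach the batch moments over repeated updates
  for (i in 1:80) st <- batch_norm(x, st)$state
  expect_equal(st$running_mean, apply(x, 3, mean), tolerance = 1e-3)
})

test_that("dropout zeroes with probability p and preserves expectation", {
  x <- matrix(1, 50, 50)
  expect_identical(dropout(x, 0, "train"), x)
  expect_identical(dropout(x, 0.9, "inference"), x)
  set.seed(8)
  dropped <- dropout(x, 0.4, "train")
  expect_setequal(unique(as.vector(dropped)), c(0, 1 / 0.6))
  expect_equal(mean(dropped == 0), 0.4, tolerance = 0.03)
  reps <- replicate(200, mean(dropout(x[1:10, 1:10], 0.5, "train")))
  expect_equal(mean(reps), 1, tolerance = 0.03)
})

test_that("max and average pooling follow the region definitions", {
  region <- matrix(c(1, 2, 3, 6), 2, 2)  # rows: (1,3),(2,6)
  expect_equal(pool_deterministic(region, kernel = 2, stride = 2, "max"),
               matrix(6, 1, 1))
  expect_equal(pool_deterministic(region, kernel = 2, stride = 2, "average"),
               matrix(3, 1, 1))
  cmap <- matrix(0.3, 6, 6)
  expect_equal(pool_deterministic(cmap, mode = "max"), matrix(0.3, 3, 3))
  expect_equal(pool_deterministic(cmap, mode = "average"), matrix(0.3, 3, 3))
  # padding excluded from the average denominator: constant stays constant
  odd <- matrix(1, 5, 5)
  expect_equal(pool_deterministic(odd, mode = "average"), matrix(1, 3, 3))
})

test_that("stochastic pooling probabilities, sampling and expectation agree with the multinomial", {
  expect_equal(stochastic_pool_probs(c(1, 3)), c(0.25, 0.75))
  expect_equal(stochastic_pool_probs(5), 1)
  expect_equal(stochastic_pool_probs(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_error(stochastic_pool_probs(c(1, -1)), class = "NegativeActivation")

  expect_equal(stochastic_pool_sample(c(0, 7, 0, 0)), 7)
  expect_equal(stochastic_pool_sample(c(0, 0)), 0)
  set.seed(12)
  draws <- replicate(1e4, stochastic_pool_sample(c(1, 3)))
  expect_true(all(draws %in% c(1, 3)))
  expect_equal(mean(draws == 3), 0.75, tolerance = 0.015)
  set.seed(5); a <- replicate(50, stochastic_pool_sample(c(1, 2, 3)))
  set.seed(5); b <- replicate(50, stochastic_pool_sample(c(1, 2, 3)))
  expect_identical(a, b)

  expect_equal(stochastic_pool_expect(c(1, 3)), 2.5)
  expect_equal(stochastic_pool_expect(c(4, 4, 4)), 4)
  expect_equal(stochastic_pool_expect(c(0, 9, 0)), 9)  # one-hot = max pooling
})

test_that("stochastic expectation lies in [min, max] and dominates the average", {
  set.seed(21)
  for (i in 1:200) {
    region <- runif(sample(2:9, 1), 0, 5)
    e <- stochastic_pool_expect(region)
    expect_gte(e, min(region))
    expect_lte(e, max(region))
    expect_gte(e, mean(region) - 1e-12)
  }
})

test_that("all pooling modes coincide on constant maps", {
  cmap <- matrix(2.5, 8, 8)
  mx <- pool_deterministic(cmap, mode = "max")
  av <- pool_deterministic(cmap, mode = "average")
  ex <- stochastic_pool(cmap, variant = "expect")
  sm <- stochastic_pool(cmap, variant = "sample")
  expect_equal(mx, av)
  expect_equal(mx, ex)
  expect_equal(mx, sm)
})

test_that("sampled pooling outputs are elements of their regions", {
  set.seed(30)
  x <- matrix(runif(100), 10, 10)
  pooled <- stochastic_pool(x, kernel = 3, stride = 2, variant = "sample")
  expect_true(all(pooled %in% c(0, as.vector(x))))
})

test_that("fully-connected layer and softmax behave as linear map and distribution", {
  expect_equal(fc_forward(c(2, 3), diag(2)), c(2, 3))
  expect_equal(fc_forward(c(2, 3), matrix(0, 2, 2), bias = c(4, 5)), c(4, 5))
  expect_equal(fc_forward(c(2, 3), matrix(c(1, 1), 1, 2)), 5)
  expect_error(fc_forward(c(1, 2, 3), diag(2)), class = "DimensionMismatch")

  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  z <- rnorm(5)
  expect_equal(softmax(z + 100), softmax(z))
  stable <- softmax(c(1000, 0))
  expect_equal(stable, c(1, 0))
  m <- softmax(matrix(rnorm(12), 3, 4))
  expect_equal(colSums(m), rep(1, 4))
})
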