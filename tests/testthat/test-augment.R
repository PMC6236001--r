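test_that("rotation is identity at 0, symmetric at 180, invertible on the interior", {
  x <- smooth_image(48)
  expect_identical(rotate_image(x, 0), x)

  sym <- (x + x[48:1, 48:1]) / 2          # point-symmetric about the center
  expect_equal(rotate_image(sym, 180), sym, tolerance = 1e-8)

  back <- rotate_image(rotate_image(x, 10), -10)
  interior <- 13:36
  expect_equal(back[interior, interior], x[interior, interior], tolerance = 0.02)
})

test_that("rescale keeps shape, fixes the identity and zero images", {
  x <- smooth_image(40)
  expect_identical(rescale_image(x, 1), x)
  expect_equal(rescale_image(matrix(0, 20, 20), 0.7), matrix(0, 20, 20))
  expect_equal(dim(rescale_image(x, 1.3)), dim(x))
  expect_equal(dim(rescale_image(x, 0.7)), dim(x))
  # zoom-out pads with zeros: corners must be background
  shrunk <- rescale_image(x + 0.5, 0.7)
  expect_equal(shrunk[1, 1], 0)
  expect_error(rescale_image(x, 0), class = "NonPositiveFactor")
})

test_that("noise injection has the configured variance and is seed-reproducible", {
  x <- matrix(0.5, 256, 256)
  expect_identical(add_gaussian_noise(x, 0), x)
  set.seed(9)
  noisy <- add_gaussian_noise(x, 0.01)
  expect_equal(var(as.vector(noisy - x)), 0.01, tolerance = 0.05)
  expect_true(all(noisy >= 0 & noisy <= 1))
  set.seed(11)
  a <- add_gaussian_noise(x, 0.01)
  set.seed(11)
  b <- add_gaussian_noise(x, 0.01)
  expect_identical(a, b)
  expect_error(add_gaussian_noise(x, -1), class = "NegativeVariance")
})

test_that("translation shifts by whole pixels with zero fill", {
  x <- smooth_image(16)
  expect_identical(translate_image(x, 0, 0), x)
  fwd <- translate_image(x, 3, 0)
  expect_equal(fwd[, 1:3], matrix(0, 16, 3))
  back <- translate_image(fwd, -3, 0)
  expect_equal(back[, 1:13], x[, 1:13])
  expect_equal(back[, 14:16], matrix(0, 16, 3))
  # zero fill never adds mass
  set.seed(2)
  for (i in 1:10) {
    dx <- sample(-8:8, 1); dy <- sample(-8:8, 1)
    expect_lte(sum(translate_image(x, dx, dy)), sum(x) + 1e-12)
  }
})

test_that("gamma correction fixes the identity and follows the power law", {
  x <- smooth_image(16)
  expect_identical(gamma_correct(x, 1), x)
  expect_equal(gamma_correct(matrix(0.25, 1, 1), 0.5), matrix(0.5, 1, 1))
  ones <- matrix(1, 4, 4)
  expect_equal(gamma_correct(ones, 3.7), ones)
  expect_error(gamma_correct(x, 0), class = "NonPositiveGamma")
})

test_that("the default grids contain 30 values each and no identity", {
  config <- augment_config()
  expect_length(config$rotation_angles, 30)
  expect_length(config$scale_factors, 30)
  expect_length(config$gamma_values, 30)
  expect_false(any(config$rotation_angles == 0))
  expect_false(any(abs(config$scale_factors - 1) < 1e-9))
  expect_false(any(abs(config$gamma_values - 1) < 1e-9))
  expect_equal(config$noise_count, 30L)
  expect_equal(config$translation_count, 30L)
})

test_that("augment_image yields exactly 150 in-range images of the input shape", {
  x <- smooth_image(24)
  set.seed(5)
  out <- augment_image(x, augment_config())
  expect_length(out, 150)
  for (im in out) {
    expect_equal(dim(im), dim(x))
    expect_true(all(im >= 0 & im <= 1))
  }
  empty <- augment_config(rotation_angles = numeric(), scale_factors = numeric(),
                          noise_count = 0, translation_count = 0,
                          gamma_values = numeric())
  expect_length(augment_image(x, empty), 0)
})

test_that("deterministic grids are bit-reproducible; stochastic ones under a seed", {
  x <- smooth_image(24)
  config <- augment_config(seed = 3)
  set.seed(1); a <- augment_image(x, config)
  set.seed(1); b <- augment_image(x, config)
  expect_identical(a, b)
  set.seed(2); c2 <- augment_image(x, config)
  # grids identical regardless of RNG; draws differ
  expect_identical(a[["rot+10"]], c2[["rot+10"]])
  expect_identical(a[["gamma0.48"]], c2[["gamma0.48"]])
  expect_false(identical(a[["noise01"]], c2[["noise01"]]))
})

test_that("augmenting a training set scales it 151-fold with labels inherited", {
  ds <- small_study(n = 2, side = 24)
  aug <- augment_training_set(ds, augment_config(seed = 4))
  expect_length(aug, 151 * 4)
  expect_equal(unname(class_counts(aug)), c(302, 302))
  # originals retained verbatim, derived ids encode the parent
  expect_true(all(ds$sample_id %in% aug$sample_id))
  expect_equal(sum(startsWith(aug$sample_id, ds$sample_id[1])), 151)
  # reproducible from the config seed
  again <- augment_training_set(ds, augment_config(seed = 4))
  expect_identical(aug$images, again$images)
  expect_error(augment_training_set(image_dataset(list(), character()),
                                    augment_config()),
               class = "EmptySource")
})
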