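#' Data-augmentation configuration
#'
#' Holds the parameter grids of the five augmentation operators. The default
#' grids reproduce the published scheme: rotation angles from -30 to 30
#' degrees in steps of 2, scale factors from 0.7 to 1.3 in steps of 0.02,
#' 30 draws of zero-mean Gaussian noise with variance 0.01, 30 random
#' integer translations with per-axis magnitude uniform on \[0, 15\] pixels,
#' and gamma values from 0.4 to 1.6 in steps of 0.04. The identity parameter
#' of each deterministic grid (0 degrees, scale 1, gamma 1) is excluded, so
#' every operator contributes exactly 30 derived images and each original
#' yields 150 new images (a 151-fold training set).
#'
#' @param rotation_angles degrees; identity 0 removed automatically.
#' @param scale_factors isotropic zoom ratios; identity 1 removed.
#' @param noise_variance variance of the additive Gaussian noise (intensity
#'   units squared, on the \[0, 1\] scale).
#' @param noise_count number of independent noise draws per image.
#' @param translation_max maximum per-axis shift magnitude in pixels.
#' @param translation_count number of random translation draws per image.
#' @param gamma_values gamma-correction exponents; identity 1 removed.
#' @param seed integer seed used by [augment_training_set()] for the
#'   stochastic operators.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(rotation_angles = seq(-30, 30, by = 2),
                           scale_factors = seq(0.7, 1.3, by = 0.02),
                           noise_variance = 0.01,
                           noise_count = 30,
                           translation_max = 15,
                           translation_count = 30,
                           gamma_values = seq(0.4, 1.6, by = 0.04),
                           seed = 1L) {
  rotation_angles <- rotation_angles[abs(rotation_angles) > 1e-9]
  scale_factors <- scale_factors[abs(scale_factors - 1) > 1e-9]
  gamma_values <- gamma_values[abs(gamma_values - 1) > 1e-9]
  stopifnot(noise_variance >= 0, noise_count >= 0,
            translation_max >= 0, translation_count >= 0,
            all(scale_factors > 0), all(gamma_values > 0))
  structure(
    list(rotation_angles = rotation_angles, scale_factors = scale_factors,
         noise_variance = noise_variance, noise_count = as.integer(noise_count),
         translation_max = as.integer(translation_max),
         translation_count = as.integer(translation_count),
         gamma_values = gamma_values, seed = as.integer(seed)),
    class = "augment_config"
  )
}

# center of rotation/zoom: EBImage's affine works on pixel-corner coordinates,
# so the geometric center of an H x W image is (H/2, W/2)
warp_affine <- function(image, linear) {
  ctr <- dim(image) / 2
  m <- rbind(linear, ctr - ctr %*% linear)
  out <- EBImage::affine(image, m, filter = "bilinear", bg.col = 0,
                         output.dim = dim(image))
  unclass(as.matrix(out))
}

#' Rotate an image about its center
#'
#' Bilinear interpolation, zero fill outside the original support, output
#' shape equal to the input shape.
#'
#' @param image numeric matrix.
#' @param angle rotation angle in degrees.
#' @return rotated matrix of the same shape.
#' @export
rotate_image <- function(image, angle) {
  image <- as_gray_image(image, normalized = FALSE)
  stopifnot(is.finite(angle))
  if (angle %% 360 == 0) return(image)
  th <- angle * pi / 180
  out <- warp_affine(image, rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))))
  pmin(pmax(out, min(0, min(image))), max(image))
}

#' Isotropically rescale an image about its center
#'
#' Zoom by `factor` with bilinear interpolation; the result is center-cropped
#' (factor > 1) or zero-padded (factor < 1) back to the input shape.
#'
#' @param image numeric matrix.
#' @param factor zoom ratio, > 0.
#' @return matrix of the same shape as the input.
#' @export
rescale_image <- function(image, factor) {
  image <- as_gray_image(image, normalized = FALSE)
  if (!is.finite(factor) || factor <= 0) {
    msnet_error("NonPositiveFactor", "scale factor must be > 0")
  }
  if (abs(factor - 1) < 1e-12) return(image)
  warp_affine(image, diag(c(factor, factor)))
}

#' Add zero-mean Gaussian noise
#'
#' Perturbs every pixel independently with N(0, `variance`) noise and clips
#' the result to \[0, 1\]. Draws come from R's RNG, so `set.seed()` makes the
#' output reproducible.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param variance noise variance on the unit intensity scale (default 0.01).
#' @return noisy matrix in \[0, 1\].
#' @export
add_gaussian_noise <- function(image, variance = 0.01) {
  image <- as_gray_image(image)
  if (!is.finite(variance) || variance < 0) {
    msnet_error("NegativeVariance", "noise variance must be >= 0")
  }
  if (variance == 0) return(image)
  noisy <- image + rnorm(length(image), mean = 0, sd = sqrt(variance))
  pmin(pmax(noisy, 0), 1)
}

#' Translate an image by whole pixels
#'
#' Integer shift with zero fill; shape preserved. `dy` moves content down
#' (toward higher row indices), `dx` to the right (higher column indices).
#'
#' @param image numeric matrix.
#' @param dx,dy integer shifts in pixels.
#' @return shifted matrix of the same shape.
#' @export
translate_image <- function(image, dx, dy) {
  image <- as_gray_image(image, normalized = FALSE)
  dx <- as.integer(dx); dy <- as.integer(dy)
  h <- nrow(image); w <- ncol(image)
  if (abs(dx) > w || abs(dy) > h) {
    msnet_error("ShiftTooLarge", "translation exceeds image extent")
  }
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
  out
}

#' Gamma correction
#'
#' Elementwise power transform \eqn{\varphi^\gamma} on the unit intensity
#' scale; 0 and 1 are fixed points, gamma < 1 brightens mid-tones and
#' gamma > 1 darkens them.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param gamma exponent, > 0.
#' @return corrected matrix in \[0, 1\].
#' @export
gamma_correct <- function(image, gamma) {
  image <- as_gray_image(image)
  if (!is.finite(gamma) || gamma <= 0) {
    msnet_error("NonPositiveGamma", "gamma must be > 0")
  }
  image^gamma
}

#' Generate all augmented variants of one image
#'
#' Applies the five operators over the grids in `config`: every rotation
#' angle, every scale factor, `noise_count` noise draws, `translation_count`
#' random translations (per-axis integer magnitude uniform on
#' \[0, `translation_max`\] with independent random sign) and every gamma
#' value. With the default configuration this returns exactly 150 images.
#' Stochastic draws consume R's RNG stream; seed it (or use
#' [augment_training_set()], which seeds from `config$seed`) for
#' reproducibility.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param config an [augment_config()].
#' @return named list of derived images, names encoding transform and
#'   parameter (e.g. `rot-10`, `scale1.14`, `noise07`, `trans12_+3_-7`,
#'   `gamma0.48`).
#' @export
augment_image <- function(image, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  image <- as_gray_image(image)
  out <- list()
  for (a in config$rotation_angles) {
    out[[sprintf("rot%+g", a)]] <- rotate_image(image, a)
  }
  for (s in config$scale_factors) {
    out[[sprintf("scale%.2f", s)]] <- rescale_image(image, s)
  }
  for (i in seq_len(config$noise_count)) {
    out[[sprintf("noise%02d", i)]] <- add_gaussian_noise(image, config$noise_variance)
  }
  for (i in seq_len(config$translation_count)) {
    dx <- sample(0:config$translation_max, 1) * sample(c(-1L, 1L), 1)
    dy <- sample(0:config$translation_max, 1) * sample(c(-1L, 1L), 1)
    out[[sprintf("trans%02d_%+d_%+d", i, dx, dy)]] <- translate_image(image, dx, dy)
  }
  for (g in config$gamma_values) {
    out[[sprintf("gamma%.2f", g)]] <- gamma_correct(image, g)
  }
  out
}

#' Augment a training set
#'
#' Expands a training [image_dataset()] with every derived image from
#' [augment_image()]; labels are inherited and derived sample ids encode
#' parent, transform and parameter. With the default grids the result is
#' 151 times the original size. Augmentation is applied to training data
#' only; the evaluation harness never augments the test branch.
#'
#' @param train an [image_dataset()].
#' @param config an [augment_config()]; `config$seed` makes the stochastic
#'   operators reproducible.
#' @return an [image_dataset()] containing the originals plus all variants.
#' @export
augment_training_set <- function(train, config = augment_config()) {
  stopifnot(inherits(train, "image_dataset"))
  if (length(train) == 0) msnet_error("EmptySource", "training set is empty")
  n <- length(train)
  chunks <- vector("list", n)
  labels <- vector("list", n)
  ids <- vector("list", n)
  src <- vector("list", n)
  withr::with_seed(config$seed, {
    for (i in seq_len(n)) {
      derived <- augment_image(train$images[[i]], config)
      chunks[[i]] <- c(list(train$images[[i]]), derived)
      labels[[i]] <- rep(as.character(train$label[i]), 1 + length(derived))
      ids[[i]] <- c(train$sample_id[i],
                    paste(train$sample_id[i], names(derived), sep = "_"))
      src[[i]] <- rep(train$source_id[i], 1 + length(derived))
    }
  })
  image_dataset(do.call(c, chunks), unlist(labels), unlist(ids), unlist(src))
}
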