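#' Parameters of the synthetic brain-slice generator
#'
#' Describes axial-slice-like grayscale phantoms: an elliptical "brain" of
#' smoothly textured tissue on a dark background, with the MS class carrying
#' a small number of hyperintense plaques (bright Gaussian blobs, the MRI
#' hallmark of demyelinating lesions) and the HC class carrying none. The
#' two classes are drawn through different raw intensity scales ("virtual
#' scanners"), so the per-image histogram stretch demonstrably performs its
#' inter-source normalization role.
#'
#' Defaults (for `image_side = 256`, scaled proportionally otherwise):
#' brain semi-axes ~ (102, 84) px, tissue mean 0.55 with smoothed texture of
#' sd 0.06 (correlation length ~ side/16, coarser than any plaque, and well below
#' the plaque contrast so lesions
#' are not confusable with texture), 1-4 plaques of radius 8-18 px and
#' contrast 0.35 above tissue, background 0.05, pixel noise sd 0.02.
#'
#' @param image_side image side in pixels.
#' @param brain_axes ellipse semi-axes in pixels (default scaled from side).
#' @param tissue_mean,tissue_sd mean and texture amplitude of the tissue.
#' @param plaque_count_range integer range of plaques per MS slice.
#' @param plaque_radius_range plaque radius range in pixels (default scaled).
#' @param plaque_contrast intensity offset of plaques above tissue; the
#'   class-separability knob (0 makes the classes indistinguishable).
#' @param background_level intensity outside the brain.
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param seed integer seed used by [generate_dataset()].
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(image_side = 256,
                         brain_axes = NULL,
                         tissue_mean = 0.55, tissue_sd = 0.06,
                         plaque_count_range = c(1, 4),
                         plaque_radius_range = NULL,
                         plaque_contrast = 0.35,
                         background_level = 0.05,
                         noise_sd = 0.02,
                         seed = 1L) {
  if (is.null(brain_axes)) brain_axes <- round(image_side * c(0.40, 0.33))
  if (is.null(plaque_radius_range)) {
    plaque_radius_range <- pmax(1, round(image_side * c(0.03, 0.07)))
  }
  if (image_side < 8 || plaque_contrast < 0 ||
      max(plaque_radius_range) >= min(brain_axes) ||
      any(plaque_count_range < 0) || noise_sd < 0) {
    msnet_error("InvalidParams", "inconsistent synthetic-slice parameters")
  }
  structure(
    list(image_side = as.integer(image_side), brain_axes = brain_axes,
         tissue_mean = tissue_mean, tissue_sd = tissue_sd,
         plaque_count_range = as.integer(plaque_count_range),
         plaque_radius_range = plaque_radius_range,
         plaque_contrast = plaque_contrast,
         background_level = background_level, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synth_params"
  )
}

# low-pass filtered white noise: separable Gaussian smoothing via the
# package's own convolution kernel
smooth_noise <- function(side, sigma) {
  k <- ceiling(3 * sigma)
  g <- exp(-(seq(-k, k))^2 / (2 * sigma^2))
  g <- g / sum(g)
  z <- matrix(rnorm(side * side), side, side)
  kh <- array(matrix(g, ncol = 1), c(2 * k + 1, 1, 1, 1))
  kv <- array(matrix(g, nrow = 1), c(1, 2 * k + 1, 1, 1))
  z <- conv2d(z, kh)
  z <- conv2d(z, kv)
  z / sd(z)
}

#' Generate one synthetic labeled slice
#'
#' Draws the tissue texture, places plaques (MS only) uniformly inside the
#' central 80% of the brain ellipse, pushes the image through the label's
#' virtual-scanner intensity scale and clips to \[0, 1\]. Consumes R's RNG;
#' see [generate_dataset()] for the seeded batch interface.
#'
#' @param params a [synth_params()].
#' @param label `"MS"` or `"HC"`.
#' @return list with `image` (matrix in \[0, 1\]), `label`, and `plaques`
#'   (data frame of plaque centers/radii; zero rows for HC).
#' @export
generate_slice <- function(params, label = c("MS", "HC")) {
  stopifnot(inherits(params, "synth_params"))
  label <- match.arg(label)
  side <- params$image_side
  ctr <- (side + 1) / 2
  xx <- matrix(rep(seq_len(side), side), side, side)        # column index
  yy <- t(xx)                                               # row index
  inside <- ((yy - ctr) / params$brain_axes[1])^2 +
    ((xx - ctr) / params$brain_axes[2])^2 <= 1
  texture <- params$tissue_mean + params$tissue_sd * smooth_noise(side, side / 16)
  img <- matrix(params$background_level, side, side)
  img[inside] <- texture[inside]

  plaques <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (label == "MS") {
    k <- sample(params$plaque_count_range[1]:params$plaque_count_range[2], 1)
    for (i in seq_len(k)) {
      # rejection-sample a center inside 80% of the ellipse
      repeat {
        r0 <- ctr + 0.8 * params$brain_axes[1] * (2 * runif(1) - 1)
        c0 <- ctr + 0.8 * params$brain_axes[2] * (2 * runif(1) - 1)
        if (((r0 - ctr) / (0.8 * params$brain_axes[1]))^2 +
            ((c0 - ctr) / (0.8 * params$brain_axes[2]))^2 <= 1) break
      }
      rad <- runif(1, params$plaque_radius_range[1], params$plaque_radius_range[2])
      blob <- params$plaque_contrast *
        exp(-((yy - r0)^2 + (xx - c0)^2) / (2 * (rad / 1.5)^2))
      img <- img + blob * inside
      plaques <- rbind(plaques, data.frame(row = r0, col = c0, radius = rad))
    }
  }
  img <- img + params$noise_sd * matrix(rnorm(side * side), side, side)
  # virtual scanners: each class arrives on its own raw dynamic range, which
  # the histogram-stretch stage is responsible for matching
  img <- if (label == "MS") 0.12 + 0.75 * img else 0.05 + 0.55 * img
  img <- pmin(pmax(img, 0), 1)
  list(image = img, label = label, plaques = plaques)
}

#' Generate a labeled synthetic dataset
#'
#' `n_ms` plaque-bearing and `n_hc` plaque-free slices, each produced from a
#' per-slice seed derived from `seed`, so any slice is reproducible in
#' isolation. Plaque ground truth (centers and radii) is attached as the
#' `"provenance"` attribute.
#'
#' @param params a [synth_params()].
#' @param n_ms,n_hc class sizes (defaults mirror the clinical source sizes,
#'   676 MS and 681 HC slices).
#' @param seed master seed (defaults to `params$seed`).
#' @return an [image_dataset()]; `attr(, "provenance")` is a data frame with
#'   one row per plaque (sample_id, row, col, radius) plus `n_plaques` per
#'   image in `attr(, "n_plaques")`.
#' @export
generate_dataset <- function(params = synth_params(), n_ms = 676, n_hc = 681,
                             seed = params$seed) {
  stopifnot(n_ms >= 0, n_hc >= 0, n_ms + n_hc > 0)
  labels <- c(rep("MS", n_ms), rep("HC", n_hc))
  n <- length(labels)
  slice_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  images <- vector("list", n)
  prov <- vector("list", n)
  n_plaques <- integer(n)
  ids <- sprintf("%s%06d", tolower(labels), c(seq_len(n_ms), seq_len(n_hc)))
  for (i in seq_len(n)) {
    sl <- withr::with_seed(slice_seeds[i], generate_slice(params, labels[i]))
    images[[i]] <- sl$image
    n_plaques[i] <- nrow(sl$plaques)
    if (nrow(sl$plaques)) {
      prov[[i]] <- cbind(sample_id = ids[i], sl$plaques)
    }
  }
  ds <- image_dataset(images, labels, ids,
                      source_id = ifelse(labels == "MS", "synth-scanner-a",
                                         "synth-scanner-b"))
  attr(ds, "provenance") <- do.call(rbind, prov[!vapply(prov, is.null, logical(1))])
  attr(ds, "n_plaques") <- n_plaques
  ds
}
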