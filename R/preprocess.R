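#' Contrast normalization by histogram stretching
#'
#' Linearly rescales the intensities of a grayscale image so that its minimum
#' maps to 0 and its maximum to 1:
#' \deqn{\varphi(x, y) = \frac{\mu(x, y) - \mu_{\min}}{\mu_{\max} - \mu_{\min}}}
#' Brain slices acquired on different scanners arrive with different dynamic
#' ranges; stretching each image to the full unit interval performs
#' inter-scan contrast normalization before the two sources are pooled.
#'
#' The stretch is computed per image, from that image's own minimum and
#' maximum, and is idempotent and invariant to positive affine rescaling of
#' the input intensities.
#'
#' @param image a numeric matrix of intensities (any real scale).
#' @return a numeric matrix of the same shape with values in \[0, 1\],
#'   attaining both 0 and 1.
#' @examples
#' histogram_stretch(matrix(c(2, 6, 4, 10), 2, 2))
#' @export
histogram_stretch <- function(image) {
  image <- as_gray_image(image, normalized = FALSE)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    msnet_error("DegenerateRange",
      "histogram_stretch: constant image has no intensity range to stretch")
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

# validate a grayscale image; normalized = TRUE additionally requires [0, 1]
as_gray_image <- function(x, normalized = TRUE) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1 || ncol(x) < 1) {
    msnet_error("InvalidImage", "a grayscale image must be a non-empty numeric matrix")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    msnet_error("InvalidImage", "image contains non-finite intensities")
  }
  if (normalized && (min(x) < 0 || max(x) > 1)) {
    msnet_error("InvalidImage", "image intensities must lie in [0, 1]")
  }
  x
}

#' Construct a labeled two-class image dataset
#'
#' The container every pipeline stage consumes: an ordered collection of
#' grayscale images with class labels (`"MS"` or `"HC"`), unique sample ids
#' and a source tag per image.
#'
#' @param images list of numeric matrices, all the same shape.
#' @param labels character or factor of `"MS"` / `"HC"`, one per image.
#' @param sample_id character vector of unique ids (default `img000001`...).
#' @param source_id character vector naming the origin of each image.
#' @return an object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels,
                          sample_id = sprintf("img%06d", seq_along(images)),
                          source_id = rep("unknown", length(images))) {
  stopifnot(is.list(images))
  labels <- factor(as.character(labels), levels = c("MS", "HC"))
  if (anyNA(labels)) msnet_error("InvalidLabel", "labels must be 'MS' or 'HC'")
  if (length(labels) != length(images) || length(sample_id) != length(images)) {
    msnet_error("InvalidDataset", "images, labels and sample_id lengths differ")
  }
  if (anyDuplicated(sample_id)) {
    msnet_error("InvalidDataset", "sample_id values must be unique")
  }
  if (length(images)) {
    shp <- dim(images[[1]])
    ok <- vapply(images, function(im) identical(dim(im), shp), logical(1))
    if (!all(ok)) msnet_error("InvalidDataset", "all images must share one shape")
  }
  structure(
    list(images = images, label = labels,
         sample_id = as.character(sample_id),
         source_id = as.character(source_id)),
    class = "image_dataset"
  )
}

#' @export
length.image_dataset <- function(x) length(x$images)

#' @export
print.image_dataset <- function(x, ...) {
  cnt <- class_counts(x)
  shp <- if (length(x)) paste(dim(x$images[[1]]), collapse = "x") else "-"
  cat(sprintf("<image_dataset> %d images (%s): %d MS, %d HC\n",
              length(x), shp, cnt[["MS"]], cnt[["HC"]]))
  invisible(x)
}

#' Per-class image counts of a dataset
#' @param dataset an [image_dataset()].
#' @return named integer vector with elements `MS` and `HC`.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "image_dataset"))
  c(table(dataset$label))
}

# subset by positional index, preserving all parallel fields
dataset_subset <- function(dataset, idx) {
  image_dataset(dataset$images[idx], dataset$label[idx],
                dataset$sample_id[idx], dataset$source_id[idx])
}

#' Merge the MS and healthy-control sources into one normalized dataset
#'
#' Each image is contrast-normalized by [histogram_stretch()] (per image, so
#' both sources end up on the same dynamic range) and the two collections are
#' concatenated with labels assigned by source. With the study's source sizes
#' (676 MS and 681 HC slices) this yields the 1,357-image dataset.
#'
#' @param ms_images list of grayscale matrices from the MS source.
#' @param hc_images list of grayscale matrices from the healthy-control source.
#' @param normalize apply [histogram_stretch()] to every image (default TRUE).
#' @param ms_source,hc_source source tags recorded per image.
#' @return an [image_dataset()] of size `length(ms_images) + length(hc_images)`.
#' @export
assemble_dataset <- function(ms_images, hc_images, normalize = TRUE,
                             ms_source = "ms", hc_source = "hc") {
  if (length(ms_images) == 0 || length(hc_images) == 0) {
    msnet_error("EmptySource", "both image sources must be non-empty")
  }
  imgs <- c(ms_images, hc_images)
  if (normalize) imgs <- lapply(imgs, histogram_stretch)
  n_ms <- length(ms_images)
  n_hc <- length(hc_images)
  image_dataset(
    imgs,
    labels = c(rep("MS", n_ms), rep("HC", n_hc)),
    sample_id = c(sprintf("ms%06d", seq_len(n_ms)), sprintf("hc%06d", seq_len(n_hc))),
    source_id = c(rep(ms_source, n_ms), rep(hc_source, n_hc))
  )
}

#' Contrast-normalize every image of a dataset
#'
#' Applies [histogram_stretch()] per image. Required whenever the images
#' come from sources with different intensity scales (different scanners,
#' or the synthetic generator's two virtual scanners): without it a
#' classifier can read the class off the dynamic range alone.
#'
#' @param dataset an [image_dataset()].
#' @return the dataset with every image stretched to \[0, 1\].
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "image_dataset"))
  dataset$images <- lapply(dataset$images, histogram_stretch)
  dataset
}

#' Seeded hold-out split with fixed per-class counts
#'
#' Draws a uniform random permutation within each class (under `seed`) and
#' assigns the first `train_*` images to the training set and the next
#' `test_*` to the test set. The study's split takes 350 MS + 350 HC for
#' training and 326 MS + 331 HC for test, exactly consuming both classes;
#' when the requested counts undersubscribe a class the leftover images are
#' dropped from both sets.
#'
#' @param dataset an [image_dataset()].
#' @param train_ms,train_hc,test_ms,test_hc per-class counts.
#' @param seed integer seed; the same seed always reproduces the same split.
#' @return list with elements `train` and `test`, both [image_dataset()]s,
#'   disjoint by `sample_id`.
#' @export
holdout_split <- function(dataset, train_ms = 350, train_hc = 350,
                          test_ms = 326, test_hc = 331, seed = 1L) {
  stopifnot(inherits(dataset, "image_dataset"))
  cnt <- class_counts(dataset)
  need <- c(MS = train_ms + test_ms, HC = train_hc + test_hc)
  for (cl in c("MS", "HC")) {
    if (need[[cl]] > cnt[[cl]]) {
      msnet_error("InsufficientSamples", sprintf(
        "class %s has %d images but %d requested", cl, cnt[[cl]], need[[cl]]))
    }
  }
  idx_ms <- which(dataset$label == "MS")
  idx_hc <- which(dataset$label == "HC")
  withr::with_seed(seed, {
    idx_ms <- sample(idx_ms)
    idx_hc <- sample(idx_hc)
  })
  train_idx <- c(idx_ms[seq_len(train_ms)], idx_hc[seq_len(train_hc)])
  test_idx <- c(
    idx_ms[seq_len(test_ms) + train_ms],
    idx_hc[seq_len(test_hc) + train_hc]
  )
  list(train = dataset_subset(dataset, train_idx),
       test = dataset_subset(dataset, test_idx))
}

#' Read a grayscale image from PNG, TIFF or single-slice NIfTI
#'
#' Color channels are averaged to one intensity plane. Integer-typed NIfTI
#' data are mapped to \[0, 1\] by dividing by the maximum of the storage
#' type, so the downstream histogram stretch is independent of on-disk dtype;
#' PNG and TIFF readers already return \[0, 1\].
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param slice axial slice index for NIfTI volumes (required when the file
#'   holds more than one slice).
#' @return numeric matrix in \[0, 1\].
#' @export
read_gray_image <- function(path, slice = NULL) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      msnet_error("MissingReader", "the 'tiff' package is required for TIFF input")
    }
    img <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] == 1) {
        arr <- arr[, , 1]
      } else {
        if (is.null(slice)) {
          msnet_error("MissingSlice", "NIfTI volume has >1 slice; supply `slice`")
        }
        arr <- arr[, , slice]
      }
    }
    storage <- attr(vol, "datatype")
    dmax <- max(arr)
    if (dmax > 1) {
      # integer-typed acquisition: scale by the dtype ceiling
      ceiling_for <- if (dmax <= 255) 255 else if (dmax <= 65535) 65535 else dmax
      arr <- arr / ceiling_for
    }
    img <- arr
  } else {
    msnet_error("UnknownFormat", paste("unsupported image format:", path))
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  as_gray_image(unclass(as.matrix(img)), normalized = TRUE)
}

#' Write a dataset as PNG files plus a CSV manifest
#'
#' @param dataset an [image_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest data frame (sample_id, label, source_id,
#'   path) that is also written to `manifest.csv` in `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "image_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(dataset$sample_id, ".png"))
  for (i in seq_along(dataset$images)) {
    png::writePNG(pmin(pmax(dataset$images[[i]], 0), 1), paths[i])
  }
  manifest <- data.frame(
    sample_id = dataset$sample_id,
    label = as.character(dataset$label),
    source_id = dataset$source_id,
    path = paths,
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset previously written by [write_dataset()]
#' @param dir directory containing `manifest.csv` and the PNG files.
#' @return an [image_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  imgs <- lapply(manifest$path, read_gray_image)
  image_dataset(imgs, manifest$label, manifest$sample_id, manifest$source_id)
}
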