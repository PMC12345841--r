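# Focused (region-targeted) augmentation: multiplicative speckle noise
# followed by Gaussian smoothing, applied only inside the union of
# target-class bounding boxes. Pixels outside the union are bit-identical
# to the input and box geometry is never touched, so the augmented copy
# reuses the original label file verbatim.
#
# The two operators are, per pixel inside the region:
#   I'  = clip(I + I * n, 0, 255),  n ~ N(0, sigma^2)      (speckle)
#   I'' = sum_{i,j in [-k,k]} I'(x+i, y+j) * G(i,j)        (Gaussian blur)
# with G a normalized Gaussian kernel of half-width k (kernel_size = 2k+1).
# The blur reads its neighborhood from the full noise-applied image, so
# context just outside the box informs the convolution and no seam forms at
# the box edge; only masked pixels are written.

#' Configuration for focused augmentation
#'
#' @param sigma_speckle Standard deviation of the zero-mean multiplicative
#'   Gaussian noise (unitless; each pixel is perturbed by `I * n`). Default
#'   0.10, i.e. about 10 gray levels at mid intensity.
#' @param kernel_size Odd Gaussian kernel size (`2k + 1`); default 5 (k = 2).
#' @param sigma_blur Gaussian kernel standard deviation in pixels; default 1.
#' @param target_classes Class ids whose boxes are augmented; default `1`
#'   (the fracture class).
#' @param copies_per_image Augmented variants generated per original;
#'   default 1, which doubles the training split when merged.
#' @param seed Integer base seed; per-image streams are derived from it.
#' @return An `augment_config` list.
#' @export
augment_config <- function(sigma_speckle = 0.10, kernel_size = 5L,
                           sigma_blur = 1.0, target_classes = 1L,
                           copies_per_image = 1L, seed = 0L) {
  if (sigma_speckle < 0) stop("sigma_speckle must be >= 0")
  if (sigma_blur < 0) stop("sigma_blur must be >= 0")
  if (kernel_size < 1 || kernel_size %% 2 == 0) stop("kernel_size must be odd and >= 1")
  if (length(target_classes) == 0) stop("target_classes must be non-empty")
  if (copies_per_image < 1) stop("copies_per_image must be a positive integer")
  structure(list(sigma_speckle = sigma_speckle,
                 kernel_size = as.integer(kernel_size),
                 sigma_blur = sigma_blur,
                 target_classes = as.integer(target_classes),
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Rasterize target-class boxes into a boolean region mask
#'
#' The mask is true exactly on the union of the pixel regions (see
#' [to_pixel()]) of boxes whose class is in `target_classes`; overlapping
#' boxes contribute once. No target boxes gives an all-false mask.
#'
#' @param boxes A box `data.frame`.
#' @param target_classes Integer class ids to include.
#' @param W,H Image width and height in pixels.
#' @return An `H x W` logical matrix.
#' @export
build_mask <- function(boxes, target_classes, W, H) {
  mask <- matrix(FALSE, nrow = H, ncol = W)
  boxes <- validate_boxes(boxes)
  for (i in seq_len(nrow(boxes))) {
    if (!boxes$class_id[i] %in% target_classes) next
    px <- to_pixel(boxes[i, ], W, H)
    mask[(px$y1 + 1):px$y2, (px$x1 + 1):px$x2] <- TRUE
  }
  mask
}

#' Apply multiplicative speckle noise inside a region
#'
#' Masked pixels become `clip(round(I + I * n), 0, 255)` with one
#' `n ~ N(0, sigma^2)` draw per masked pixel position, shared across
#' channels (grayscale-as-RGB stays channel-consistent). Unmasked pixels
#' are bit-identical to the input. Draws come from the current RNG stream;
#' callers seed it (see [focused_augment_image()]).
#'
#' @param image An [image_grid()].
#' @param mask An `H x W` logical matrix.
#' @param sigma Noise standard deviation; 0 is the identity.
#' @return A new [image_grid()].
#' @export
speckle_noise <- function(image, mask, sigma) {
  stopifnot(inherits(image, "image_grid"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (!identical(dim(mask), dim(image)[1:2])) stop("mask shape must match image")
  idx <- which(mask)
  if (length(idx) == 0 || sigma == 0) return(image)
  n <- stats::rnorm(length(idx), mean = 0, sd = sigma)
  out <- unclass(image)
  plane <- img_height(image) * img_width(image)
  for (c in seq_len(img_channels(image))) {
    v <- as.numeric(out[idx + (c - 1L) * plane])
    out[idx + (c - 1L) * plane] <- as.integer(clip255(round_half_away(v + v * n)))
  }
  as_image_grid(out)
}

#' Build a normalized 2-D Gaussian kernel
#'
#' Weights are proportional to `exp(-(i^2 + j^2) / (2 * sigma^2))` for
#' offsets `i, j` in `[-k, k]` with `k = (kernel_size - 1) / 2`, normalized
#' to sum to 1. `sigma_blur = 0` yields the delta (identity) kernel.
#'
#' @param kernel_size Odd kernel size; e.g. 5 gives `k = 2`.
#' @param sigma_blur Standard deviation in pixels.
#' @return A `gaussian_kernel` list with fields `weights` and `k`.
#' @export
#' @examples
#' make_gaussian_kernel(5, 1.0)$k # 2
make_gaussian_kernel <- function(kernel_size, sigma_blur) {
  if (kernel_size < 1 || kernel_size %% 2 == 0) {
    stop("kernel_size must be odd and >= 1")
  }
  if (sigma_blur < 0) stop("sigma_blur must be >= 0")
  k <- (as.integer(kernel_size) - 1L) %/% 2L
  if (sigma_blur == 0 || k == 0L) {
    w <- matrix(0, kernel_size, kernel_size)
    w[k + 1L, k + 1L] <- 1
  } else {
    off <- (-k):k
    w <- exp(-outer(off^2, off^2, `+`) / (2 * sigma_blur^2))
    w <- w / sum(w)
  }
  structure(list(weights = w, k = k), class = "gaussian_kernel")
}

# reflect-101 index fold: 1-based index i into [1, n], mirrored about the
# edges without duplicating the border pixel
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' Gaussian-blur an image inside a region
#'
#' For masked pixels, `I''(x, y) = sum I'(x + i, y + j) * G(i, j)`, rounded
#' half away from zero and clipped to \[0, 255\]. Neighborhood values are
#' read from the full input image (reflect padding at frame borders), so
#' context outside the box informs the convolution; unmasked pixels are
#' bit-identical to the input.
#'
#' @param image An [image_grid()].
#' @param mask An `H x W` logical matrix.
#' @param kernel A [make_gaussian_kernel()] result.
#' @return A new [image_grid()].
#' @export
blur_region <- function(image, mask, kernel) {
  stopifnot(inherits(image, "image_grid"), inherits(kernel, "gaussian_kernel"))
  if (!identical(dim(mask), dim(image)[1:2])) stop("mask shape must match image")
  if (!any(mask)) return(image)
  k <- kernel$k
  H <- img_height(image); W <- img_width(image)
  rows <- reflect_index((1L - k):(H + k), H)
  cols <- reflect_index((1L - k):(W + k), W)
  out <- unclass(image)
  midx <- which(mask)
  for (c in seq_len(img_channels(image))) {
    pad <- matrix(as.numeric(image[, , c]), H, W)[rows, cols, drop = FALSE]
    acc <- matrix(0, H, W)
    for (di in -k:k) {
      for (dj in -k:k) {
        acc <- acc + kernel$weights[di + k + 1L, dj + k + 1L] *
          pad[(1L:H) + k + di, (1L:W) + k + dj, drop = FALSE]
      }
    }
    ch <- out[, , c]
    ch[midx] <- as.integer(clip255(round_half_away(acc[midx])))
    out[, , c] <- ch
  }
  as_image_grid(out)
}

#' Apply focused augmentation to one labeled image
#'
#' Builds the target-class region mask, applies speckle noise then Gaussian
#' blur inside it, and returns a copy with the boxes untouched and the
#' image id suffixed. An image with no target-class boxes is emitted
#' unchanged (suffix still applied). Deterministic: the noise stream is
#' seeded from `(seed, image_id, copy)` via [derive_seed()].
#'
#' @param item A [labeled_image()].
#' @param config An [augment_config()].
#' @param copy Copy index used in the seed derivation and id suffix.
#' @param seed Base seed; defaults to `config$seed`.
#' @return A new [labeled_image()].
#' @export
focused_augment_image <- function(item, config = augment_config(), copy = 1L,
                                  seed = config$seed) {
  stopifnot(inherits(item, "labeled_image"), inherits(config, "augment_config"))
  W <- img_width(item$image); H <- img_height(item$image)
  mask <- build_mask(item$boxes, config$target_classes, W, H)
  kernel <- make_gaussian_kernel(config$kernel_size, config$sigma_blur)
  img <- with_seed(derive_seed(seed, item$image_id, copy), {
    noisy <- speckle_noise(item$image, mask, config$sigma_speckle)
    blur_region(noisy, mask, kernel)
  })
  labeled_image(paste0(item$image_id, "_faug", copy), img, item$boxes)
}

#' Augment a training split and merge with the originals
#'
#' Emits the originals unmodified followed by `copies_per_image` focused
#' variants per original, each with a distinct image id. Per-image noise
#' streams are derived from `(seed, image_id, copy)`, so shuffling the
#' input order changes no output pixel. With the default single copy the
#' split size doubles. Only the training split should pass through this;
#' validation and test data are never augmented.
#'
#' @param train A list of [labeled_image()]s (non-empty).
#' @param config An [augment_config()].
#' @return A list of `(1 + copies_per_image) * length(train)` items.
#' @export
augment_training_set <- function(train, config = augment_config()) {
  if (length(train) == 0) stop("training split is empty")
  variants <- list()
  for (it in train) {
    for (cp in seq_len(config$copies_per_image)) {
      variants[[length(variants) + 1L]] <- focused_augment_image(it, config, copy = cp)
    }
  }
  c(train, variants)
}
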