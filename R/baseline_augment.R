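# Conventional whole-image augmentation baseline: random rotation (+/-30
# degrees), brightness/contrast adjustment, and Gaussian blurring applied
# to the entire frame, with bounding boxes transformed geometrically
# (axis-aligned envelope of the exactly rotated corners, clipped to the
# frame, with a minimum-visibility filter).

#' Configuration for conventional (whole-image) augmentation
#'
#' The transform families follow common augmentation-library defaults; only
#' the rotation range is a study-level constant (+/-30 degrees). All are
#' config-exposed.
#'
#' @param max_rotation_deg Rotation drawn uniformly in `[-max, max]`
#'   degrees; default 30.
#' @param brightness_delta_range Additive brightness drawn uniformly in
#'   `[-delta, delta]` gray levels; default 25.
#' @param contrast_factor_range Multiplicative contrast factor range;
#'   default `c(0.8, 1.2)`.
#' @param blur_kernel_size Odd Gaussian blur kernel size; default 3.
#' @param blur_sigma Blur kernel standard deviation in pixels; default 1.
#' @param p_apply Per-transform application probability; default 0.5 each.
#' @param min_box_visibility Boxes whose clipped area falls below this
#'   fraction of the original area after rotation are dropped; default 0.2.
#' @param seed Integer base seed.
#' @return A `global_augment_config` list.
#' @export
global_augment_config <- function(max_rotation_deg = 30, brightness_delta_range = 25,
                                  contrast_factor_range = c(0.8, 1.2),
                                  blur_kernel_size = 3L, blur_sigma = 1.0,
                                  p_apply = 0.5, min_box_visibility = 0.2,
                                  seed = 0L) {
  if (max_rotation_deg < 0 || max_rotation_deg > 90) {
    stop("max_rotation_deg must be in [0, 90]")
  }
  if (p_apply < 0 || p_apply > 1) stop("p_apply must be in [0, 1]")
  if (any(contrast_factor_range <= 0)) stop("contrast factors must be > 0")
  if (blur_kernel_size < 1 || blur_kernel_size %% 2 == 0) {
    stop("blur_kernel_size must be odd and >= 1")
  }
  structure(list(max_rotation_deg = max_rotation_deg,
                 brightness_delta_range = brightness_delta_range,
                 contrast_factor_range = sort(contrast_factor_range),
                 blur_kernel_size = as.integer(blur_kernel_size),
                 blur_sigma = blur_sigma, p_apply = p_apply,
                 min_box_visibility = min_box_visibility,
                 seed = as.integer(seed)),
            class = "global_augment_config")
}

rot_matrix <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Exact corner rotation of a normalized box about the image center, in
# pixel coordinates; returns the axis-aligned envelope before clipping,
# as continuous pixel coordinates c(x1, y1, x2, y2).
rotate_box_envelope <- function(box, angle_deg, W, H) {
  R <- rot_matrix(angle_deg)
  cxp <- box$cx * W; cyp <- box$cy * H
  wp <- box$w * W; hp <- box$h * H
  corners <- rbind(c(cxp - wp / 2, cyp - hp / 2), c(cxp + wp / 2, cyp - hp / 2),
                   c(cxp - wp / 2, cyp + hp / 2), c(cxp + wp / 2, cyp + hp / 2))
  centered <- sweep(corners, 2, c(W / 2, H / 2))
  rot <- t(R %*% t(centered)) + matrix(c(W / 2, H / 2), 4, 2, byrow = TRUE)
  c(min(rot[, 1]), min(rot[, 2]), max(rot[, 1]), max(rot[, 2]))
}

#' Rotate an image about its center together with its boxes
#'
#' The image is rotated with bilinear resampling at the same output size;
#' pixels mapping outside the source frame are filled with 0 (the dark CT
#' background). Each box's four corners are rotated exactly, replaced by
#' their axis-aligned envelope, and clipped to the frame; boxes whose
#' clipped area falls below `min_box_visibility` times the original area
#' are dropped. Angle 0 is the exact identity.
#'
#' @param image An [image_grid()].
#' @param boxes A box `data.frame`.
#' @param angle Rotation angle in degrees (mathematically positive in
#'   x-right/y-down pixel coordinates); `|angle| <= 180`.
#' @param min_box_visibility Visibility threshold for the box filter.
#' @return `list(image = , boxes = )`.
#' @export
rotate_image_and_boxes <- function(image, boxes, angle, min_box_visibility = 0.2) {
  stopifnot(inherits(image, "image_grid"), abs(angle) <= 180)
  boxes <- validate_boxes(boxes)
  H <- img_height(image); W <- img_width(image)
  if (angle == 0) return(list(image = image, boxes = boxes))

  # inverse-map each output pixel center into the source frame
  Rinv <- rot_matrix(-angle)
  xs <- (seq_len(W) - 0.5) - W / 2
  ys <- (seq_len(H) - 0.5) - H / 2
  sx <- Rinv[1, 1] * matrix(xs, H, W, byrow = TRUE) + Rinv[1, 2] * matrix(ys, H, W) + W / 2
  sy <- Rinv[2, 1] * matrix(xs, H, W, byrow = TRUE) + Rinv[2, 2] * matrix(ys, H, W) + H / 2
  u <- sx - 0.5; v <- sy - 0.5
  x0 <- floor(u); y0 <- floor(v)
  fx <- u - x0; fy <- v - y0
  out <- unclass(image)
  gather <- function(M, yi, xi) {
    ok <- yi >= 0 & yi <= H - 1 & xi >= 0 & xi <= W - 1
    val <- matrix(0, H, W)
    val[ok] <- M[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    val
  }
  for (c in seq_len(img_channels(image))) {
    M <- matrix(as.numeric(image[, , c]), H, W)
    interp <- gather(M, y0, x0) * (1 - fx) * (1 - fy) +
      gather(M, y0, x0 + 1) * fx * (1 - fy) +
      gather(M, y0 + 1, x0) * (1 - fx) * fy +
      gather(M, y0 + 1, x0 + 1) * fx * fy
    out[, , c] <- as.integer(clip255(round_half_away(interp)))
  }

  kept <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    env <- rotate_box_envelope(boxes[i, ], angle, W, H)
    x1 <- max(env[1], 0); y1 <- max(env[2], 0)
    x2 <- min(env[3], W); y2 <- min(env[4], H)
    if (x2 <= x1 || y2 <= y1) next
    orig_area <- (boxes$w[i] * W) * (boxes$h[i] * H)
    if ((x2 - x1) * (y2 - y1) < min_box_visibility * orig_area) next
    kept[[i]] <- norm_boxes(boxes$class_id[i],
                            cx = (x1 + x2) / 2 / W, cy = (y1 + y2) / 2 / H,
                            w = (x2 - x1) / W, h = (y2 - y1) / H)
  }
  kept <- kept[!vapply(kept, is.null, TRUE)]
  list(image = as_image_grid(out),
       boxes = if (length(kept)) do.call(rbind, kept) else norm_boxes())
}

#' Adjust brightness and contrast
#'
#' Per pixel, `clip(round(contrast * I + brightness), 0, 255)`. A purely
#' photometric transform: box coordinates are untouched.
#'
#' @param image An [image_grid()].
#' @param contrast Multiplicative factor (> 0).
#' @param brightness Additive offset in gray levels.
#' @return A new [image_grid()].
#' @export
adjust_brightness_contrast <- function(image, contrast = 1, brightness = 0) {
  stopifnot(inherits(image, "image_grid"))
  if (contrast <= 0) stop("contrast must be > 0")
  out <- unclass(image)
  out[] <- as.integer(clip255(round_half_away(contrast * as.numeric(out) + brightness)))
  as_image_grid(out)
}

#' Apply one conventional (whole-image) augmentation pass
#'
#' Applies, in order, optional rotation, optional brightness/contrast,
#' optional whole-image Gaussian blur, each with probability `p_apply` and
#' parameters drawn from the config ranges. If every probability draw
#' declines, one transform (chosen uniformly) is forced so the copy is
#' never identical to the original. Deterministic given `(seed, image_id,
#' copy)`. The names of the transforms actually applied are attached as
#' the `"applied"` attribute of the result.
#'
#' @param item A [labeled_image()].
#' @param config A [global_augment_config()].
#' @param copy Copy index used in seed derivation and the id suffix.
#' @param seed Base seed; defaults to `config$seed`.
#' @return A new [labeled_image()].
#' @export
conventional_augment_image <- function(item, config = global_augment_config(),
                                       copy = 1L, seed = config$seed) {
  stopifnot(inherits(item, "labeled_image"),
            inherits(config, "global_augment_config"))
  with_seed(derive_seed(seed, item$image_id, "conv", copy), {
    do_rot <- stats::runif(1) < config$p_apply
    do_pho <- stats::runif(1) < config$p_apply
    do_blur <- stats::runif(1) < config$p_apply
    if (!do_rot && !do_pho && !do_blur) {
      forced <- sample.int(3, 1)
      do_rot <- forced == 1; do_pho <- forced == 2; do_blur <- forced == 3
    }
    img <- item$image; boxes <- item$boxes
    if (do_rot) {
      angle <- stats::runif(1, -config$max_rotation_deg, config$max_rotation_deg)
      r <- rotate_image_and_boxes(img, boxes, angle, config$min_box_visibility)
      img <- r$image; boxes <- r$boxes
    }
    if (do_pho) {
      contrast <- stats::runif(1, config$contrast_factor_range[1],
                               config$contrast_factor_range[2])
      brightness <- stats::runif(1, -config$brightness_delta_range,
                                 config$brightness_delta_range)
      img <- adjust_brightness_contrast(img, contrast, brightness)
    }
    if (do_blur) {
      kernel <- make_gaussian_kernel(config$blur_kernel_size, config$blur_sigma)
      full <- matrix(TRUE, img_height(img), img_width(img))
      img <- blur_region(img, full, kernel)
    }
    out <- labeled_image(paste0(item$image_id, "_caug", copy), img, boxes)
    attr(out, "applied") <- c("rotation", "photometric", "blur")[
      c(do_rot, do_pho, do_blur)]
    out
  })
}

#' Conventionally augment a training split and merge with the originals
#'
#' Emits the originals unmodified followed by one conventional variant per
#' original (doubling the split), with per-image seeding as in
#' [augment_training_set()].
#'
#' @param train A list of [labeled_image()]s (non-empty).
#' @param config A [global_augment_config()].
#' @return A list of `2 * length(train)` items.
#' @export
conventional_augment_set <- function(train, config = global_augment_config()) {
  if (length(train) == 0) stop("training split is empty")
  c(train, lapply(train, conventional_augment_image, config = config))
}
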