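# Normalized bounding boxes and their pixel-space realization.
#
# A box set is a data.frame with columns class_id, cx, cy, w, h: centers and
# extents as fractions of image width/height (the normalized label
# convention used by single-stage detectors). Class 1 marks fracture
# regions, class 0 intact ("no fracture") regions in the rib-CT setting.

#' Construct a set of normalized bounding boxes
#'
#' @param class_id Non-negative integer class ids.
#' @param cx,cy Box centers as fractions of image width/height in \[0, 1\].
#' @param w,h Box extents as fractions in (0, 1\].
#' @return A validated `data.frame` with columns `class_id, cx, cy, w, h`.
#' @export
#' @examples
#' norm_boxes(1, 0.5, 0.5, 0.2, 0.1)
norm_boxes <- function(class_id = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric()) {
  b <- data.frame(class_id = as.integer(class_id), cx = as.numeric(cx),
                  cy = as.numeric(cy), w = as.numeric(w), h = as.numeric(h))
  validate_boxes(b)
}

#' Validate (and gently clamp) a box set
#'
#' Boxes whose extent overhangs \[0, 1\] by at most `slop` (annotation-tool
#' rounding) have their centers pulled inside; larger violations are errors.
#'
#' @param boxes A box `data.frame` (see [norm_boxes()]).
#' @param slop Maximum tolerated overhang before erroring (default 1e-6).
#' @return The validated box `data.frame`.
#' @export
validate_boxes <- function(boxes, slop = 1e-6) {
  stopifnot(is.data.frame(boxes))
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!all(need %in% names(boxes))) {
    stop("box set must have columns: ", paste(need, collapse = ", "))
  }
  b <- boxes[, need, drop = FALSE]
  if (nrow(b) == 0) return(b)
  if (any(!is.finite(as.matrix(b[-1]))) || any(is.na(b$class_id))) {
    stop("box coordinates must be finite")
  }
  if (any(b$class_id < 0 | b$class_id != floor(b$class_id))) {
    stop("class_id must be a non-negative integer")
  }
  if (any(b$w <= 0 | b$h <= 0)) stop("box extents w, h must be positive")
  if (any(b$w > 1 + slop | b$h > 1 + slop)) stop("box extents w, h must be <= 1")
  b$w <- pmin(b$w, 1)
  b$h <- pmin(b$h, 1)
  over <- pmax(b$w / 2 - b$cx, b$cx + b$w / 2 - 1,
               b$h / 2 - b$cy, b$cy + b$h / 2 - 1)
  if (any(over > slop)) {
    stop(sprintf("box %d overhangs the unit square by %.3g (> %g)",
                 which.max(over), max(over), slop))
  }
  # clamp center so the box sits inside [0,1]
  b$cx <- pmin(pmax(b$cx, b$w / 2), 1 - b$w / 2)
  b$cy <- pmin(pmax(b$cy, b$h / 2), 1 - b$h / 2)
  b
}

#' Convert a normalized box to integer pixel coordinates
#'
#' Uses floor/ceil expansion so the returned half-open pixel region
#' `[x1, x2) x [y1, y2)` (0-based) always fully covers the continuous box;
#' it can exceed it by less than one pixel per side. A small numeric guard
#' keeps boxes that land exactly on pixel boundaries from gaining a full
#' extra pixel through floating-point slop.
#'
#' @param box A single-row box `data.frame` or a list with `cx, cy, w, h`.
#' @param W,H Image width and height in pixels.
#' @return A list with integer fields `x1, y1, x2, y2` (0-based, half-open).
#' @export
#' @examples
#' to_pixel(norm_boxes(1, 0.5, 0.5, 0.25, 0.25), 640, 640)
to_pixel <- function(box, W, H) {
  stopifnot(W >= 1, H >= 1)
  eps <- 1e-7
  x1 <- max(0L, as.integer(floor((box$cx - box$w / 2) * W + eps)))
  x2 <- min(as.integer(W), as.integer(ceiling((box$cx + box$w / 2) * W - eps)))
  y1 <- max(0L, as.integer(floor((box$cy - box$h / 2) * H + eps)))
  y2 <- min(as.integer(H), as.integer(ceiling((box$cy + box$h / 2) * H - eps)))
  if (x1 >= x2 || y1 >= y2) {
    stop(sprintf("box maps to an empty pixel region on a %dx%d image", W, H))
  }
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# Inverse of to_pixel for boxes created in pixel space (phantom generator):
# converts a half-open pixel rectangle to a normalized box.
pixel_to_norm <- function(x1, y1, x2, y2, W, H, class_id = 0L) {
  norm_boxes(class_id = class_id,
             cx = (x1 + x2) / 2 / W, cy = (y1 + y2) / 2 / H,
             w = (x2 - x1) / W, h = (y2 - y1) / H)
}
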