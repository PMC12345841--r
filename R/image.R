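# 8-bit image rasters. Stored as an integer array with dim c(H, W, C),
# C in {1, 3}; values in [0, 255]. Grayscale stays single-channel; 3-channel
# inputs are kept as-is (no silent conversion).

#' Construct an 8-bit image grid
#'
#' @param values A numeric matrix (`H x W`, treated as single-channel) or an
#'   `H x W x C` array with `C` of 1 or 3, all values integers in \[0, 255\].
#' @return An integer array of dim `c(H, W, C)` with class `image_grid`.
#' @export
#' @examples
#' img <- image_grid(matrix(0L, 64, 64))
image_grid <- function(values) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L || !dim(values)[3] %in% c(1L, 3L)) {
    stop("image must be H x W or H x W x C with C in {1, 3}")
  }
  if (dim(values)[1] < 8L || dim(values)[2] < 8L) {
    stop("image must be at least 8 x 8 pixels")
  }
  v <- as.numeric(values)
  if (any(!is.finite(v)) || any(v < 0 | v > 255) || any(v != floor(v))) {
    stop("pixel values must be integers in [0, 255]")
  }
  storage.mode(values) <- "integer"
  class(values) <- c("image_grid", class(values))
  values
}

img_height <- function(img) dim(img)[1]
img_width  <- function(img) dim(img)[2]
img_channels <- function(img) dim(img)[3]

# re-wrap a plain integer array produced by arithmetic
as_image_grid <- function(values) {
  storage.mode(values) <- "integer"
  if (!inherits(values, "image_grid")) class(values) <- c("image_grid", class(values))
  values
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d x %d, range [%d, %d]>\n",
              dim(x)[1], dim(x)[2], dim(x)[3], min(x), max(x)))
  invisible(x)
}

#' Read an image file into an `image_grid`
#'
#' PNG files are read with the \pkg{png} package; JPEG files require the
#' \pkg{EBImage} package (JPEG is supported read-only, since augmented
#' outputs must be lossless). Alpha channels are dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [image_grid()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package; convert to PNG instead")
    }
    e <- EBImage::readImage(path)
    x <- EBImage::imageData(e)
    if (length(dim(x)) >= 2) {
      # EBImage stores x,y(,c); transpose to row = y
      x <- if (length(dim(x)) == 2) t(x) else aperm(x, c(2, 1, 3))
    }
  } else {
    stop("unsupported image format: .", ext)
  }
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 2L) x <- x[, , 1L, drop = FALSE]          # gray + alpha
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]          # rgb + alpha
  image_grid(array(as.integer(round(x * 255)), dim = dim(x)))
}

#' Write an `image_grid` to a PNG file (lossless)
#'
#' @param img An [image_grid()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  x <- unclass(img) / 255
  if (dim(x)[3] == 1L) x <- x[, , 1L] # writePNG writes grayscale for a matrix
  png::writePNG(x, target = path)
  invisible(path)
}
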