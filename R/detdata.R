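# Detection datasets on disk: one plain-text label file per image in the
# normalized "class cx cy w h" dialect, images as PNG (JPEG read-only), and
# a YAML manifest naming the class set and the split directories. Mirrors
# the layout single-stage detector tooling consumes: each split's image
# directory has a sibling "labels" directory with one .txt per image.

#' Parse a normalized label file
#'
#' Each non-empty line must hold 5 whitespace-separated numeric tokens:
#' `class cx cy w h`, with coordinates as fractions of the image size.
#'
#' @param text The file contents as a single string (or vector of lines).
#' @return A box `data.frame` (see [norm_boxes()]), one row per line, in
#'   file order.
#' @export
#' @examples
#' parse_label_file("1 0.5 0.5 0.2 0.1")
parse_label_file <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- vector("list", length(lines))
  kept <- logical(length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) != 5L) {
      stop(sprintf("label line %d: expected 5 tokens, got %d", i, length(toks)))
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) stop(sprintf("label line %d: non-numeric token", i))
    row <- tryCatch(
      norm_boxes(vals[1], vals[2], vals[3], vals[4], vals[5]),
      error = function(e) stop(sprintf("label line %d: %s", i, conditionMessage(e)),
                               call. = FALSE)
    )
    out[[i]] <- row
    kept[i] <- TRUE
  }
  if (!any(kept)) return(norm_boxes())
  do.call(rbind, out[kept])
}

#' Serialize boxes to the normalized label dialect
#'
#' Space-separated, 6-decimal fixed point, one box per line, `"\n"`
#' terminated. `parse_label_file(write_label_file(b))` reproduces `b` with
#' coordinates equal to 6 decimal places.
#'
#' @param boxes A box `data.frame`.
#' @return A single string; `""` for an empty box set.
#' @export
write_label_file <- function(boxes) {
  boxes <- validate_boxes(boxes)
  if (nrow(boxes) == 0) return("")
  paste0(paste(sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                       boxes$cx, boxes$cy, boxes$w, boxes$h),
               collapse = "\n"), "\n")
}

#' Bundle an image with its boxes
#'
#' @param image_id Unique string identifier (used as the file stem on disk).
#' @param image An [image_grid()].
#' @param boxes A box `data.frame`; may be empty.
#' @return A `labeled_image` list.
#' @export
labeled_image <- function(image_id, image, boxes = norm_boxes()) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            inherits(image, "image_grid"))
  structure(list(image_id = image_id, image = image,
                 boxes = validate_boxes(boxes)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image '%s': %dx%d, %d box(es)>\n", x$image_id,
              img_height(x$image), img_width(x$image), nrow(x$boxes)))
  invisible(x)
}

#' Assemble a detection dataset
#'
#' @param class_names Named character vector mapping class id (as name) to
#'   class label, e.g. `c("0" = "no_fracture", "1" = "fracture")`.
#' @param splits Named list of `labeled_image` lists; names drawn from
#'   `train`, `val`, `test`.
#' @return A `det_dataset` list.
#' @export
det_dataset <- function(class_names, splits) {
  stopifnot(is.character(class_names), !is.null(names(class_names)))
  if (!all(names(splits) %in% c("train", "val", "test"))) {
    stop("split names must be among train, val, test")
  }
  ids <- unlist(lapply(splits, function(s) vapply(s, `[[`, "", "image_id")))
  if (anyDuplicated(ids)) stop("image_id values must be unique across the dataset")
  declared <- as.integer(names(class_names))
  for (s in splits) for (it in s) {
    if (!all(it$boxes$class_id %in% declared)) {
      stop(sprintf("image '%s' references a class id not in class_names", it$image_id))
    }
  }
  structure(list(class_names = class_names, splits = splits),
            class = "det_dataset")
}

#' @export
print.det_dataset <- function(x, ...) {
  cat("<det_dataset>\n  classes:",
      paste(sprintf("%s=%s", names(x$class_names), x$class_names), collapse = ", "),
      "\n")
  for (s in names(x$splits)) {
    cat(sprintf("  %s: %d image(s)\n", s, length(x$splits[[s]])))
  }
  invisible(x)
}

#' Randomly split items into train/val/test
#'
#' Shuffles indices with a seeded generator and slices: the first
#' `round(n * f_train)` items go to train, the next `round(n * f_val)` to
#' val, the remainder to test. Deterministic given `seed`; the three parts
#' are disjoint and exhaustive.
#'
#' @param items A list (typically of `labeled_image`s).
#' @param fractions Numeric triple summing to 1 (default `c(0.7, 0.2, 0.1)`).
#' @param seed Integer seed.
#' @return A named list `list(train = , val = , test = )`.
#' @export
#' @examples
#' split_dataset(as.list(1:10), c(0.7, 0.2, 0.1), seed = 1)
split_dataset <- function(items, fractions = c(0.7, 0.2, 0.1), seed = 0L) {
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("fractions must be 3 positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(items)
  n_train <- as.integer(round_half_away(n * fractions[1]))
  n_val <- as.integer(round_half_away(n * fractions[2]))
  if (n_train + n_val > n) stop("rounded split counts exceed the item count")
  perm <- with_seed(seed, sample.int(n))
  list(train = items[perm[seq_len(n_train)]],
       val = items[perm[n_train + seq_len(n_val)]],
       test = items[perm[setdiff(seq_len(n), seq_len(n_train + n_val))]])
}

label_dir_for <- function(image_dir) {
  parts <- strsplit(image_dir, "/", fixed = TRUE)[[1]]
  hit <- which(parts == "images")
  if (length(hit) == 0) return(file.path(dirname(image_dir), "labels"))
  parts[max(hit)] <- "labels"
  paste(parts, collapse = "/")
}

#' Load a detection dataset from disk
#'
#' Expects `root/manifest.yaml` with keys `names` (class id to name) and any
#' of `train`/`val`/`test` giving image-directory paths relative to `root`;
#' labels live in the parallel `labels` directory. An image without a label
#' file gets an empty box set.
#'
#' @param root Dataset root directory.
#' @return A [det_dataset()].
#' @export
load_dataset <- function(root) {
  manifest_path <- file.path(root, "manifest.yaml")
  if (!file.exists(manifest_path)) stop("no manifest.yaml under ", root)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$names)) stop("manifest lacks a 'names' mapping")
  class_names <- vapply(man$names, as.character, "")
  splits <- list()
  for (s in intersect(c("train", "val", "test"), names(man))) {
    img_dir <- file.path(root, man[[s]])
    if (!dir.exists(img_dir)) stop("manifest names a missing split directory: ", img_dir)
    lab_dir <- label_dir_for(img_dir)
    files <- sort(list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE))
    items <- vector("list", length(files))
    for (i in seq_along(files)) {
      id <- tools::file_path_sans_ext(files[i])
      lab_path <- file.path(lab_dir, paste0(id, ".txt"))
      boxes <- if (file.exists(lab_path)) {
        parse_label_file(readLines(lab_path, warn = FALSE))
      } else {
        norm_boxes()
      }
      if (!all(boxes$class_id %in% as.integer(names(class_names)))) {
        stop(sprintf("label for '%s' references a class id not in the manifest", id))
      }
      items[[i]] <- labeled_image(id, read_image(file.path(img_dir, files[i])), boxes)
    }
    splits[[s]] <- items
  }
  det_dataset(class_names, splits)
}

#' Save a detection dataset to disk
#'
#' Writes PNG images (lossless, so `save_dataset()` then [load_dataset()]
#' round-trips pixel values and boxes exactly), label files, and a
#' `manifest.yaml`.
#'
#' @param ds A [det_dataset()].
#' @param root Output root directory (created if needed).
#' @return `root`, invisibly.
#' @export
save_dataset <- function(ds, root) {
  stopifnot(inherits(ds, "det_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  man <- list(names = as.list(stats::setNames(as.vector(ds$class_names),
                                              names(ds$class_names))))
  for (s in names(ds$splits)) {
    img_dir <- file.path(root, s, "images")
    lab_dir <- file.path(root, s, "labels")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
    for (it in ds$splits[[s]]) {
      write_image(it$image, file.path(img_dir, paste0(it$image_id, ".png")))
      cat(write_label_file(it$boxes),
          file = file.path(lab_dir, paste0(it$image_id, ".txt")))
    }
    man[[s]] <- file.path(s, "images")
  }
  yaml::write_yaml(man, file.path(root, "manifest.yaml"))
  invisible(root)
}

#' Ground-truth boxes per image id for one split
#'
#' Extracts the box frames of a split keyed by image id, the shape the
#' evaluation engine consumes.
#'
#' @param ds A [det_dataset()].
#' @param split Split name (default `"test"`).
#' @return A named list of box `data.frame`s.
#' @export
gts_from_split <- function(ds, split = "test") {
  items <- ds$splits[[split]]
  if (is.null(items)) stop("dataset has no split '", split, "'")
  stats::setNames(lapply(items, `[[`, "boxes"),
                  vapply(items, `[[`, "", "image_id"))
}
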