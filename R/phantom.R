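# Synthetic CT-like phantoms: a dark noisy background with bright curved
# bands (schematic rib cross-sections) arranged symmetrically about the
# vertical midline. A band may carry a gap defect (darkened break),
# tightly boxed as class 1 (fracture); intact band segments are boxed as
# class 0 (no fracture), which are more prevalent in expectation -- the
# class imbalance of clinical rib-CT data. The phantoms are schematic, not
# anatomically faithful: they exist to exercise geometry, contrast, and
# imbalance in the augmentation and evaluation code.

#' Configuration for phantom generation
#'
#' @param image_size Square image side in pixels (default 640, the
#'   resolution of the emulated CT slices; minimum 64).
#' @param n_rib_bands Number of bright curved bands (default 8).
#' @param fracture_prob_per_band Probability that a band carries a gap
#'   defect (default 0.3).
#' @param background_noise_std Additive background noise standard
#'   deviation in gray levels (default 5).
#' @param seed Integer base seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 640L, n_rib_bands = 8L,
                           fracture_prob_per_band = 0.3,
                           background_noise_std = 5, seed = 0L) {
  if (image_size < 64) stop("image_size must be >= 64")
  if (fracture_prob_per_band < 0 || fracture_prob_per_band > 1) {
    stop("fracture_prob_per_band must be in [0, 1]")
  }
  if (background_noise_std < 0) stop("background_noise_std must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_rib_bands = as.integer(n_rib_bands),
                 fracture_prob_per_band = fracture_prob_per_band,
                 background_noise_std = background_noise_std,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Configuration for the simulated detector
#'
#' A test double for a trained detector: it reproduces ground truths with
#' controllable miss rate, localization jitter and false-positive rate, so
#' evaluation metrics have known expected values. True-positive
#' confidences are kept above false-positive confidences so
#' precision-recall curves are non-degenerate.
#'
#' @param miss_rate Probability a ground truth goes undetected.
#' @param fp_per_image Expected Poisson count of false boxes per image.
#' @param loc_jitter_std Localization jitter std as a fraction of box size.
#' @param tp_conf_range Confidence interval for true detections.
#' @param fp_conf_range Confidence interval for false boxes; must lie
#'   below `tp_conf_range`.
#' @param seed Integer base seed.
#' @return A `detector_sim_config` list.
#' @export
detector_sim_config <- function(miss_rate = 0.2, fp_per_image = 1.0,
                                loc_jitter_std = 0.05,
                                tp_conf_range = c(0.60, 0.95),
                                fp_conf_range = c(0.05, 0.40), seed = 0L) {
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must be in [0, 1]")
  if (fp_per_image < 0) stop("fp_per_image must be >= 0")
  if (loc_jitter_std < 0) stop("loc_jitter_std must be >= 0")
  rng_ok <- function(r) length(r) == 2 && all(r >= 0 & r <= 1) && r[1] <= r[2]
  if (!rng_ok(tp_conf_range) || !rng_ok(fp_conf_range)) {
    stop("confidence ranges must be ordered subintervals of [0, 1]")
  }
  if (tp_conf_range[1] < fp_conf_range[2]) {
    stop("tp_conf_range must lie above fp_conf_range")
  }
  structure(list(miss_rate = miss_rate, fp_per_image = fp_per_image,
                 loc_jitter_std = loc_jitter_std,
                 tp_conf_range = tp_conf_range, fp_conf_range = fp_conf_range,
                 seed = as.integer(seed)),
            class = "detector_sim_config")
}

#' Generate one synthetic CT-like phantom
#'
#' Deterministic given `(config$seed, image_id)`. Gap defects are darkened
#' well below the band intensity, so the mean intensity inside a fracture
#' box is below that of the flanking band; fracture boxes carry a 2-pixel
#' margin around the gap so floor/ceil pixelization never truncates the
#' defect.
#'
#' @param config A [phantom_config()].
#' @param image_id Identifier for the emitted [labeled_image()] (also
#'   salts the RNG stream).
#' @return A [labeled_image()] with class-1 (fracture) and class-0
#'   (intact segment) boxes.
#' @export
generate_phantom <- function(config = phantom_config(), image_id = "phantom_0001") {
  stopifnot(inherits(config, "phantom_config"))
  S <- config$image_size
  with_seed(derive_seed(config$seed, image_id), {
    M <- matrix(25 + stats::rnorm(S * S, sd = config$background_noise_std), S, S)
    thick <- max(3L, as.integer(round(S / 64)))
    gap_hw <- max(2L, as.integer(round(S / 80)))
    amp <- 0.05 * S
    y_centers <- seq(0.12 * S, 0.82 * S, length.out = config$n_rib_bands)
    boxes <- list()
    xs <- seq_len(S)
    arc <- amp * sin(pi * (xs - 0.5) / S) # symmetric about the midline
    for (b in seq_len(config$n_rib_bands)) {
      level <- stats::runif(1, 155, 185)
      yc <- as.integer(round(y_centers[b] - arc))
      band_rows <- function(x1, x2) { # inclusive pixel columns
        cols <- x1:x2
        list(top = pmax(1L, yc[cols]), cols = cols)
      }
      # paint the band
      for (dt in 0:(thick - 1L)) {
        rr <- pmin(S, pmax(1L, yc + dt))
        M[cbind(rr, xs)] <- level + stats::rnorm(S, sd = 3)
      }
      has_gap <- stats::runif(1) < config$fracture_prob_per_band
      gap_cols <- integer()
      if (has_gap) {
        xg <- as.integer(round(stats::runif(1, 0.15 * S, 0.85 * S)))
        gap_cols <- max(1L, xg - gap_hw):min(S, xg + gap_hw)
        for (dt in 0:(thick - 1L)) {
          rr <- pmin(S, pmax(1L, yc[gap_cols] + dt))
          M[cbind(rr, gap_cols)] <- 35 + stats::rnorm(length(gap_cols), sd = 3)
        }
        x1 <- max(0L, min(gap_cols) - 1L - 2L) # 0-based with 2 px margin
        x2 <- min(S, max(gap_cols) + 2L)
        y1 <- max(0L, min(yc[gap_cols]) - 1L - 2L)
        y2 <- min(S, max(yc[gap_cols]) + thick - 1L + 2L)
        boxes[[length(boxes) + 1L]] <- pixel_to_norm(x1, y1, x2, y2, S, S, 1L)
      }
      # 1-2 intact segments boxed as class 0, kept clear of the gap
      n0 <- 1L + (stats::runif(1) < 0.5)
      seg_hw <- 2L * gap_hw
      for (k in seq_len(n0)) {
        for (try in 1:20) {
          xc <- as.integer(round(stats::runif(1, 0.1 * S, 0.9 * S)))
          if (length(gap_cols) == 0 ||
              abs(xc - mean(gap_cols)) > (seg_hw + 3L * gap_hw)) break
        }
        cols <- max(1L, xc - seg_hw):min(S, xc + seg_hw)
        x1 <- max(0L, min(cols) - 1L - 2L)
        x2 <- min(S, max(cols) + 2L)
        y1 <- max(0L, min(yc[cols]) - 1L - 2L)
        y2 <- min(S, max(yc[cols]) + thick - 1L + 2L)
        boxes[[length(boxes) + 1L]] <- pixel_to_norm(x1, y1, x2, y2, S, S, 0L)
      }
    }
    img <- image_grid(matrix(as.integer(clip255(round_half_away(M))), S, S))
    labeled_image(image_id, img,
                  if (length(boxes)) do.call(rbind, boxes) else norm_boxes())
  })
}

#' Generate a phantom detection dataset
#'
#' `n_images` phantoms with sequential ids, split 70/20/10 (train/val/test)
#' with [split_dataset()]. Classes: 0 = no_fracture, 1 = fracture.
#'
#' @param n_images Number of phantoms (>= 1).
#' @param config A [phantom_config()].
#' @param fractions Split fractions; default `c(0.7, 0.2, 0.1)`.
#' @return A [det_dataset()].
#' @export
generate_dataset <- function(n_images, config = phantom_config(),
                             fractions = c(0.7, 0.2, 0.1)) {
  stopifnot(n_images >= 1)
  items <- lapply(seq_len(n_images), function(i) {
    generate_phantom(config, sprintf("phantom_%04d", i))
  })
  det_dataset(c("0" = "no_fracture", "1" = "fracture"),
              split_dataset(items, fractions,
                            seed = derive_seed(config$seed, "split")))
}

#' Simulate an imperfect detector over ground-truth boxes
#'
#' Each ground truth is emitted with probability `1 - miss_rate`, its
#' center and size jittered by `loc_jitter_std` (as a fraction of the box
#' size), with confidence uniform in `tp_conf_range`; `Poisson(fp_per_image)`
#' false boxes are placed uniformly with confidence in `fp_conf_range`.
#' Deterministic given `(seed, image_id)`.
#'
#' @param gts_by_image Named list (by image id) of ground-truth box frames.
#' @param sim A [detector_sim_config()].
#' @return A named list of [detections()] frames, aligned to
#'   `names(gts_by_image)`.
#' @export
simulate_detections <- function(gts_by_image, sim = detector_sim_config()) {
  stopifnot(inherits(sim, "detector_sim_config"))
  all_classes <- sort(unique(unlist(lapply(gts_by_image, function(g) g$class_id))))
  if (length(all_classes) == 0) all_classes <- 0L
  out <- stats::setNames(vector("list", length(gts_by_image)), names(gts_by_image))
  for (id in names(gts_by_image)) {
    out[[id]] <- with_seed(derive_seed(sim$seed, "simdet", id), {
      g <- gts_by_image[[id]]
      rows <- list()
      for (i in seq_len(nrow(g))) {
        if (stats::runif(1) >= 1 - sim$miss_rate) next
        j <- sim$loc_jitter_std
        w <- max(0.004, min(1, g$w[i] * (1 + stats::rnorm(1, sd = j))))
        h <- max(0.004, min(1, g$h[i] * (1 + stats::rnorm(1, sd = j))))
        cx <- min(max(g$cx[i] + stats::rnorm(1, sd = j) * g$w[i], w / 2), 1 - w / 2)
        cy <- min(max(g$cy[i] + stats::rnorm(1, sd = j) * g$h[i], h / 2), 1 - h / 2)
        conf <- stats::runif(1, sim$tp_conf_range[1], sim$tp_conf_range[2])
        rows[[length(rows) + 1L]] <- detections(g$class_id[i], conf, cx, cy, w, h)
      }
      n_fp <- stats::rpois(1, sim$fp_per_image)
      for (k in seq_len(n_fp)) {
        w <- stats::runif(1, 0.03, 0.10); h <- stats::runif(1, 0.03, 0.10)
        cx <- stats::runif(1, w / 2, 1 - w / 2)
        cy <- stats::runif(1, h / 2, 1 - h / 2)
        cls <- sample(all_classes, 1)
        conf <- stats::runif(1, sim$fp_conf_range[1], sim$fp_conf_range[2])
        rows[[length(rows) + 1L]] <- detections(cls, conf, cx, cy, w, h)
      }
      if (length(rows)) do.call(rbind, rows) else detections()
    })
  }
  out
}
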