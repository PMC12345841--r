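# Detector evaluation from scratch: IoU matching, precision/recall sweeps,
# 101-point interpolated average precision (the COCO convention), mAP@50
# and mAP@50-95, F1-confidence curves, and the percent-change comparison
# arithmetic used to contrast two augmentation strategies.

#' Construct a set of detections
#'
#' @param class_id Integer class ids.
#' @param confidence Scores in \[0, 1\].
#' @param cx,cy,w,h Normalized box coordinates (see [norm_boxes()]).
#' @return A `data.frame` with columns
#'   `class_id, confidence, cx, cy, w, h`.
#' @export
detections <- function(class_id = integer(), confidence = numeric(),
                       cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric()) {
  if (any(confidence < 0 | confidence > 1)) stop("confidence must be in [0, 1]")
  b <- norm_boxes(class_id, cx, cy, w, h)
  cbind(b[, "class_id", drop = FALSE], confidence = as.numeric(confidence),
        b[, c("cx", "cy", "w", "h")])
}

#' Intersection over union of two normalized boxes
#'
#' Closed-form axis-aligned rectangle overlap in continuous normalized
#' coordinates; 0 for disjoint boxes. Class ids are ignored.
#'
#' @param a,b Single-row box `data.frame`s or lists with `cx, cy, w, h`.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' iou(norm_boxes(1, .5, .5, .2, .2), norm_boxes(1, .5, .5, .2, .2)) # 1
iou <- function(a, b) {
  ix <- min(a$cx + a$w / 2, b$cx + b$w / 2) - max(a$cx - a$w / 2, b$cx - b$w / 2)
  iy <- min(a$cy + a$h / 2, b$cy + b$h / 2) - max(a$cy - a$h / 2, b$cy - b$h / 2)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Greedily match detections to ground truths at an IoU threshold
#'
#' Detections are processed in descending confidence (ties by input order);
#' each is a true positive if its best-IoU unmatched same-class ground
#' truth reaches `iou_thr` (that ground truth then becomes matched), else a
#' false positive. Each ground truth matches at most once.
#'
#' @param dets A [detections()] `data.frame` for one image.
#' @param gts A box `data.frame` of ground truths for the same image.
#' @param iou_thr IoU threshold in (0, 1\].
#' @return A logical vector of TP flags aligned to the input row order of
#'   `dets`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  n <- nrow(dets)
  tp <- logical(n)
  if (n == 0) return(tp)
  ord <- order(-dets$confidence) # stable: ties keep input order
  matched <- logical(nrow(gts))
  for (d in ord) {
    best <- 0; best_g <- 0L
    for (g in seq_len(nrow(gts))) {
      if (matched[g] || gts$class_id[g] != dets$class_id[d]) next
      o <- iou(dets[d, ], gts[g, ])
      if (o > best) { best <- o; best_g <- g }
    }
    if (best_g > 0L && best >= iou_thr) {
      tp[d] <- TRUE
      matched[best_g] <- TRUE
    }
  }
  tp
}

#' Precision-recall curve from pooled TP flags
#'
#' Sorts by descending confidence (ties by input order) and accumulates
#' TP/FP counts; one curve point per detection.
#'
#' @param tp Logical TP flags.
#' @param confidence Matching confidence scores.
#' @param n_gt Number of ground-truth objects (>= 1).
#' @return A `pr_curve` list with `thresholds`, `precision`, `recall`,
#'   `n_gt`.
#' @export
pr_curve <- function(tp, confidence, n_gt) {
  stopifnot(length(tp) == length(confidence), n_gt >= 1)
  ord <- order(-confidence)
  tp <- tp[ord]; conf <- confidence[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  structure(list(thresholds = conf,
                 precision = if (length(tp)) ctp / (ctp + cfp) else numeric(),
                 recall = if (length(tp)) ctp / n_gt else numeric(),
                 n_gt = as.integer(n_gt)),
            class = "pr_curve")
}

#' 101-point interpolated average precision
#'
#' Builds the cumulative precision/recall sweep over descending confidence,
#' takes the precision envelope (the maximum precision at recall at least
#' r), and averages the envelope at the 101 recall points 0, 0.01, ..., 1.
#'
#' @param tp Logical TP flags (pooled over images for one class).
#' @param confidence Matching confidence scores.
#' @param n_gt Number of ground-truth objects (>= 1).
#' @return AP in \[0, 1\].
#' @export
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), c(.9, .8, .7), n_gt = 2) # ~0.835
average_precision <- function(tp, confidence, n_gt) {
  stopifnot(n_gt >= 1)
  if (length(tp) == 0) return(0)
  pc <- pr_curve(tp, confidence, n_gt)
  grid <- seq(0, 1, by = 0.01)
  ap <- 0
  for (r in grid) {
    sel <- pc$recall >= r - 1e-9
    ap <- ap + if (any(sel)) max(pc$precision[sel]) else 0
  }
  ap / length(grid)
}

#' Operating point at maximum F1
#'
#' Scans a precision-recall curve for the point maximizing
#' `F1 = 2PR / (P + R)`; ties are broken toward higher confidence.
#'
#' @param curve A [pr_curve()].
#' @return `list(precision = , recall = , confidence = , f1 = )`.
#' @export
pr_at_max_f1 <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  if (length(curve$thresholds) == 0) {
    return(list(precision = 0, recall = 0, confidence = 1, f1 = 0))
  }
  denom <- curve$precision + curve$recall
  f1 <- ifelse(denom > 0, 2 * curve$precision * curve$recall / denom, 0)
  i <- which.max(f1) # first (= highest-confidence) maximum
  list(precision = curve$precision[i], recall = curve$recall[i],
       confidence = curve$thresholds[i], f1 = f1[i])
}

#' F1 as a function of the confidence cutoff
#'
#' For each grid confidence, keeps detections with confidence at or above
#' it and reports the resulting F1 (0 when nothing survives the cutoff).
#'
#' @param curve A [pr_curve()].
#' @param grid Confidence cutoffs in \[0, 1\].
#' @return A `data.frame` with columns `confidence`, `f1`.
#' @export
f1_confidence_curve <- function(curve, grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(curve, "pr_curve"), all(grid >= 0 & grid <= 1))
  f1 <- vapply(grid, function(g) {
    sel <- which(curve$thresholds >= g - 1e-12)
    if (length(sel) == 0) return(0)
    i <- max(sel) # lowest surviving threshold = all detections above cutoff
    p <- curve$precision[i]; r <- curve$recall[i]
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  data.frame(confidence = grid, f1 = f1)
}

#' Plot an F1-confidence curve
#'
#' @param curves A named list of [f1_confidence_curve()] data frames (one
#'   line each).
#' @param main Plot title.
#' @return Invisibly, `NULL`. Draws on the active graphics device.
#' @export
plot_f1_confidence <- function(curves, main = "F1-confidence curve") {
  if (is.data.frame(curves)) curves <- list(curves)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "confidence", ylab = "F1", main = main)
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$confidence, curves[[i]]$f1, col = i, lwd = 2)
  }
  if (!is.null(names(curves))) {
    graphics::legend("bottomleft", legend = names(curves),
                     col = seq_along(curves), lwd = 2, bty = "n")
  }
  invisible(NULL)
}

#' Evaluate detections against ground truth
#'
#' Per class and per IoU threshold, TP/FP flags are pooled over images
#' before the precision-recall sweep. `ap50_95` averages AP over the 10
#' thresholds 0.50, 0.55, ..., 0.95; `map50`/`map50_95` are macro means
#' over classes present in the ground truth. Scalar precision/recall per
#' class are taken at the maximum-F1 confidence of the IoU-0.50 curve (the
#' convention behind reported detector P/R); a class with no detections
#' gets precision 0 and recall 0. Detections for classes absent from the
#' ground truth are skipped with a warning.
#'
#' @param dets_by_image Named list (by image id) of [detections()] frames.
#' @param gts_by_image Named list (by image id) of ground-truth box frames;
#'   must cover every image id in `dets_by_image`.
#' @param iou_thresholds IoU thresholds; default `seq(0.5, 0.95, 0.05)`.
#' @return An `eval_report` list: `per_class` data.frame (`class_id, n_gt,
#'   precision, recall, f1, confidence, ap50, ap50_95`), `ap_by_iou`
#'   matrix (class x threshold), `curves` (per-class IoU-0.50 [pr_curve()]),
#'   `map50`, `map50_95`.
#' @export
evaluate <- function(dets_by_image, gts_by_image,
                     iou_thresholds = seq(0.50, 0.95, by = 0.05)) {
  if (length(gts_by_image) == 0) stop("ground truth collection is empty")
  extra <- setdiff(names(dets_by_image), names(gts_by_image))
  if (length(extra)) {
    stop("detections for image ids absent from ground truth: ",
         paste(extra, collapse = ", "))
  }
  gt_classes <- sort(unique(unlist(lapply(gts_by_image, function(g) g$class_id))))
  if (length(gt_classes) == 0) stop("ground truth collection has no boxes")
  det_classes <- unique(unlist(lapply(dets_by_image, function(d) d$class_id)))
  orphan <- setdiff(det_classes, gt_classes)
  if (length(orphan)) {
    warning("detections for class(es) with no ground truth skipped: ",
            paste(orphan, collapse = ", "))
  }
  image_ids <- sort(names(gts_by_image))
  thr_lab <- sprintf("%.2f", iou_thresholds)
  ap_by_iou <- matrix(0, length(gt_classes), length(iou_thresholds),
                      dimnames = list(gt_classes, thr_lab))
  per_class <- data.frame(class_id = gt_classes, n_gt = 0L, precision = 0,
                          recall = 0, f1 = 0, confidence = NA_real_,
                          ap50 = 0, ap50_95 = 0)
  curves <- stats::setNames(vector("list", length(gt_classes)),
                            as.character(gt_classes))
  for (ci in seq_along(gt_classes)) {
    cls <- gt_classes[ci]
    n_gt <- sum(vapply(gts_by_image, function(g) sum(g$class_id == cls), 0L))
    per_class$n_gt[ci] <- n_gt
    for (ti in seq_along(iou_thresholds)) {
      tp_all <- logical(); conf_all <- numeric()
      for (id in image_ids) {
        dets <- dets_by_image[[id]]
        if (is.null(dets) || nrow(dets) == 0) next
        dsel <- dets[dets$class_id == cls, , drop = FALSE]
        if (nrow(dsel) == 0) next
        gsel <- gts_by_image[[id]]
        gsel <- gsel[gsel$class_id == cls, , drop = FALSE]
        tp_all <- c(tp_all, match_detections(dsel, gsel, iou_thresholds[ti]))
        conf_all <- c(conf_all, dsel$confidence)
      }
      ap_by_iou[ci, ti] <- if (n_gt >= 1) {
        average_precision(tp_all, conf_all, n_gt)
      } else 0
      if (abs(iou_thresholds[ti] - 0.5) < 1e-9 && n_gt >= 1) {
        curves[[ci]] <- pr_curve(tp_all, conf_all, n_gt)
        if (length(tp_all)) {
          op <- pr_at_max_f1(curves[[ci]])
          per_class$precision[ci] <- op$precision
          per_class$recall[ci] <- op$recall
          per_class$f1[ci] <- op$f1
          per_class$confidence[ci] <- op$confidence
        }
      }
    }
    per_class$ap50[ci] <- ap_by_iou[ci, which(abs(iou_thresholds - 0.5) < 1e-9)]
    per_class$ap50_95[ci] <- mean(ap_by_iou[ci, ])
  }
  structure(list(per_class = per_class, ap_by_iou = ap_by_iou, curves = curves,
                 iou_thresholds = iou_thresholds,
                 map50 = mean(per_class$ap50),
                 map50_95 = mean(per_class$ap50_95)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: mAP@50 = %.4f, mAP@50-95 = %.4f>\n",
              x$map50, x$map50_95))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Signed percent change of a metric between two runs
#'
#' `100 * (v_new - v_old) / v_old`, rounded to 2 decimals and rendered with
#' an explicit sign and a percent mark, the format of detector comparison
#' tables.
#'
#' @param v_new,v_old Metric values; `v_old` must be positive.
#' @return A string such as `"+0.99%"`.
#' @export
#' @examples
#' relative_change(0.921, 0.912)
relative_change <- function(v_new, v_old) {
  if (v_old <= 0) stop("reference value must be > 0")
  sprintf("%+.2f%%", 100 * (v_new - v_old) / v_old)
}

#' Comparison table between two evaluation reports
#'
#' Emits the standard report layout: one row per aggregate mAP metric, then
#' per-class precision and recall rows, each with the signed percent change
#' of run A relative to run B.
#'
#' @param report_a,report_b `eval_report`s over the same class set
#'   (conventionally A = focused augmentation, B = baseline).
#' @param model_label Free-text label for the model column.
#' @return A `data.frame` with columns `model, metric, class_id, value_a,
#'   value_b, percent_change`.
#' @export
compare_runs <- function(report_a, report_b, model_label = "model") {
  stopifnot(inherits(report_a, "eval_report"), inherits(report_b, "eval_report"))
  if (!identical(report_a$per_class$class_id, report_b$per_class$class_id)) {
    stop("reports cover different class sets")
  }
  rows <- list(
    data.frame(model = model_label, metric = "mAP50", class_id = NA_integer_,
               value_a = report_a$map50, value_b = report_b$map50,
               percent_change = relative_change(report_a$map50, report_b$map50)),
    data.frame(model = model_label, metric = "mAP50-95", class_id = NA_integer_,
               value_a = report_a$map50_95, value_b = report_b$map50_95,
               percent_change = relative_change(report_a$map50_95, report_b$map50_95))
  )
  for (i in seq_len(nrow(report_a$per_class))) {
    for (metric in c("precision", "recall")) {
      va <- report_a$per_class[[metric]][i]
      vb <- report_b$per_class[[metric]][i]
      rows[[length(rows) + 1L]] <- data.frame(
        model = model_label, metric = metric,
        class_id = report_a$per_class$class_id[i],
        value_a = va, value_b = vb,
        percent_change = if (vb > 0) relative_change(va, vb) else NA_character_)
    }
  }
  do.call(rbind, rows)
}

#' Read per-image detection files
#'
#' One `.txt` per image with lines `class confidence cx cy w h`
#' (normalized coordinates).
#'
#' @param dir Directory of detection files.
#' @return A named list (by file stem) of [detections()] frames.
#' @export
read_detections_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$"))
  out <- stats::setNames(vector("list", length(files)),
                         tools::file_path_sans_ext(files))
  for (i in seq_along(files)) {
    lines <- readLines(file.path(dir, files[i]), warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      out[[i]] <- detections()
      next
    }
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    if (any(lengths(toks) != 6L)) {
      stop("detection file ", files[i], ": expected 6 tokens per line")
    }
    m <- matrix(as.numeric(unlist(toks)), ncol = 6, byrow = TRUE)
    out[[i]] <- detections(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])
  }
  out
}

#' Write per-image detection files
#'
#' @param dets_by_image Named list of [detections()] frames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_detections_dir <- function(dets_by_image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dets_by_image)) {
    d <- dets_by_image[[id]]
    txt <- if (nrow(d) == 0) "" else {
      paste0(paste(sprintf("%d %.6f %.6f %.6f %.6f %.6f", d$class_id,
                           d$confidence, d$cx, d$cy, d$w, d$h),
                   collapse = "\n"), "\n")
    }
    cat(txt, file = file.path(dir, paste0(id, ".txt")))
  }
  invisible(dir)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(list(per_class = report$per_class,
                            ap_by_iou = report$ap_by_iou,
                            iou_thresholds = report$iou_thresholds,
                            map50 = report$map50,
                            map50_95 = report$map50_95),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an evaluation report written by [write_eval_report()]
#'
#' Curves are not serialized; the returned report supports
#' [compare_runs()].
#'
#' @param path JSON path.
#' @return An `eval_report` (without `curves`).
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_class = x$per_class, ap_by_iou = as.matrix(x$ap_by_iou),
                 curves = NULL, iou_thresholds = x$iou_thresholds,
                 map50 = x$map50, map50_95 = x$map50_95),
            class = "eval_report")
}
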