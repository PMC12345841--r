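test_that("iou matches closed-form rectangle overlap", {
  a <- norm_boxes(1, 0.5, 0.5, 0.2, 0.2)
  expect_equal(iou(a, a), 1.0)
  b <- norm_boxes(1, 0.9, 0.9, 0.1, 0.1)
  expect_equal(iou(a, b), 0.0)
  # (0,0)-(10,10) vs (5,5)-(15,15) on a 100-unit frame: 25/175
  p <- norm_boxes(1, 0.05, 0.05, 0.1, 0.1)
  q <- norm_boxes(1, 0.10, 0.10, 0.1, 0.1)
  expect_equal(iou(p, q), 25 / 175, tolerance = 1e-12)
  # cross-check by fine-grid area enumeration
  g <- expand.grid(x = (1:400 - 0.5) / 400 * 0.2, y = (1:400 - 0.5) / 400 * 0.2)
  inp <- g$x <= 0.10 & g$y <= 0.10
  inq <- g$x >= 0.05 & g$x <= 0.15 & g$y >= 0.05 & g$y <= 0.15
  expect_equal(sum(inp & inq) / sum(inp | inq), iou(p, q), tolerance = 1e-3)
})

test_that("greedy matching follows descending confidence with single-use gts", {
  gt <- norm_boxes(1, 0.5, 0.5, 0.2, 0.2)
  # no ground truth: all FP
  d <- detections(c(1, 1), c(0.9, 0.8), c(0.5, 0.3), c(0.5, 0.3), c(0.2, 0.1), c(0.2, 0.1))
  expect_identical(match_detections(d, norm_boxes(), 0.5), c(FALSE, FALSE))
  # exact hit: TP
  d1 <- detections(1, 0.9, 0.5, 0.5, 0.2, 0.2)
  expect_identical(match_detections(d1, gt, 0.5), TRUE)
  # two identical detections on one gt: TP then FP
  d2 <- detections(c(1, 1), c(0.9, 0.8), c(0.5, 0.5), c(0.5, 0.5),
                   c(0.2, 0.2), c(0.2, 0.2))
  expect_identical(match_detections(d2, gt, 0.5), c(TRUE, FALSE))
  # class-strict: a perfect box of the wrong class is FP
  d3 <- detections(0, 0.9, 0.5, 0.5, 0.2, 0.2)
  expect_identical(match_detections(d3, gt, 0.5), FALSE)
})

test_that("average precision reproduces hand-derived values", {
  expect_equal(average_precision(TRUE, 0.9, n_gt = 1), 1.0)
  expect_equal(average_precision(c(FALSE, FALSE), c(0.9, 0.8), n_gt = 2), 0.0)
  # TP .9, FP .8, TP .7 over 2 gts: (51*1 + 50*(2/3)) / 101
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2),
               (51 + 50 * 2 / 3) / 101, tolerance = 1e-12)
  expect_lt(abs(average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2) -
                0.8350), 1e-4)
})

test_that("average precision equals the brute-force envelope oracle", {
  set.seed(33)
  for (rep in 1:1000) {
    n <- sample(1:10, 1)
    n_gt <- sample(1:5, 1)
    tp <- runif(n) < 0.5
    if (sum(tp) > n_gt) tp[which(tp)[seq_len(sum(tp) - n_gt)]] <- FALSE
    conf <- runif(n)
    expect_equal(average_precision(tp, conf, n_gt), oracle_ap(tp, conf, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("AP is non-increasing in the IoU threshold", {
  set.seed(34)
  for (rep in 1:60) {
    n_img <- sample(1:3, 1)
    gts <- list(); dets <- list()
    for (i in seq_len(n_img)) {
      id <- sprintf("im%d", i)
      gts[[id]] <- random_test_boxes(sample(1:4, 1), classes = 0:1)
      dets[[id]] <- {
        g <- gts[[id]]
        jit <- function(v, s) pmin(pmax(v + rnorm(length(v), sd = s), 0.051), 0.949)
        detections(g$class_id, runif(nrow(g)),
                   jit(g$cx, 0.03), jit(g$cy, 0.03),
                   pmin(g$w, 0.1), pmin(g$h, 0.1))
      }
    }
    rep_out <- evaluate(dets, gts)
    for (ci in seq_len(nrow(rep_out$ap_by_iou))) {
      aps <- rep_out$ap_by_iou[ci, ]
      expect_true(all(diff(aps) <= 1e-12))
    }
  }
})

test_that("evaluate handles perfect, threshold-straddling and empty detectors", {
  gts <- list(im1 = norm_boxes(c(0, 1), c(0.3, 0.7), c(0.3, 0.7),
                               c(0.2, 0.2), c(0.2, 0.2)),
              im2 = norm_boxes(1, 0.5, 0.5, 0.3, 0.3))
  perfect <- lapply(gts, function(g) {
    detections(g$class_id, rep(1, nrow(g)), g$cx, g$cy, g$w, g$h)
  })
  r <- evaluate(perfect, gts)
  expect_equal(r$map50, 1.0)
  expect_equal(r$map50_95, 1.0)

  # every detection's IoU with its gt in (0.50, 0.55): ap50 = 1, rest 0
  straddle <- lapply(gts, function(g) {
    # x-shift of 0.3158*w gives IoU = (1 - .3158)/(1 + .3158) ~ 0.520
    detections(g$class_id, rep(0.9, nrow(g)), g$cx + 0.3158 * g$w,
               g$cy, g$w, g$h)
  })
  # verify the construction itself
  for (id in names(gts)) {
    for (i in seq_len(nrow(gts[[id]]))) {
      o <- iou(straddle[[id]][i, ], gts[[id]][i, ])
      expect_gt(o, 0.50); expect_lt(o, 0.55)
    }
  }
  r2 <- evaluate(straddle, gts)
  expect_equal(r2$map50, 1.0)
  expect_identical(r2$map50_95, 0.1)

  # no detections at all: precision 0, recall 0, AP 0
  none <- lapply(gts, function(g) detections())
  r3 <- evaluate(none, gts)
  expect_equal(r3$map50, 0)
  expect_equal(r3$per_class$precision, c(0, 0))
  expect_equal(r3$per_class$recall, c(0, 0))

  expect_error(evaluate(perfect, list()), "empty")
  expect_error(evaluate(c(perfect, list(im9 = detections())), gts), "im9")
  expect_warning(
    evaluate(list(im1 = detections(7, 0.5, 0.5, 0.5, 0.1, 0.1)),
             gts["im1"]),
    "skipped")
})

test_that("metrics are invariant to detection input order", {
  set.seed(35)
  g <- random_test_boxes(5, classes = 0:1)
  gts <- list(imA = g)
  d <- detections(g$class_id, c(0.95, 0.8, 0.65, 0.5, 0.35),
                  g$cx, g$cy, g$w, g$h)
  r1 <- evaluate(list(imA = d), gts)
  perm <- sample(5)
  r2 <- evaluate(list(imA = d[perm, ]), gts)
  expect_equal(r1$map50, r2$map50)
  expect_equal(r1$map50_95, r2$map50_95)
  expect_equal(r1$per_class, r2$per_class)
})

test_that("pr_at_max_f1 picks the F1-maximizing point, ties to higher confidence", {
  # single TP, no FP
  c1 <- pr_curve(TRUE, 0.8, n_gt = 1)
  op <- pr_at_max_f1(c1)
  expect_equal(op$precision, 1); expect_equal(op$recall, 1)
  expect_equal(op$confidence, 0.8)

  # all FP: F1 = 0 everywhere; highest-confidence point returned
  c2 <- pr_curve(c(FALSE, FALSE, FALSE), c(0.9, 0.6, 0.3), n_gt = 2)
  expect_equal(pr_at_max_f1(c2)$confidence, 0.9)
  expect_equal(pr_at_max_f1(c2)$f1, 0)

  # constructed three-point curve: middle point wins
  # TP .9 (P=1, R=1/3, F1=.5), FP .8, TP .7 (P=2/3, R=2/3, F1=2/3),
  # then two FPs drag precision down
  c3 <- pr_curve(c(TRUE, FALSE, TRUE, FALSE, FALSE),
                 c(0.9, 0.8, 0.7, 0.6, 0.5), n_gt = 3)
  op3 <- pr_at_max_f1(c3)
  expect_equal(op3$confidence, 0.7)
  expect_equal(op3$f1, 2 / 3, tolerance = 1e-12)
})

test_that("the F1-confidence curve is consistent with the max-F1 point", {
  c3 <- pr_curve(c(TRUE, FALSE, TRUE, FALSE), c(0.9, 0.8, 0.7, 0.6), n_gt = 3)
  # cutoff above every confidence: recall 0, F1 0
  expect_equal(f1_confidence_curve(c3, grid = 0.95)$f1, 0)
  # perfect detections at cutoff 0
  cp <- pr_curve(c(TRUE, TRUE), c(0.9, 0.8), n_gt = 2)
  expect_equal(f1_confidence_curve(cp, grid = 0)$f1, 1)
  # reproduces the max-F1 operating point at its confidence
  op <- pr_at_max_f1(c3)
  expect_equal(f1_confidence_curve(c3, grid = op$confidence)$f1, op$f1)
  # full grid stays within [0, max F1]
  curve <- f1_confidence_curve(c3)
  expect_true(all(curve$f1 >= 0 & curve$f1 <= op$f1 + 1e-12))
})

test_that("relative_change renders signed rounded percent strings", {
  expect_identical(relative_change(0.921, 0.912), "+0.99%")
  expect_identical(relative_change(0.5, 0.5), "+0.00%")
  expect_identical(relative_change(0.5, 1.0), "-50.00%")
  expect_error(relative_change(0.5, 0), "> 0")
})

test_that("compare_runs emits the two-table layout with percent changes", {
  gts <- list(im1 = norm_boxes(c(0, 1), c(0.3, 0.7), c(0.3, 0.7),
                               c(0.2, 0.2), c(0.2, 0.2)))
  perfect <- lapply(gts, function(g) {
    detections(g$class_id, rep(0.9, nrow(g)), g$cx, g$cy, g$w, g$h)
  })
  r <- evaluate(perfect, gts)
  tab <- compare_runs(r, r, "modelX")
  # 2 mAP rows + 2 classes x (precision, recall)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$percent_change == "+0.00%"))
  expect_identical(tab$metric[1:2], c("mAP50", "mAP50-95"))

  # manufactured reports carrying the published-style mAP50 comparison
  ra <- r; ra$map50 <- 0.921
  rb <- r; rb$map50 <- 0.912
  expect_identical(compare_runs(ra, rb)$percent_change[1], "+0.99%")
})

test_that("detection files round-trip through disk", {
  set.seed(36)
  g <- random_test_boxes(4, classes = 0:1)
  dets <- list(a = detections(g$class_id, runif(4), g$cx, g$cy, g$w, g$h),
               b = detections())
  dir <- withr::local_tempdir()
  write_detections_dir(dets, dir)
  back <- read_detections_dir(dir)
  expect_identical(names(back), c("a", "b"))
  expect_equal(nrow(back$b), 0)
  expect_equal(back$a$class_id, dets$a$class_id)
  expect_true(all(abs(back$a$confidence - dets$a$confidence) <= 5e-7 + 1e-12))
  expect_true(all(abs(back$a$cx - dets$a$cx) <= 5e-7 + 1e-12))
})

test_that("eval reports round-trip through JSON for comparison", {
  gts <- list(im1 = norm_boxes(c(0, 1), c(0.3, 0.7), c(0.3, 0.7),
                               c(0.2, 0.2), c(0.2, 0.2)))
  perfect <- lapply(gts, function(g) {
    detections(g$class_id, rep(0.9, nrow(g)), g$cx, g$cy, g$w, g$h)
  })
  r <- evaluate(perfect, gts)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, path)
  back <- read_eval_report(path)
  expect_equal(back$map50, r$map50)
  expect_equal(back$map50_95, r$map50_95)
  tab <- compare_runs(back, back)
  expect_true(all(tab$percent_change == "+0.00%"))
})
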