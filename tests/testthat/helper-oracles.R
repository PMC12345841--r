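# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the blur oracle is a literal quadruple
# loop over pixels and kernel offsets, the AP oracle explicitly builds the
# precision envelope, and the rotation oracle applies the 2x2 rotation
# matrix to box corners in closed form.

# mirror-without-edge-duplication fold of a 1-based index into [1, n]
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# naive quadruple-loop convolution with round-half-away-from-zero and clip;
# reads neighborhoods from the full input, writes only masked pixels
oracle_blur <- function(img, mask, weights) {
  k <- (nrow(weights) - 1) / 2
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- img
  for (c in seq_len(C)) {
    for (y in seq_len(H)) {
      for (x in seq_len(W)) {
        if (!mask[y, x]) next
        acc <- 0
        for (di in -k:k) {
          for (dj in -k:k) {
            yy <- oracle_reflect(y + di, H)
            xx <- oracle_reflect(x + dj, W)
            acc <- acc + img[yy, xx, c] * weights[di + k + 1, dj + k + 1]
          }
        }
        r <- sign(acc) * floor(abs(acc) + 0.5)
        out[y, x, c] <- as.integer(min(max(r, 0), 255))
      }
    }
  }
  out
}

# brute-force 101-point interpolated AP: build the envelope explicitly and
# sum the grid values
oracle_ap <- function(tp, conf, n_gt) {
  if (length(tp) == 0) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_gt
  total <- 0
  for (r in 0:100 / 100) {
    best <- 0
    for (i in seq_along(rec)) {
      if (rec[i] >= r - 1e-9 && prec[i] > best) best <- prec[i]
    }
    total <- total + best
  }
  total / 101
}

# exact rotated-corner envelope of a normalized box, in pixel coordinates,
# before clipping: returns c(x1, y1, x2, y2)
oracle_rot_envelope <- function(cx, cy, w, h, angle_deg, W, H) {
  th <- angle_deg * pi / 180
  xs <- c(cx - w / 2, cx + w / 2, cx - w / 2, cx + w / 2) * W - W / 2
  ys <- c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2) * H - H / 2
  rx <- cos(th) * xs - sin(th) * ys + W / 2
  ry <- sin(th) * xs + cos(th) * ys + H / 2
  c(min(rx), min(ry), max(rx), max(ry))
}

random_test_image <- function(H, W, C = 1L) {
  image_grid(array(sample.int(256, H * W * C, replace = TRUE) - 1L,
                   dim = c(H, W, C)))
}

random_test_boxes <- function(n, classes = 0:1) {
  w <- runif(n, 0.05, 0.4); h <- runif(n, 0.05, 0.4)
  norm_boxes(sample(classes, n, replace = TRUE),
             cx = runif(n, w / 2, 1 - w / 2), cy = runif(n, h / 2, 1 - h / 2),
             w = w, h = h)
}

small_phantom <- function(seed, size = 96L, id = "p") {
  generate_phantom(phantom_config(image_size = size, seed = seed), id)
}
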