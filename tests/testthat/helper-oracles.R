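# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: percentiles by explicit sort-and-interpolate,
# Welch's t by the textbook formula, Mander's by voxel loops, distances by
# brute-force pairwise computation.

quantile_oracle <- function(x, p) {
  # linear interpolation between order statistics: h = (n-1)p + 1
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

welch_oracle <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

manders_oracle <- function(a, b, thrA, thrB) {
  d <- dim(a)
  numA <- denA <- numB <- denB <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    av <- a[i, j, k]; bv <- b[i, j, k]
    if (av > thrA) {
      denA <- denA + av
      if (bv > thrB) numA <- numA + av
    }
    if (bv > thrB) {
      denB <- denB + bv
      if (av > thrA) numB <- numB + bv
    }
  }
  list(M1 = if (denA > 0) numA / denA else NA_real_,
       M2 = if (denB > 0) numB / denB else NA_real_)
}

# minimum Euclidean distance (µm) from each query pixel to any target pixel
bf_min_dist_um <- function(query_idx, target_idx, nx, pixel_size_um) {
  qx <- ((query_idx - 1) %% nx) + 1; qy <- ((query_idx - 1) %/% nx) + 1
  tx <- ((target_idx - 1) %% nx) + 1; ty <- ((target_idx - 1) %/% nx) + 1
  d2 <- outer(qx, tx, "-")^2 + outer(qy, ty, "-")^2
  sqrt(apply(d2, 1, min)) * pixel_size_um
}

# rasterized disk / bar label maps for feature tests
disk_mask <- function(r, nx = 2 * r + 11, cx = (nx + 1) / 2, cy = cx) {
  xs <- matrix(seq_len(nx), nx, nx)
  ys <- t(xs)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

bar_mask <- function(len = 30, nx = len + 10) {
  m <- matrix(FALSE, nx, nx)
  m[6:(5 + len), 6] <- TRUE
  m
}

features_of_mask <- function(mask, pixel_size_um = 1) {
  compute_object_features(label_map(mask * 1L, pixel_size_um))
}

# two-rectangle intensity image with exact pixel areas, for size filters
two_object_image <- function(pixel_size_um, area1_um2 = 30, area2_um2 = 40,
                             intensity = 100, width_um = 64) {
  n <- round(width_um / pixel_size_um)
  img <- matrix(0, n, n)
  px2 <- pixel_size_um^2
  n1 <- round(area1_um2 / px2); n2 <- round(area2_um2 / px2)
  near_square <- function(n) {        # exact factor pair closest to square
    w <- floor(sqrt(n))
    while (n %% w != 0) w <- w - 1
    c(w, n / w)
  }
  d1 <- near_square(n1); d2 <- near_square(n2)
  img[5 + seq_len(d1[1]), 5 + seq_len(d1[2])] <- intensity
  img[(n - 5 - d2[1]) + seq_len(d2[1]), (n - 5 - d2[2]) + seq_len(d2[2])] <- intensity
  list(img = image_grid(img, pixel_size_um, "X04"), n1 = n1, n2 = n2)
}
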