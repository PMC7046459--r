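#' Segment fluorescent staining by top-hat filtering and local thresholding
#'
#' Mirrors the whole-slide quantitation chain used for methoxy-X04, Lamp1,
#' ApoE and Iba1 channels: a white top-hat with a disc structuring element
#' flattens background, a local mean threshold binarizes, binary opening and
#' closing (1-pixel disc) remove speckle, 8-connected components are
#' labelled, and objects smaller than `min_size_um2` are excluded. Optional
#' lower bounds on shape features remove elongated objects (see
#' [filter_by_shape()]).
#'
#' @param img an [image_grid()].
#' @param tophat_radius_um radius of the top-hat disc, µm.
#' @param local_window_um side of the local-mean window, µm (must be at
#'   least 3 pixels after conversion).
#' @param local_offset additive offset on the local mean; a pixel is
#'   foreground when its top-hat value exceeds local mean + offset.
#' @param min_size_um2 minimum object area in µm² (34 for costain channels,
#'   9 for X-34 by convention); converted to pixels as
#'   `ceiling(min_size_um2 / pixel_area)`.
#' @param shape_limits optional named list with elements among
#'   `shape_factor`, `roundness`, `solidity`: lower bounds in \[0,1\].
#' @return a list of class `Segmentation` with `labels` (a [label_map()])
#'   and `table` (an object table, see [compute_object_features()]).
#' @examples
#' sc <- make_scene(scene_spec(n_plaques = 4, width_um = 128,
#'                             height_um = 128, seed = 1))
#' seg <- segment_fluorescence(sc$channels$X04, min_size_um2 = 34)
#' nrow(seg$table)
#' @export
segment_fluorescence <- function(img, tophat_radius_um = 25,
                                 local_window_um = 75, local_offset = 0,
                                 min_size_um2 = 34, shape_limits = NULL) {
  stopifnot(is_image_grid(img))
  if (tophat_radius_um <= 0 || local_window_um <= 0)
    stop("radii and windows must be positive")
  if (min_size_um2 < 0) stop("`min_size_um2` must be >= 0")
  px <- img$pixel_size_um
  win_px <- round(local_window_um / px)
  if (win_px < 3) stop("local window is smaller than 3 pixels at this pixel size")

  if (all(img$data == 0)) {
    return(new_segmentation(matrix(0L, nrow(img$data), ncol(img$data)), px))
  }

  th <- EBImage::whiteTopHat(img$data,
                             disc_kernel(um_to_px_radius(tophat_radius_um, px)))
  half <- max(1L, as.integer(floor((win_px - 1) / 2)))
  bin <- th > local_box_mean(th, half) + local_offset
  k1 <- disc_kernel(1L)
  bin <- EBImage::closing(EBImage::opening(bin, k1), k1)

  lab <- label_components_8(bin > 0)
  lab <- drop_small_objects(lab, min_size_um2, px)
  seg <- new_segmentation(lab, px)
  if (!is.null(shape_limits)) seg <- do.call(filter_by_shape, c(list(seg), shape_limits))
  seg
}

new_segmentation <- function(lab, pixel_size_um) {
  lab <- relabel_contiguous(lab)
  lm <- label_map(lab, pixel_size_um)
  structure(list(labels = lm, table = compute_object_features(lm)),
            class = "Segmentation")
}

#' @export
print.Segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d objects, %.3g um/px\n",
              nrow(x$table), x$labels$pixel_size_um))
  invisible(x)
}

# local mean over a (2*half+1)^2 box, windows clipped at the frame edge;
# exact summed-area-table computation so a flat region never exceeds its
# own mean (strict > in the caller leaves uniform areas as background)
local_box_mean <- function(x, half) {
  nx <- nrow(x); ny <- ncol(x)
  sat <- matrix(0, nx + 1L, ny + 1L)
  sat[-1L, -1L] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  i0 <- pmax(seq_len(nx) - half, 1L); i1 <- pmin(seq_len(nx) + half, nx)
  j0 <- pmax(seq_len(ny) - half, 1L); j1 <- pmin(seq_len(ny) + half, ny)
  sums <- sat[i1 + 1L, j1 + 1L, drop = FALSE] - sat[i0, j1 + 1L, drop = FALSE] -
    sat[i1 + 1L, j0, drop = FALSE] + sat[i0, j0, drop = FALSE]
  sums / outer(i1 - i0 + 1L, j1 - j0 + 1L)
}

# 8-connected components: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_components_8 <- function(mask) {
  mask <- as.matrix(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nx, -ny]), as.vector(lab[-1, -1])),  # \ diagonal
    cbind(as.vector(lab[-1, -ny]), as.vector(lab[-nx, -1]))   # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  out <- lab
  out[lab > 0L] <- root[lab[lab > 0L]]
  relabel_contiguous(out)
}

# remove objects with fewer than ceiling(min_size_um2 / pixel_area) pixels
drop_small_objects <- function(lab, min_size_um2, pixel_size_um) {
  if (min_size_um2 <= 0 || max(lab) == 0L) return(lab)
  min_px <- ceiling(min_size_um2 / pixel_size_um^2)
  cnt <- tabulate(lab[lab > 0L], nbins = max(lab))
  kill <- which(cnt < min_px)
  if (length(kill)) lab[lab %in% kill] <- 0L
  relabel_contiguous(lab)
}

#' Per-object geometry and shape features
#'
#' For every labelled object computes physical area and centroid, perimeter
#' (Vossepoel–Smeulders weighted chain code on the outer boundary), and the
#' three shape descriptors used to exclude elongated staining artefacts:
#' shape factor `4*pi*A/P^2`, roundness `4*A/(pi*L^2)` with `L` the major
#' axis length from second-order moments, and solidity `A / convex hull
#' area` (hull over pixel centres augmented with pixel corners). Objects of
#' one or two pixels are assigned feature value 1 (a point is round).
#'
#' @param labels a [label_map()].
#' @return data frame with columns `label`, `area_um2`, `centroid_x_um`,
#'   `centroid_y_um`, `perimeter_um`, `shape_factor`, `roundness`,
#'   `solidity`.
#' @export
compute_object_features <- function(labels) {
  stopifnot(inherits(labels, "LabelMap"))
  lab <- labels$data
  px <- labels$pixel_size_um
  k <- max(lab)
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      perimeter_um = numeric(0), shape_factor = numeric(0),
                      roundness = numeric(0), solidity = numeric(0))
  if (k == 0L) return(empty)

  idx <- which(lab > 0L)
  li <- lab[idx]
  xs <- ((idx - 1L) %% nrow(lab)) + 1L
  ys <- ((idx - 1L) %/% nrow(lab)) + 1L
  npix <- tabulate(li, nbins = k)
  sx <- tapply(xs, li, sum); sy <- tapply(ys, li, sum)
  cx <- as.numeric(sx) / npix
  cy <- as.numeric(sy) / npix

  contours <- EBImage::ocontour(lab)
  perim <- numeric(k)
  for (j in seq_len(k)) perim[j] <- chain_perimeter(contours[[j]])

  sf <- rn <- so <- numeric(k)
  ord <- order(li)
  xs <- xs[ord]; ys <- ys[ord]; li2 <- li[ord]
  starts <- c(1L, which(diff(li2) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(li2))
  for (j in seq_len(k)) {
    pxs <- xs[starts[j]:ends[j]]; pys <- ys[starts[j]:ends[j]]
    n <- length(pxs)
    if (n <= 2L) { sf[j] <- rn[j] <- so[j] <- 1; next }
    a <- n
    sf[j] <- min_cap(4 * pi * a / perim[j]^2)
    # major axis from second central moments (ellipse-equivalent length)
    vx <- sum((pxs - mean(pxs))^2) / n + 1 / 12
    vy <- sum((pys - mean(pys))^2) / n + 1 / 12
    vxy <- sum((pxs - mean(pxs)) * (pys - mean(pys))) / n
    lam <- (vx + vy) / 2 + sqrt(((vx - vy) / 2)^2 + vxy^2)
    major <- 4 * sqrt(lam)
    rn[j] <- min_cap(4 * a / (pi * major^2))
    so[j] <- min_cap(a / hull_area_px(pxs, pys))
  }
  data.frame(label = seq_len(k), area_um2 = npix * px^2,
             centroid_x_um = (cx - 0.5) * px, centroid_y_um = (cy - 0.5) * px,
             perimeter_um = perim * px,
             shape_factor = sf, roundness = rn, solidity = so)
}

min_cap <- function(x) min(x, 1.25)  # rasterization can push ratios past 1

# Vossepoel-Smeulders perimeter from an ocontour chain (0-based x,y rows).
# The chain passes through boundary-pixel centres, half a pixel inside the
# true outline; offsetting a convex outline outward by 0.5 px adds exactly
# pi, so that is added back.
chain_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(4)      # unit-square boundary of a single pixel
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  d <- nxt - pts
  diag_step <- (d[, 1] != 0) & (d[, 2] != 0)
  ne <- sum(!diag_step); no <- sum(diag_step)
  # corners: direction changes along the chain
  dirs <- atan2(d[, 2], d[, 1])
  nc <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
  max(0.980 * ne + 1.406 * no - 0.091 * nc + pi, 4)
}

# convex hull area over pixel centres plus the 4 corners of each pixel
hull_area_px <- function(pxs, pys) {
  x <- c(pxs - 0.5, pxs - 0.5, pxs + 0.5, pxs + 0.5)
  y <- c(pys - 0.5, pys + 0.5, pys - 0.5, pys + 0.5)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Remove elongated objects by shape-feature lower bounds
#'
#' Drops objects whose shape factor, roundness or solidity falls below the
#' provided lower bound; omitted bounds are not applied. The label map is
#' relabelled contiguously and the object table rebuilt so labels match.
#'
#' @param seg a `Segmentation` (list with `labels`, `table`) as returned by
#'   [segment_fluorescence()].
#' @param shape_factor,roundness,solidity lower bounds in \[0,1\], or `NULL`
#'   to skip.
#' @return filtered `Segmentation`.
#' @export
filter_by_shape <- function(seg, shape_factor = NULL, roundness = NULL,
                            solidity = NULL) {
  stopifnot(inherits(seg, "Segmentation"))
  for (b in c(shape_factor, roundness, solidity))
    if (!is.null(b) && (b < 0 || b > 1)) stop("shape bounds must lie in [0,1]")
  tab <- seg$table
  if (nrow(tab) == 0L) return(seg)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(shape_factor)) keep <- keep & tab$shape_factor >= shape_factor
  if (!is.null(roundness))    keep <- keep & tab$roundness    >= roundness
  if (!is.null(solidity))     keep <- keep & tab$solidity     >= solidity
  if (all(keep)) return(seg)
  lab <- seg$labels$data
  lab[lab %in% tab$label[!keep]] <- 0L
  new_segmentation(lab, seg$labels$pixel_size_um)
}
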