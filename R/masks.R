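#' Tissue-area mask from the pan-microglial channel
#'
#' Total tissue area is detected by global thresholding of the Iba1 signal
#' followed by binary closing and hole filling, giving a small set of solid
#' regions whose area normalizes whole-section percent-positivity.
#'
#' @param iba1 an [image_grid()] of the Iba1 channel.
#' @param threshold global intensity threshold; pixels strictly above it are
#'   tissue. Defaults to Otsu's threshold (`EBImage::otsu`) on the image.
#' @param closing_radius_um radius of the closing disc, µm.
#' @return a [binary_mask()] with attribute `area_um2`.
#' @export
tissue_mask <- function(iba1, threshold = NULL, closing_radius_um = 10) {
  stopifnot(is_image_grid(iba1))
  x <- iba1$data
  if (is.null(threshold)) {
    rng <- range(x)
    # constant image: positive constants are all tissue, an empty frame none
    threshold <- if (diff(rng) == 0) rng[1] / 2 else {
      sc <- (x - rng[1]) / diff(rng)
      EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
    }
  }
  m <- x > threshold
  if (any(m)) {
    k <- disc_kernel(um_to_px_radius(closing_radius_um, iba1$pixel_size_um))
    m <- EBImage::closing(m, k)
    m <- EBImage::fillHull(m) > 0
  }
  out <- binary_mask(m, iba1$pixel_size_um)
  attr(out, "area_um2") <- mask_area_um2(out)
  attr(out, "threshold") <- threshold
  out
}

#' Maximum intensity projection of a z-stack
#'
#' @param stack a [zstack()].
#' @return an [image_grid()] of per-pixel maxima across slices.
#' @export
max_projection <- function(stack) {
  stopifnot(is_zstack(stack))
  arr <- stack$data
  image_grid(apply(arr, c(1, 2), max), stack$pixel_size_um, stack$channel)
}

#' Background threshold from unstained control images
#'
#' Pools all pixel intensities of the control images and returns the
#' percentile that excludes essentially all background: by default the
#' 99.99th percentile (linear interpolation between order statistics), so a
#' strict `>` comparison against it keeps under 0.01% of control pixels.
#'
#' @param controls list of [image_grid()]s with no positive staining.
#' @param percentile percentile in (0, 100\]; default 99.99.
#' @return intensity threshold (single number).
#' @export
control_background_threshold <- function(controls, percentile = 99.99) {
  if (is_image_grid(controls)) controls <- list(controls)
  if (length(controls) == 0L) stop("at least one control image is required")
  pool <- unlist(lapply(controls, function(g) as.vector(g$data)))
  if (length(pool) == 0L) stop("control pixel pool is empty")
  if (percentile <= 0 || percentile > 100) stop("percentile out of range")
  unname(stats::quantile(pool, percentile / 100, type = 7, names = FALSE))
}

#' Re-threshold images at a pooled within-mask percentile
#'
#' One global threshold is computed as the given percentile of the pixel
#' intensities inside the union of positive masks, pooled across all images
#' of the batch; each image is then re-thresholded (inclusively, within its
#' own positive mask) at that value. Used with the 80th percentile to
#' isolate compact plaque area and the 50th for compact+diffuse area.
#' Post-threshold cleanup mirrors the initial segmentation: binary opening
#' and closing with a 1-pixel disc, then `min_size_um2` exclusion.
#'
#' @param images list of [image_grid()]s.
#' @param positive_masks list of [binary_mask()]s aligned with `images`.
#' @param percentile percentile in (0, 100).
#' @param min_size_um2 minimum object size after thresholding (µm²),
#'   default 9.
#' @param cleanup apply opening/closing and the size filter (default TRUE).
#' @return list of [binary_mask()]s, with attribute `threshold`.
#' @export
percentile_threshold_mask <- function(images, positive_masks, percentile,
                                      min_size_um2 = 9, cleanup = TRUE) {
  if (is_image_grid(images)) images <- list(images)
  if (inherits(positive_masks, "BinaryMask")) positive_masks <- list(positive_masks)
  stopifnot(length(images) == length(positive_masks))
  if (percentile < 0 || percentile >= 100) stop("percentile must lie in [0,100)")
  pool <- unlist(Map(function(g, m) g$data[m$data], images, positive_masks))
  if (length(pool) == 0L) stop("pooled positive mask is empty: no positive pixels in batch")
  thr <- unname(stats::quantile(pool, percentile / 100, type = 7, names = FALSE))
  k1 <- disc_kernel(1L)
  out <- Map(function(g, m) {
    sel <- m$data & (g$data >= thr)
    if (cleanup && any(sel)) {
      sel <- EBImage::closing(EBImage::opening(sel, k1), k1) > 0
      lab <- label_components_8(sel)
      lab <- drop_small_objects(lab, min_size_um2, g$pixel_size_um)
      sel <- lab > 0L
    }
    binary_mask(sel, g$pixel_size_um)
  }, images, positive_masks)
  attr(out, "threshold") <- thr
  out
}

#' Threshold-based plaque density in a 3D volume
#'
#' Identifies labelled plaques in a two-photon volume by global
#' thresholding, 26-connected component labelling and a minimum voxel
#' filter, and reports their count per mm³ of imaged volume.
#'
#' @param volume a [zstack()] (use `slice_spacing_um = 2` for 2 µm z-steps)
#'   or 3D array.
#' @param threshold global intensity threshold (strict `>`).
#' @param min_voxels minimum component size in voxels.
#' @param pixel_size_um,z_step_um voxel dimensions when `volume` is a raw
#'   array.
#' @return list with `count`, `volume_mm3` and `density_per_mm3`.
#' @export
plaque_density_3d <- function(volume, threshold, min_voxels = 1,
                              pixel_size_um = NULL, z_step_um = 2) {
  if (is_zstack(volume)) {
    arr <- volume$data
    pixel_size_um <- volume$pixel_size_um
    z_step_um <- volume$slice_spacing_um
  } else {
    arr <- volume
    if (is.null(pixel_size_um)) stop("`pixel_size_um` required for raw arrays")
  }
  d <- dim(arr)
  vol_mm3 <- prod(d) * pixel_size_um^2 * z_step_um / 1e9
  if (vol_mm3 <= 0) stop("imaged volume is zero")
  lab <- label_components_26(arr > threshold)
  cnt <- if (max(lab) > 0L) tabulate(lab[lab > 0L], nbins = max(lab)) else integer(0)
  count <- sum(cnt >= min_voxels)
  list(count = count, volume_mm3 = vol_mm3, density_per_mm3 = count / vol_mm3)
}

# 26-connected 3D component labelling by union-find over the 13 forward
# neighbour shifts (no installed package labels in 3D)
label_components_26 <- function(mask) {
  d <- dim(mask)
  idfg <- which(mask)
  n <- length(idfg)
  lab <- array(0L, d)
  if (n == 0L) return(lab)
  comp <- integer(prod(d)); comp[idfg] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ix <- ((idfg - 1L) %% d[1]) + 1L
  iy <- (((idfg - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((idfg - 1L) %/% (d[1] * d[2])) + 1L
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[order(shifts$dz, shifts$dy, shifts$dx), ]
  shifts <- shifts[14:27, ][-1, , drop = FALSE]  # 13 strictly-forward offsets
  for (s in seq_len(nrow(shifts))) {
    nx <- ix + shifts$dx[s]; ny <- iy + shifts$dy[s]; nz <- iz + shifts$dz[s]
    ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
    if (!any(ok)) next
    nidx <- (nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]
    here <- comp[idfg[ok]]; there <- comp[nidx]
    pair <- which(there > 0L)
    for (p in pair) {
      a <- find(here[p]); b <- find(there[p])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[idfg] <- match(root, sort(unique(root)))
  lab
}
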