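#' Calibrated raster types
#'
#' All imaging operations consume calibrated rasters: an `ImageGrid` is a 2D
#' matrix of non-negative intensities with a physical pixel size in
#' micrometres, a `ZStack` is an ordered set of slices sharing shape and
#' pixel size, a `BinaryMask` is a logical grid and a `LabelMap` an integer
#' grid (0 = background). Matrices are indexed `[x, y]`.
#'
#' @param data numeric matrix of intensities (non-negative, finite).
#' @param pixel_size_um physical size of one pixel edge, micrometres (> 0).
#' @param channel channel name, e.g. `"X04"`, `"Iba1"`.
#' @return an object of class `ImageGrid`: a list with elements `data`,
#'   `pixel_size_um` and `channel`.
#' @examples
#' img <- image_grid(matrix(runif(100), 10, 10), pixel_size_um = 0.5)
#' dim(img$data)
#' @export
image_grid <- function(data, pixel_size_um, channel = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data) || length(dim(data)) != 2L)
    stop("`data` must be a 2D numeric matrix")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("image must be at least 1x1")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 channel = as.character(channel)),
            class = "ImageGrid")
}

#' @param x object to test.
#' @rdname image_grid
#' @export
is_image_grid <- function(x) inherits(x, "ImageGrid")

#' Confocal z-stack
#'
#' @param slices list of `ImageGrid` objects (same shape and pixel size), or
#'   a 3D numeric array `[x, y, z]`.
#' @param pixel_size_um in-plane pixel size (µm); taken from the first slice
#'   when `slices` is a list of `ImageGrid`s.
#' @param slice_spacing_um axial spacing between slices (µm); confocal
#'   acquisitions here use 1 µm.
#' @param channel channel name.
#' @return object of class `ZStack`: list with `data` (3D array),
#'   `pixel_size_um`, `slice_spacing_um`, `channel`.
#' @export
zstack <- function(slices, pixel_size_um = NULL, slice_spacing_um = 1,
                   channel = "unknown") {
  if (is.list(slices) && all(vapply(slices, is_image_grid, logical(1)))) {
    if (length(slices) < 1L) stop("a z-stack needs at least one slice")
    dims <- vapply(slices, function(s) dim(s$data), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all slices must share the same shape")
    ps <- vapply(slices, function(s) s$pixel_size_um, numeric(1))
    if (any(abs(ps - ps[1]) > 1e-12))
      stop("all slices must share the same pixel size")
    pixel_size_um <- ps[1]
    channel <- slices[[1]]$channel
    arr <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$data
  } else {
    arr <- slices
    if (!is.array(arr) || length(dim(arr)) != 3L)
      stop("`slices` must be a list of ImageGrids or a 3D array")
    if (is.null(pixel_size_um))
      stop("`pixel_size_um` is required when passing a raw array")
  }
  if (dim(arr)[3] < 1L) stop("a z-stack needs at least one slice")
  if (slice_spacing_um <= 0) stop("`slice_spacing_um` must be positive")
  structure(list(data = arr, pixel_size_um = pixel_size_um,
                 slice_spacing_um = slice_spacing_um,
                 channel = as.character(channel)),
            class = "ZStack")
}

#' @rdname zstack
#' @param x object to test.
#' @export
is_zstack <- function(x) inherits(x, "ZStack")

#' Binary mask over a calibrated grid
#'
#' @param data logical matrix (or 0/1 numeric coerced to logical).
#' @param pixel_size_um pixel size in µm.
#' @return object of class `BinaryMask`.
#' @export
binary_mask <- function(data, pixel_size_um) {
  data <- as.matrix(data)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask may not contain NA")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  structure(list(data = data, pixel_size_um = pixel_size_um),
            class = "BinaryMask")
}

#' Label map of segmented objects
#'
#' Labels are non-negative integers, 0 meaning background; after any
#' filtering operation labels are contiguous `1..K`.
#'
#' @param data integer matrix of labels.
#' @param pixel_size_um pixel size in µm.
#' @return object of class `LabelMap`.
#' @export
label_map <- function(data, pixel_size_um) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L)) stop("labels must be non-negative")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  structure(list(data = data, pixel_size_um = pixel_size_um),
            class = "LabelMap")
}

#' Physical area of a mask or label map
#'
#' @param x a `BinaryMask`, `LabelMap` (non-zero pixels) or logical matrix.
#' @param pixel_size_um required when `x` is a bare matrix.
#' @return area in µm².
#' @export
mask_area_um2 <- function(x, pixel_size_um = NULL) {
  if (inherits(x, c("BinaryMask", "LabelMap"))) {
    sum(x$data != 0) * x$pixel_size_um^2
  } else {
    if (is.null(pixel_size_um)) stop("`pixel_size_um` required")
    sum(x != 0) * pixel_size_um^2
  }
}

# relabel a label matrix so non-zero labels are contiguous 1..K,
# preserving order of first appearance of the sorted original labels
relabel_contiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  out <- lab
  out[lab > 0L] <- match(lab[lab > 0L], u)
  storage.mode(out) <- "integer"
  out
}

# µm -> integer pixel radius, at least 1
um_to_px_radius <- function(um, pixel_size_um) {
  max(1L, as.integer(round(um / pixel_size_um)))
}

disc_kernel <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}
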