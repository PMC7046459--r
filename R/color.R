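#' Colour-range classifiers for brightfield stains
#'
#' Silver and IHC stains (e.g. Campbell-Switzer plaque silver, amino cupric
#' silver, DAB) are segmented by combining narrow inclusive ranges in RGB
#' and/or HSV space, each tagged positive or negative. A pixel is classified
#' positive when it falls inside at least one positive range and inside no
#' negative range.
#'
#' Units: R, G, B in \[0, 1\]; H in \[0, 360); S, V in \[0, 1\]. Omitted
#' channels are unconstrained.
#'
#' @param positive logical; positive (include) or negative (exclude) range.
#' @param r,g,b,h,s,v each `c(lo, hi)` or `NULL`.
#' @return object of class `ColorRange`.
#' @export
color_range <- function(positive = TRUE, r = NULL, g = NULL, b = NULL,
                        h = NULL, s = NULL, v = NULL) {
  rng <- list(r = r, g = g, b = b, h = h, s = s, v = v)
  for (nm in names(rng)) {
    x <- rng[[nm]]
    if (is.null(x)) next
    if (length(x) != 2L || anyNA(x)) stop("range for '", nm, "' must be c(lo, hi)")
    if (x[1] > x[2]) stop("inverted range for channel '", nm, "'")
  }
  structure(c(list(positive = isTRUE(positive)), rng), class = "ColorRange")
}

#' @param ... `ColorRange` objects; at least one must be positive.
#' @rdname color_range
#' @export
color_classifier <- function(...) {
  ranges <- list(...)
  if (length(ranges) == 1L && is.list(ranges[[1]]) &&
      !inherits(ranges[[1]], "ColorRange")) ranges <- ranges[[1]]
  if (!all(vapply(ranges, inherits, logical(1), "ColorRange")))
    stop("all arguments must be ColorRange objects")
  if (!any(vapply(ranges, function(x) x$positive, logical(1))))
    stop("at least one positive colour range is required")
  structure(ranges, class = "ColorClassifier")
}

#' Classify pixels of an RGB image by colour ranges
#'
#' HSV is derived from RGB by the standard hexcone transform
#' (`grDevices::rgb2hsv`). Optional cleanup (binary opening/closing and
#' minimum-size exclusion) is applied as configured.
#'
#' @param rgb list of three [image_grid()]s (R, G, B; values in \[0,1\]) or
#'   a 3D array `[x, y, 3]` with `pixel_size_um` supplied.
#' @param classifier a [color_classifier()].
#' @param pixel_size_um required when `rgb` is a raw array.
#' @param opening_radius_px,closing_radius_px cleanup disc radii in pixels
#'   (0 = skip).
#' @param min_size_um2 minimum object size after classification (0 = skip).
#' @return a [binary_mask()].
#' @export
color_classify <- function(rgb, classifier, pixel_size_um = NULL,
                           opening_radius_px = 0, closing_radius_px = 0,
                           min_size_um2 = 0) {
  stopifnot(inherits(classifier, "ColorClassifier"))
  if (is.list(rgb) && all(vapply(rgb, is_image_grid, logical(1)))) {
    stopifnot(length(rgb) == 3L)
    dims <- vapply(rgb, function(g) dim(g$data), integer(2))
    if (any(dims != dims[, 1])) stop("RGB channels must share shape")
    pixel_size_um <- rgb[[1]]$pixel_size_um
    arr <- array(c(rgb[[1]]$data, rgb[[2]]$data, rgb[[3]]$data),
                 c(dims[1, 1], dims[2, 1], 3))
  } else {
    arr <- rgb
    if (is.null(pixel_size_um)) stop("`pixel_size_um` required for raw arrays")
  }
  d <- dim(arr)[1:2]
  rv <- as.vector(arr[, , 1]); gv <- as.vector(arr[, , 2]); bv <- as.vector(arr[, , 3])
  hsv <- grDevices::rgb2hsv(r = rv, g = gv, b = bv, maxColorValue = 1)
  chan <- list(r = rv, g = gv, b = bv,
               h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])

  in_range <- function(rng) {
    sel <- rep(TRUE, length(rv))
    for (nm in c("r", "g", "b", "h", "s", "v")) {
      x <- rng[[nm]]
      if (!is.null(x)) sel <- sel & chan[[nm]] >= x[1] & chan[[nm]] <= x[2]
    }
    sel
  }
  pos <- rep(FALSE, length(rv)); neg <- rep(FALSE, length(rv))
  for (rng in classifier) {
    if (rng$positive) pos <- pos | in_range(rng) else neg <- neg | in_range(rng)
  }
  m <- matrix(pos & !neg, d[1], d[2])
  if (opening_radius_px > 0 && any(m))
    m <- EBImage::opening(m, disc_kernel(opening_radius_px)) > 0
  if (closing_radius_px > 0 && any(m))
    m <- EBImage::closing(m, disc_kernel(closing_radius_px)) > 0
  if (min_size_um2 > 0 && any(m))
    m <- drop_small_objects(label_components_8(m), min_size_um2, pixel_size_um) > 0L
  binary_mask(m, pixel_size_um)
}
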