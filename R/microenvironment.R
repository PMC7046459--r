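#' Marker-controlled watershed partition of peri-plaque territory
#'
#' Detected plaques act as markers: every pixel is assigned to the influence
#' zone of its nearest plaque under the Euclidean distance transform, which
#' equals a marker-controlled watershed of that surface. Pixels whose two
#' smallest plaque distances tie exactly form the watershed lines of
#' separation and belong to no zone (label 0).
#'
#' @param plaques a [label_map()] of detected plaques.
#' @return list of class `WatershedPartition` with `zones` (a [label_map()]),
#'   `dist_um` (matrix: each pixel's distance to its nearest plaque, µm) and
#'   `n_plaques`. An empty plaque map yields an empty (all-zero) partition.
#' @export
watershed_partition <- function(plaques) {
  stopifnot(inherits(plaques, "LabelMap"))
  lab <- plaques$data
  px <- plaques$pixel_size_um
  k <- max(lab)
  if (k == 0L) {
    return(structure(list(zones = label_map(lab, px),
                          dist_um = matrix(Inf, nrow(lab), ncol(lab)),
                          n_plaques = 0L),
                     class = "WatershedPartition"))
  }
  d1 <- matrix(Inf, nrow(lab), ncol(lab))  # smallest distance
  d2 <- d1                                 # second smallest
  zone <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_len(k)) {
    di <- EBImage::distmap(matrix(as.numeric(lab != i), nrow(lab)))
    di <- matrix(as.numeric(di), nrow(lab))
    closer <- di < d1
    d2 <- ifelse(closer, d1, pmin(d2, di))
    d1[closer] <- di[closer]
    zone[closer] <- i
  }
  on_line <- is.finite(d1) & (d2 - d1) < 1e-9 & lab == 0L
  zone[on_line] <- 0L
  structure(list(zones = label_map(zone, px), dist_um = d1 * px,
                 n_plaques = k),
            class = "WatershedPartition")
}

#' Constrained dilation of plaque masks into rings
#'
#' Dilates each plaque mask by `radius_um` (default 17 µm) but constrains
#' the dilation to the plaque's own watershed influence zone, preventing the
#' merging of plaques in close proximity. The ring of plaque *i* is the set
#' of non-plaque pixels within `radius_um` of plaque *i* that lie inside its
#' zone; rings of distinct plaques are therefore disjoint.
#'
#' @param plaques a [label_map()] of plaques.
#' @param partition a [watershed_partition()] of the same map (computed if
#'   `NULL`).
#' @param radius_um dilation radius, µm.
#' @return a [label_map()] of rings (same label as the parent plaque).
#' @export
constrained_dilation <- function(plaques, partition = NULL, radius_um = 17) {
  stopifnot(inherits(plaques, "LabelMap"))
  if (radius_um <= 0) stop("`radius_um` must be positive")
  if (is.null(partition)) partition <- watershed_partition(plaques)
  lab <- plaques$data
  px <- plaques$pixel_size_um
  ring <- matrix(0L, nrow(lab), ncol(lab))
  if (partition$n_plaques > 0L) {
    sel <- lab == 0L & partition$zones$data > 0L & partition$dist_um <= radius_um
    ring[sel] <- partition$zones$data[sel]
  }
  label_map(ring, px)
}

#' Plaque-associated marker signal fractions
#'
#' Quantifies how much of a marker's segmented signal lies in each plaque's
#' microenvironment. Two normalizations are used: `"ring"` (Lamp1, Iba1)
#' constrains signal to the dilated area around the plaque and normalizes to
#' that same area; `"plaque"` (ApoE) constrains signal to plaque + dilated
#' area and normalizes to the plaque area, so values may exceed 1.
#'
#' The section-level value pools pixels across plaques (total associated
#' signal area over total normalizing area).
#'
#' @param signal a [binary_mask()] of the marker's segmented staining.
#' @param plaques a [label_map()] of plaques.
#' @param rings a [label_map()] of constrained-dilation rings (labels match
#'   `plaques`).
#' @param mode `"ring"` or `"plaque"` normalization.
#' @return data frame of class `MicroenvironmentTable` (one row per plaque:
#'   `plaque_id`, `plaque_area_um2`, `ring_area_um2`, `signal_area_um2`,
#'   `fraction`, `mode`) with attribute `section_fraction`.
#' @export
plaque_associated_fraction <- function(signal, plaques, rings,
                                       mode = c("ring", "plaque")) {
  mode <- match.arg(mode)
  stopifnot(inherits(signal, "BinaryMask"), inherits(plaques, "LabelMap"),
            inherits(rings, "LabelMap"))
  if (!all(dim(signal$data) == dim(plaques$data)) ||
      !all(dim(signal$data) == dim(rings$data)))
    stop("masks must be aligned")
  px2 <- plaques$pixel_size_um^2
  k <- max(plaques$data)
  plaque_px <- if (k > 0) tabulate(plaques$data[plaques$data > 0L], k) else integer(0)
  ring_px <- if (k > 0) tabulate(rings$data[rings$data > 0L], k) else integer(0)
  sig <- signal$data
  sig_ring_px <- if (k > 0) tabulate(rings$data[rings$data > 0L & sig], k) else integer(0)
  sig_plaque_px <- if (k > 0) tabulate(plaques$data[plaques$data > 0L & sig], k) else integer(0)

  if (mode == "ring") {
    sig_px <- sig_ring_px
    denom_px <- ring_px
  } else {
    sig_px <- sig_ring_px + sig_plaque_px
    denom_px <- plaque_px
  }
  frac <- ifelse(denom_px > 0, sig_px / denom_px, NA_real_)
  if (any(denom_px == 0 & sig_px > 0))
    warning("zero normalizing area with nonzero signal: fraction recorded as NA")
  tab <- data.frame(plaque_id = seq_len(k),
                    plaque_area_um2 = plaque_px * px2,
                    ring_area_um2 = ring_px * px2,
                    signal_area_um2 = sig_px * px2,
                    fraction = frac,
                    mode = if (k > 0) mode else character(0))
  class(tab) <- c("MicroenvironmentTable", "data.frame")
  attr(tab, "section_fraction") <-
    if (sum(denom_px) > 0) sum(sig_px) / sum(denom_px) else NA_real_
  tab
}

#' Percent positive area over the tissue section
#'
#' `100 * area(signal within tissue) / area(tissue)`; the whole-section
#' normalization used for plaque load, Iba1, CD68, Gfap, amino cupric
#' silver and total Lamp1 positivity. Multi-section animals are aggregated
#' by an unweighted mean of section values (see [aggregate_sections()]).
#'
#' @param signal,tissue aligned [binary_mask()]s.
#' @return percentage in \[0, 100\].
#' @export
percent_area <- function(signal, tissue) {
  stopifnot(inherits(signal, "BinaryMask"), inherits(tissue, "BinaryMask"))
  if (!all(dim(signal$data) == dim(tissue$data))) stop("masks must be aligned")
  tiss <- sum(tissue$data)
  if (tiss == 0) stop("tissue mask is empty")
  100 * sum(signal$data & tissue$data) / tiss
}

#' Aggregate section-level values to animals
#'
#' Unweighted mean of section-level values per animal, mirroring the
#' averaging of 2-11 sections per animal.
#'
#' @param values numeric section-level values.
#' @param animal animal identifier per value.
#' @return data frame with `animal`, `value` (mean), `n_sections`.
#' @export
aggregate_sections <- function(values, animal) {
  stopifnot(length(values) == length(animal))
  sp <- split(values, animal)
  data.frame(animal = names(sp),
             value = vapply(sp, function(v) mean(v, na.rm = TRUE), numeric(1)),
             n_sections = vapply(sp, length, integer(1)),
             row.names = NULL)
}
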