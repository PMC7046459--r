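#' Plaque diffuseness index
#'
#' `(Area_diffuse+compact - Area_compact) / Area_diffuse+compact`: 0 for a
#' fully compact plaque (all X-34 signal at core intensity) and approaching
#' 1 as the diffuse halo dominates.
#'
#' @param area_compact area above the compact (80th-percentile) threshold,
#'   µm².
#' @param area_dc area above the diffuse (50th-percentile) threshold
#'   (compact + diffuse), µm².
#' @return index in \[0, 1\]; `NA` (with a warning) when `area_dc` is 0,
#'   meaning no plaque was present. Vectorized.
#' @examples
#' diffuseness_index(20, 100)  # 0.8
#' @export
diffuseness_index <- function(area_compact, area_dc) {
  if (any(area_compact < 0) || any(area_dc < 0)) stop("areas must be non-negative")
  if (any(area_compact > area_dc, na.rm = TRUE))
    stop("compact area cannot exceed diffuse+compact area")
  out <- ifelse(area_dc > 0, (area_dc - area_compact) / area_dc, NA_real_)
  if (any(area_dc == 0)) warning("zero diffuse+compact area: index is NA (no plaque)")
  out
}

#' Diffuseness analysis of X-34 confocal stacks
#'
#' Full chain for one batch analyzed together: each z-stack is
#' maximum-projected; an initial segmentation mask comes from a strict
#' threshold exceeding `control_percentile` (default 99.99%) of all pooled
#' control-image intensities, smoothed by binary opening/closing and purged
#' of objects under `min_size_um2` (default 9 µm²); then two global
#' thresholds — the `compact_percentile` (80th) and `diffuse_percentile`
#' (50th) of the pixels inside the segmentation masks pooled over all
#' positive images of the batch — give the compact and compact+diffuse
#' masks, from whose areas the per-image diffuseness index follows.
#'
#' @param stacks list of [zstack()]s (or [image_grid()]s, already
#'   projected).
#' @param controls list of [image_grid()]s without positive staining.
#' @param animal optional animal id per stack, for per-animal averaging of
#'   3-8 fields per animal.
#' @param compact_percentile,diffuse_percentile,control_percentile pooled
#'   percentiles (defaults 80, 50, 99.99).
#' @param min_size_um2 minimum object size, µm².
#' @return list with `per_image` (data frame: `image`, `animal`,
#'   `area_compact_um2`, `area_dc_um2`, `index`), `per_animal` (mean index
#'   per animal), and `thresholds` (control, compact, diffuse).
#' @export
diffuseness_pipeline <- function(stacks, controls, animal = NULL,
                                 compact_percentile = 80,
                                 diffuse_percentile = 50,
                                 control_percentile = 99.99,
                                 min_size_um2 = 9) {
  if (is_zstack(stacks) || is_image_grid(stacks)) stacks <- list(stacks)
  if (length(stacks) == 0L) stop("at least one positive image is required")
  if (compact_percentile <= diffuse_percentile)
    stop("compact percentile must exceed diffuse percentile")
  projs <- lapply(stacks, function(s) if (is_zstack(s)) max_projection(s) else s)
  thr0 <- control_background_threshold(controls, control_percentile)

  k1 <- disc_kernel(1L)
  seg_masks <- lapply(projs, function(g) {
    m <- g$data > thr0
    if (any(m)) {
      m <- EBImage::closing(EBImage::opening(m, k1), k1) > 0
      m <- drop_small_objects(label_components_8(m), min_size_um2,
                              g$pixel_size_um) > 0L
    }
    binary_mask(m, g$pixel_size_um)
  })
  if (!any(vapply(seg_masks, function(m) any(m$data), logical(1))))
    stop("no positive pixels in the entire batch above the control threshold")

  compact <- percentile_threshold_mask(projs, seg_masks, compact_percentile,
                                       min_size_um2 = min_size_um2)
  diffuse <- percentile_threshold_mask(projs, seg_masks, diffuse_percentile,
                                       min_size_um2 = min_size_um2)

  a_c <- vapply(compact, mask_area_um2, numeric(1))
  a_dc <- vapply(Map(function(c1, d1) {
    binary_mask(c1$data | d1$data, c1$pixel_size_um)  # compact is a subset; union guards rasterization
  }, compact, diffuse), mask_area_um2, numeric(1))
  idx <- suppressWarnings(diffuseness_index(a_c, a_dc))

  nm <- names(stacks)
  if (is.null(nm)) nm <- sprintf("image_%02d", seq_along(stacks))
  if (is.null(animal)) animal <- rep("animal_1", length(stacks))
  per_image <- data.frame(image = nm, animal = animal,
                          area_compact_um2 = a_c, area_dc_um2 = a_dc,
                          index = idx)
  per_animal <- aggregate_sections(idx, animal)
  names(per_animal)[names(per_animal) == "value"] <- "index"
  list(per_image = per_image, per_animal = per_animal,
       thresholds = c(control = thr0,
                      compact = attr(compact, "threshold"),
                      diffuse = attr(diffuse, "threshold")))
}
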