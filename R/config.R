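#' Quantification configuration
#'
#' Collects every tunable constant of the imaging pipeline in one validated
#' object, echoed into run manifests so no default is silent. Defaults are
#' the study conventions: 34 µm² minimum object size for costain channels
#' and 9 µm² for X-34, 17 µm constrained dilation, 80th/50th percentile
#' compact/diffuse thresholds, 99.99th percentile control background
#' threshold.
#'
#' @param pixel_size_um default pixel size when an input lacks a sidecar.
#' @param tophat_radius_um,local_window_um,local_offset segmentation
#'   parameters, see [segment_fluorescence()].
#' @param min_size_um2 minimum object size for costain channels (µm²).
#' @param min_size_x34_um2 minimum object size for X-34 (µm²).
#' @param dilation_radius_um constrained dilation radius (µm).
#' @param compact_percentile,diffuse_percentile,control_percentile
#'   diffuseness percentiles.
#' @param coloc_thresholds named per-channel thresholds for [manders()].
#' @param shape_solidity_min,shape_roundness_min lower shape bounds applied
#'   to Lamp1 and methoxy-X04 channels.
#' @param aggregation `"pooled"` (pooled-pixel ratio per section) or
#'   `"per_plaque"` (mean over plaques).
#' @param seed integer seed echoed into manifests.
#' @return validated list of class `QuantConfig`.
#' @export
quant_config <- function(pixel_size_um = 1,
                         tophat_radius_um = 25,
                         local_window_um = 75,
                         local_offset = 0,
                         min_size_um2 = 34,
                         min_size_x34_um2 = 9,
                         dilation_radius_um = 17,
                         compact_percentile = 80,
                         diffuse_percentile = 50,
                         control_percentile = 99.99,
                         coloc_thresholds = c(Iba1 = 50, ApoE = 50, X04 = 50),
                         shape_solidity_min = 0.5,
                         shape_roundness_min = 0.2,
                         aggregation = c("pooled", "per_plaque"),
                         seed = 1L) {
  aggregation <- match.arg(aggregation)
  cfg <- list(pixel_size_um = pixel_size_um,
              tophat_radius_um = tophat_radius_um,
              local_window_um = local_window_um,
              local_offset = local_offset,
              min_size_um2 = min_size_um2,
              min_size_x34_um2 = min_size_x34_um2,
              dilation_radius_um = dilation_radius_um,
              compact_percentile = compact_percentile,
              diffuse_percentile = diffuse_percentile,
              control_percentile = control_percentile,
              coloc_thresholds = coloc_thresholds,
              shape_solidity_min = shape_solidity_min,
              shape_roundness_min = shape_roundness_min,
              aggregation = aggregation,
              seed = as.integer(seed))
  validate_quant_config(cfg)
  structure(cfg, class = "QuantConfig")
}

validate_quant_config <- function(cfg) {
  for (p in c("compact_percentile", "diffuse_percentile", "control_percentile"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 100)
      stop(p, " must lie in (0, 100)")
  if (cfg$compact_percentile <= cfg$diffuse_percentile)
    stop("compact percentile must exceed diffuse percentile")
  for (p in c("pixel_size_um", "tophat_radius_um", "local_window_um",
              "dilation_radius_um"))
    if (cfg[[p]] <= 0) stop(p, " must be positive")
  if (cfg$min_size_um2 < 0 || cfg$min_size_x34_um2 < 0)
    stop("minimum sizes must be >= 0")
  invisible(cfg)
}

#' Read a quantification config from YAML
#'
#' Keys absent from the file fall back to the [quant_config()] defaults.
#'
#' @param path YAML file.
#' @return a `QuantConfig`.
#' @export
read_quant_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(quant_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$coloc_thresholds))
    vals$coloc_thresholds <- unlist(vals$coloc_thresholds)
  do.call(quant_config, vals)
}
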