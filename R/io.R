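#' Read and write calibrated TIFF images
#'
#' Images are stored as 16-bit TIFF (single- or multi-page) with a JSON
#' sidecar (`<path>.json`) holding the pixel size, channel names and the
#' intensity scale used for 16-bit quantization. An explicit
#' `pixel_size_um` argument wins over the sidecar; a mismatch is reported
#' with a message.
#'
#' @param grids an [image_grid()], [zstack()], or list of `ImageGrid`s
#'   (written as pages).
#' @param path output TIFF path.
#' @param intensity_scale intensities are divided by this before 16-bit
#'   encoding; recorded in the sidecar and undone on read. Defaults to a
#'   power of two at least the data maximum.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(grids, path, intensity_scale = NULL) {
  if (is_image_grid(grids)) grids <- list(grids)
  if (is_zstack(grids)) {
    arr <- grids$data
    grids <- lapply(seq_len(dim(arr)[3]), function(k)
      image_grid(arr[, , k], grids$pixel_size_um, grids$channel))
  }
  stopifnot(all(vapply(grids, is_image_grid, logical(1))))
  mx <- max(vapply(grids, function(g) max(g$data), numeric(1)), 1e-12)
  if (is.null(intensity_scale)) intensity_scale <- 2^ceiling(log2(mx))
  # stored as [row = y, col = x] raster order; read_image_tiff transposes back
  pages <- lapply(grids, function(g) t(pmin(g$data / intensity_scale, 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size_um = grids[[1]]$pixel_size_um,
                  channels = vapply(grids, function(g) g$channel, character(1)),
                  intensity_scale = intensity_scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path TIFF path; `<path>.json` sidecar read when present.
#' @param pixel_size_um overrides the sidecar pixel size.
#' @param as_zstack return a [zstack()] instead of a list of pages.
#' @param slice_spacing_um axial spacing for `as_zstack = TRUE`.
#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_size_um = NULL, as_zstack = FALSE,
                            slice_spacing_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  channels <- rep("unknown", length(pages))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    scale <- side$intensity_scale
    if (!is.null(side$channels)) channels <- rep_len(side$channels, length(pages))
    if (is.null(pixel_size_um)) pixel_size_um <- side$pixel_size_um
    else if (abs(pixel_size_um - side$pixel_size_um) > 1e-9)
      message("pixel size flag (", pixel_size_um, ") overrides sidecar (",
              side$pixel_size_um, ")")
  }
  if (is.null(pixel_size_um))
    stop("no pixel size: provide `pixel_size_um` or a JSON sidecar")
  # readTIFF returns [row, col] = [y, x]; transpose back to [x, y]
  grids <- Map(function(p, ch) image_grid(t(p) * scale, pixel_size_um, ch),
               pages, channels)
  if (as_zstack) zstack(grids, slice_spacing_um = slice_spacing_um)
  else if (length(grids) == 1L) grids[[1]] else grids
}

#' Write a synthetic scene to disk
#'
#' One multi-page TIFF per scene (one page per channel) plus a plaque-truth
#' CSV and the JSON sidecar with pixel size.
#'
#' @param scene a [make_scene()] result.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return named vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, basename = "scene") {
  stopifnot(inherits(scene, "Scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(basename, ".tiff"))
  write_image_tiff(unname(scene$channels), tif)
  truth_csv <- file.path(dir, paste0(basename, "_truth.csv"))
  utils::write.csv(scene$truth$plaques, truth_csv, row.names = FALSE)
  invisible(c(tiff = tif, truth = truth_csv, sidecar = paste0(tif, ".json")))
}

#' Expression matrix and gene set I/O
#'
#' Expression matrices travel as TSV with gene ids in the first column and
#' a header row of sample ids; sample groups as a two-column TSV
#' (`sample`, `group`); gene sets as GMT (name, description, then gene ids,
#' tab-separated). GMT reading is delegated to `fgsea::gmtPathways`.
#'
#' @param m genes x samples matrix with dimnames.
#' @param path output path.
#' @return `path` invisibly (writers); matrix / named vector / named list
#'   (readers).
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' @param groups named character vector (sample -> group).
#' @rdname write_expression_tsv
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(as.character(df$group), df$sample)
}

#' @param sets named list of gene-id vectors.
#' @rdname write_expression_tsv
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
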