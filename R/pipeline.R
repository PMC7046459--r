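#' Batch costain quantification (plaques, Lamp1, Iba1, ApoE)
#'
#' Runs the whole-slide quantitation chain over a cohort manifest: per
#' field, the X04 channel is segmented (34 µm² size and shape filtering),
#' the tissue mask comes from Iba1, the peri-plaque territory is assigned
#' by marker-controlled watershed with 17 µm constrained dilation, and
#' plaque-associated fractions (Lamp1/Iba1 ring-normalized, ApoE
#' plaque-normalized) plus whole-section percent areas are computed.
#' Sections aggregate to animals by unweighted means. Fields lacking a
#' channel are skipped for that channel's outputs with a logged reason.
#'
#' @param config a [quant_config()].
#' @param manifest data frame with columns `animal`, `section`, `field` and
#'   per-channel TIFF path columns among `x04`, `iba1`, `lamp1`, `apoe`
#'   (`NA` = channel absent for that field). Alternatively `scenes`, a list
#'   of in-memory [make_scene()] results (one per row of `manifest`, path
#'   columns ignored).
#' @param out_dir output directory for CSVs and the run manifest (`NULL` =
#'   return tables only).
#' @param scenes optional list of `Scene` objects replacing file input.
#' @return list with `per_plaque`, `per_section`, `per_animal` data frames
#'   and `manifest` (the run record); CSVs written when `out_dir` is set.
#' @export
run_costain <- function(config, manifest, out_dir = NULL, scenes = NULL) {
  stopifnot(inherits(config, "QuantConfig"), is.data.frame(manifest))
  need <- c("animal", "section", "field")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (nrow(manifest) == 0L) stop("empty cohort: manifest has no rows")
  warnings_log <- character(0)

  get_channel <- function(row_i, ch) {
    if (!is.null(scenes)) {
      sc <- scenes[[row_i]]
      nm <- c(x04 = "X04", iba1 = "Iba1", lamp1 = "Lamp1", apoe = "ApoE")[ch]
      if (nm %in% names(sc$channels)) return(sc$channels[[nm]])
      return(NULL)
    }
    if (!ch %in% names(manifest)) return(NULL)
    p <- manifest[[ch]][row_i]
    if (is.na(p) || !nzchar(p)) return(NULL)
    read_image_tiff(p, pixel_size_um = NULL)
  }

  per_plaque <- list(); per_field <- list()
  for (i in seq_len(nrow(manifest))) {
    fid <- sprintf("%s/%s/%s", manifest$animal[i], manifest$section[i],
                   manifest$field[i])
    x04 <- get_channel(i, "x04")
    iba1 <- get_channel(i, "iba1")
    if (is.null(x04)) {
      warnings_log <- c(warnings_log, paste0(fid, ": no X04 channel, field skipped"))
      next
    }
    seg <- segment_fluorescence(x04, config$tophat_radius_um,
                                config$local_window_um, config$local_offset,
                                config$min_size_um2,
                                shape_limits = list(
                                  solidity = config$shape_solidity_min,
                                  roundness = config$shape_roundness_min))
    tiss <- if (!is.null(iba1)) tissue_mask(iba1) else NULL
    part <- watershed_partition(seg$labels)
    rings <- constrained_dilation(seg$labels, part, config$dilation_radius_um)

    fld <- data.frame(animal = manifest$animal[i],
                      section = manifest$section[i],
                      field = manifest$field[i],
                      n_plaques = nrow(seg$table),
                      plaque_area_um2 = sum(seg$table$area_um2))
    fld$plaque_percent_area <-
      if (!is.null(tiss) && any(tiss$data))
        percent_area(binary_mask(seg$labels$data > 0L,
                                 seg$labels$pixel_size_um), tiss)
      else NA_real_

    for (ch in c("lamp1", "iba1", "apoe")) {
      img <- if (ch == "iba1") iba1 else get_channel(i, ch)
      col_fr <- paste0(ch, "_fraction")
      col_pa <- paste0(ch, "_percent_area")
      if (is.null(img)) {
        warnings_log <- c(warnings_log,
                          paste0(fid, ": no ", ch, " channel, analysis skipped"))
        fld[[col_fr]] <- NA_real_; fld[[col_pa]] <- NA_real_
        next
      }
      shape <- if (ch == "lamp1")
        list(solidity = config$shape_solidity_min,
             roundness = config$shape_roundness_min) else NULL
      segc <- segment_fluorescence(img, config$tophat_radius_um,
                                   config$local_window_um, config$local_offset,
                                   config$min_size_um2, shape_limits = shape)
      sig <- binary_mask(segc$labels$data > 0L, segc$labels$pixel_size_um)
      mode <- if (ch == "apoe") "plaque" else "ring"
      tab <- plaque_associated_fraction(sig, seg$labels, rings, mode = mode)
      if (nrow(tab)) {
        tab$channel <- ch
        tab$animal <- manifest$animal[i]
        tab$section <- manifest$section[i]
        tab$field <- manifest$field[i]
        per_plaque[[length(per_plaque) + 1L]] <- as.data.frame(tab)
      }
      fld[[col_fr]] <- if (config$aggregation == "pooled")
        attr(tab, "section_fraction") else mean(tab$fraction, na.rm = TRUE)
      fld[[col_pa]] <- if (!is.null(tiss) && any(tiss$data))
        percent_area(sig, tiss) else NA_real_
    }
    per_field[[length(per_field) + 1L]] <- fld
  }
  if (length(per_field) == 0L) stop("empty cohort: no usable field")

  per_field <- do.call(rbind, per_field)
  per_plaque <- if (length(per_plaque)) do.call(rbind, per_plaque) else
    data.frame()
  # section level: mean over fields; animal level: mean over sections
  num_cols <- setdiff(names(per_field), c("animal", "section", "field"))
  per_section <- stats::aggregate(per_field[num_cols],
                                  by = per_field[c("animal", "section")],
                                  FUN = function(v) mean(v, na.rm = TRUE))
  per_animal <- stats::aggregate(per_section[num_cols],
                                 by = per_section["animal"],
                                 FUN = function(v) mean(v, na.rm = TRUE))
  per_section <- per_section[order(per_section$animal, per_section$section), ]
  per_animal <- per_animal[order(per_animal$animal), ]
  rownames(per_section) <- rownames(per_animal) <- NULL

  run <- run_manifest(config, manifest, warnings_log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_output_csv(per_plaque, file.path(out_dir, "per_plaque.csv"), config)
    write_output_csv(per_field, file.path(out_dir, "per_field.csv"), config)
    write_output_csv(per_section, file.path(out_dir, "per_section.csv"), config)
    write_output_csv(per_animal, file.path(out_dir, "per_animal.csv"), config)
    jsonlite::write_json(run, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(per_plaque = per_plaque, per_field = per_field,
       per_section = per_section, per_animal = per_animal, manifest = run)
}

#' Batch diffuseness quantification
#'
#' Groups stacks by `batch` (the pooling unit for the global percentile
#' thresholds: one cohort analyzed together) and runs
#' [diffuseness_pipeline()] per batch.
#'
#' @param config a [quant_config()].
#' @param manifest data frame with columns `animal`, `batch` and either
#'   `path` (multi-page TIFF z-stacks) or an in-memory `stacks` list.
#' @param controls list of control [image_grid()]s, or a character vector
#'   of control TIFF paths, or a named list/vector per batch.
#' @param out_dir optional output directory.
#' @param stacks optional list of [zstack()]s replacing file input.
#' @return list with `per_image`, `per_animal`, `thresholds` (per batch).
#' @export
run_diffuseness <- function(config, manifest, controls, out_dir = NULL,
                            stacks = NULL) {
  stopifnot(inherits(config, "QuantConfig"), is.data.frame(manifest))
  if (!all(c("animal", "batch") %in% names(manifest)))
    stop("manifest needs columns: animal, batch")
  if (is.null(stacks)) {
    stacks <- lapply(manifest$path, read_image_tiff, as_zstack = TRUE)
  }
  if (is.character(controls)) controls <- lapply(controls, read_image_tiff)
  if (is_image_grid(controls)) controls <- list(controls)
  per_batch_controls <- !is.null(names(controls)) &&
    all(names(controls) %in% unique(manifest$batch)) &&
    !any(vapply(controls, is_image_grid, logical(1)))

  per_image <- list(); thresholds <- list()
  for (b in unique(manifest$batch)) {
    sel <- which(manifest$batch == b)
    ctrl <- if (per_batch_controls) controls[[b]] else controls
    if (length(ctrl) == 0L) stop("no control images for batch '", b, "'")
    res <- tryCatch(
      diffuseness_pipeline(stacks[sel], ctrl,
                           animal = manifest$animal[sel],
                           compact_percentile = config$compact_percentile,
                           diffuse_percentile = config$diffuse_percentile,
                           control_percentile = config$control_percentile,
                           min_size_um2 = config$min_size_x34_um2),
      error = function(e) stop("batch '", b, "': ", conditionMessage(e),
                               call. = FALSE))
    res$per_image$batch <- b
    per_image[[b]] <- res$per_image
    thresholds[[b]] <- res$thresholds
  }
  per_image <- do.call(rbind, per_image)
  rownames(per_image) <- NULL
  per_animal <- aggregate_sections(per_image$index, per_image$animal)
  names(per_animal)[names(per_animal) == "value"] <- "index"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_output_csv(per_image, file.path(out_dir, "diffuseness_per_image.csv"),
                     config)
    write_output_csv(per_animal, file.path(out_dir, "diffuseness_per_animal.csv"),
                     config)
  }
  list(per_image = per_image, per_animal = per_animal,
       thresholds = thresholds)
}

#' Gene-module scoring of an expression cohort
#'
#' Reads a genes x samples nRPKM TSV, a sample-to-group map and a GMT of
#' gene sets; computes per-sample gene set scores and Welch comparisons
#' between the two groups; optionally writes score, comparison and z-score
#' tables.
#'
#' @param config a [quant_config()] (echoed into outputs).
#' @param expression_tsv,groups_tsv,gmt input paths (or pass `matrix`,
#'   `groups`, `sets` directly).
#' @param out_dir optional output directory.
#' @param matrix,groups,sets in-memory alternatives to the file inputs.
#' @param floor optional log2 floor forwarded to [gene_set_scores()].
#' @return list with `scores`, `comparisons`, `zscores`.
#' @export
run_modules <- function(config, expression_tsv = NULL, groups_tsv = NULL,
                        gmt = NULL, out_dir = NULL, matrix = NULL,
                        groups = NULL, sets = NULL, floor = NULL) {
  stopifnot(inherits(config, "QuantConfig"))
  if (is.null(matrix)) matrix <- read_expression_tsv(expression_tsv)
  if (is.null(groups)) groups <- read_groups_tsv(groups_tsv)
  if (is.null(sets)) sets <- read_gmt(gmt)
  scores <- gene_set_scores(matrix, sets, floor = floor)
  comparisons <- compare_score_table(scores, groups)
  zs <- zscore_by_gene(log2_floor(matrix))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_output_csv(as.data.frame(scores), file.path(out_dir, "scores.csv"),
                     config)
    write_output_csv(comparisons, file.path(out_dir, "comparisons.csv"), config)
    write_expression_tsv(zs, file.path(out_dir, "zscores.tsv"))
  }
  list(scores = scores, comparisons = comparisons, zscores = zs)
}

# output CSVs carry the config echo as comment headers so no default is
# silent; content after the header is plain CSV
write_output_csv <- function(df, path, config) {
  hdr <- paste0("# ", config_echo(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

config_echo <- function(config) {
  flat <- unlist(config)
  paste(names(flat), unname(flat), sep = "=", collapse = "; ")
}

run_manifest <- function(config, manifest, warnings_log) {
  path_cols <- intersect(names(manifest), c("x04", "iba1", "lamp1", "apoe", "path"))
  files <- as.character(unlist(manifest[path_cols], use.names = FALSE))
  files <- files[!is.na(files) & nzchar(files)]
  files <- files[file.exists(files)]
  list(config = unclass(config),
       inputs = if (length(files))
         data.frame(file = files, md5 = unname(tools::md5sum(files))) else
           data.frame(),
       software_version = as.character(utils::packageVersion("periplaque")),
       warnings = warnings_log)
}
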