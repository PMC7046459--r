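#' Specification of a synthetic fluorescence scene
#'
#' Describes a ground-truthed multi-channel scene of amyloid plaques with a
#' bright compact core and a dimmer diffuse halo (X04 channel), Lamp1 blobs
#' near plaque rims (dystrophic neurites), microglial somata with thin
#' processes (Iba1) clustered at plaques, and small ApoE puncta. The
#' piecewise-constant radial profile (core plateau, halo plateau) makes the
#' true compact and total areas exactly analytic (pi r^2).
#'
#' Defaults represent a typical well-separated cortical field at 1 µm/px:
#' core radius 8 µm, halo radius 14 µm, plateau intensities 200/100 over
#' background 10, additive Gaussian noise SD 5 (core SNR 38).
#'
#' @param width_um,height_um scene extent, µm.
#' @param pixel_size_um pixel size, µm.
#' @param n_plaques number of plaques (>= 0).
#' @param core_radius_um,halo_radius_um plaque radii, µm
#'   (halo >= core).
#' @param core_intensity,halo_intensity,background_intensity X04 plateau
#'   intensities, `core > halo > background >= 0`.
#' @param noise_sd SD of additive Gaussian noise (clipped at 0).
#' @param channels channels to render, subset of
#'   `c("X04", "Iba1", "Lamp1", "ApoE")`.
#' @param min_center_distance_um minimum distance between plaque centers;
#'   default `2 * (halo_radius_um + 2)` keeps halos separable. Cores may
#'   never overlap (hard floor of `2 * core_radius_um`).
#' @param seed RNG seed; fixes the scene byte-for-byte.
#' @return list of class `SceneSpec`.
#' @export
scene_spec <- function(width_um = 256, height_um = 256, pixel_size_um = 1,
                       n_plaques = 10, core_radius_um = 8,
                       halo_radius_um = 14, core_intensity = 200,
                       halo_intensity = 100, background_intensity = 10,
                       noise_sd = 5,
                       channels = c("X04", "Iba1", "Lamp1", "ApoE"),
                       min_center_distance_um = NULL, seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel size must be positive")
  if (width_um <= 0 || height_um <= 0) stop("scene extent must be positive")
  if (n_plaques < 0) stop("`n_plaques` must be >= 0")
  if (halo_radius_um < core_radius_um) stop("halo radius must be >= core radius")
  ints <- c(core_intensity, halo_intensity, background_intensity)
  if (any(!is.finite(ints)) || any(ints < 0)) stop("intensities must be finite and >= 0")
  if (!(core_intensity > halo_intensity && halo_intensity > background_intensity))
    stop("intensities must satisfy core > halo > background")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  channels <- match.arg(channels, c("X04", "Iba1", "Lamp1", "ApoE"),
                        several.ok = TRUE)
  if (is.null(min_center_distance_um))
    min_center_distance_um <- 2 * (halo_radius_um + 2)
  min_center_distance_um <- max(min_center_distance_um, 2 * core_radius_um)
  structure(list(width_um = width_um, height_um = height_um,
                 pixel_size_um = pixel_size_um, n_plaques = n_plaques,
                 core_radius_um = core_radius_um,
                 halo_radius_um = halo_radius_um,
                 core_intensity = core_intensity,
                 halo_intensity = halo_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, channels = channels,
                 min_center_distance_um = min_center_distance_um,
                 seed = as.integer(seed)),
            class = "SceneSpec")
}

#' Render a ground-truthed synthetic scene
#'
#' Plaque centers are drawn by rejection sampling so no two centers come
#' closer than `min_center_distance_um` and every halo fits inside the
#' frame. Per-channel additive Gaussian noise is clipped at zero. The truth
#' record carries exact analytic areas (`pi r^2` at the stated radii),
#' rasterized true masks per channel, and per-microglia soma records.
#'
#' @param spec a [scene_spec()].
#' @param max_tries rejection-sampling budget per plaque.
#' @return list of class `Scene` with `channels` (named list of
#'   [image_grid()]), `truth` (list: `plaques` data frame, `microglia` data
#'   frame, `masks` named list of [binary_mask()]), and `spec`.
#' @export
make_scene <- function(spec, max_tries = 10000L) {
  stopifnot(inherits(spec, "SceneSpec"))
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  nx <- round(spec$width_um / px); ny <- round(spec$height_um / px)
  if (nx < 1 || ny < 1) stop("scene smaller than one pixel")
  margin <- spec$halo_radius_um + 1

  centers <- matrix(numeric(0), 0, 2)
  if (spec$n_plaques > 0) {
    if (spec$width_um <= 2 * margin || spec$height_um <= 2 * margin)
      stop("scene too small for the halo radius")
    tries <- 0L
    while (nrow(centers) < spec$n_plaques) {
      if (tries >= max_tries)
        stop("could not place ", spec$n_plaques, " plaques at minimum center ",
             "distance ", spec$min_center_distance_um,
             " um: plaque density too high for the frame")
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, spec$width_um - margin),
                stats::runif(1, margin, spec$height_um - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2)) >=
              spec$min_center_distance_um))
        centers <- rbind(centers, cand)
    }
  }

  # pixel-center coordinate grids (µm)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  gx <- matrix(xs, nx, ny)
  gy <- matrix(ys, nx, ny, byrow = TRUE)

  core_mask <- matrix(FALSE, nx, ny)
  halo_mask <- matrix(FALSE, nx, ny)
  for (i in seq_len(nrow(centers))) {
    d2 <- (gx - centers[i, 1])^2 + (gy - centers[i, 2])^2
    core_mask <- core_mask | (d2 <= spec$core_radius_um^2)
    halo_mask <- halo_mask | (d2 <= spec$halo_radius_um^2)
  }

  paint_disks <- function(canvas, cx, cy, r, value) {
    for (i in seq_along(cx)) {
      d2 <- (gx - cx[i])^2 + (gy - cy[i])^2
      canvas[d2 <= r[i]^2] <- pmax(canvas[d2 <= r[i]^2], value[i])
    }
    canvas
  }
  paint_segment <- function(canvas, x0, y0, x1, y1, value, width_um) {
    # distance from pixel centers to the segment, vectorized
    vx <- x1 - x0; vy <- y1 - y0
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((gx - x0) * vx + (gy - y0) * vy) / L2, 0), 1) else 0
    d2 <- (gx - (x0 + t * vx))^2 + (gy - (y0 + t * vy))^2
    sel <- d2 <= (width_um / 2)^2
    canvas[sel] <- pmax(canvas[sel], value)
    canvas
  }
  add_noise <- function(canvas) {
    if (spec$noise_sd > 0)
      canvas <- canvas + stats::rnorm(length(canvas), 0, spec$noise_sd)
    matrix(pmax(canvas, 0), nx, ny)
  }

  channels <- list()
  masks <- list()
  microglia <- data.frame(x_um = numeric(0), y_um = numeric(0),
                          soma_radius_um = numeric(0), plaque_id = integer(0))

  if ("X04" %in% spec$channels) {
    x04 <- matrix(spec$background_intensity, nx, ny)
    x04[halo_mask] <- spec$halo_intensity
    x04[core_mask] <- spec$core_intensity
    channels$X04 <- image_grid(add_noise(x04), px, "X04")
    masks$X04_core <- binary_mask(core_mask, px)
    masks$X04_total <- binary_mask(halo_mask, px)
  }

  np <- nrow(centers)
  if ("Lamp1" %in% spec$channels) {
    lamp <- matrix(2, nx, ny)
    lamp_truth <- matrix(FALSE, nx, ny)
    if (np > 0) {
      for (i in seq_len(np)) {
        nb <- 6L
        ang <- stats::runif(nb, 0, 2 * pi)
        rad <- stats::runif(nb, spec$halo_radius_um,
                            spec$halo_radius_um + 4)
        bx <- centers[i, 1] + rad * cos(ang)
        by <- centers[i, 2] + rad * sin(ang)
        lamp <- paint_disks(lamp, bx, by, rep(2, nb), rep(150, nb))
        for (j in seq_len(nb)) {
          d2 <- (gx - bx[j])^2 + (gy - by[j])^2
          lamp_truth <- lamp_truth | (d2 <= 4)
        }
      }
    }
    channels$Lamp1 <- image_grid(add_noise(lamp), px, "Lamp1")
    masks$Lamp1 <- binary_mask(lamp_truth, px)
  }

  if ("Iba1" %in% spec$channels) {
    iba <- matrix(20, nx, ny)  # diffuse parenchymal baseline supports tissue masking
    iba_truth <- matrix(FALSE, nx, ny)
    if (np > 0) {
      for (i in seq_len(np)) {
        nm <- 3L
        ang <- stats::runif(nm, 0, 2 * pi)
        rad <- stats::runif(nm, spec$halo_radius_um + 2,
                            spec$halo_radius_um + 8)
        sx <- centers[i, 1] + rad * cos(ang)
        sy <- centers[i, 2] + rad * sin(ang)
        for (j in seq_len(nm)) {
          iba <- paint_disks(iba, sx[j], sy[j], 5, 180)
          iba <- paint_segment(iba, sx[j], sy[j],
                               centers[i, 1], centers[i, 2], 120, 1.5)
          d2 <- (gx - sx[j])^2 + (gy - sy[j])^2
          iba_truth <- iba_truth | (d2 <= 25)
        }
        microglia <- rbind(microglia,
                           data.frame(x_um = sx, y_um = sy,
                                      soma_radius_um = 5, plaque_id = i))
      }
    }
    channels$Iba1 <- image_grid(add_noise(iba), px, "Iba1")
    masks$Iba1 <- binary_mask(iba_truth, px)
  }

  if ("ApoE" %in% spec$channels) {
    apoe <- matrix(2, nx, ny)
    apoe_truth <- matrix(FALSE, nx, ny)
    if (np > 0) {
      for (i in seq_len(np)) {
        npunc <- 8L
        ang <- stats::runif(npunc, 0, 2 * pi)
        rad <- stats::runif(npunc, 0, spec$halo_radius_um + 5)
        bx <- centers[i, 1] + rad * cos(ang)
        by <- centers[i, 2] + rad * sin(ang)
        apoe <- paint_disks(apoe, bx, by, rep(1, npunc), rep(160, npunc))
        for (j in seq_len(npunc)) {
          d2 <- (gx - bx[j])^2 + (gy - by[j])^2
          apoe_truth <- apoe_truth | (d2 <= 1)
        }
      }
    }
    channels$ApoE <- image_grid(add_noise(apoe), px, "ApoE")
    masks$ApoE <- binary_mask(apoe_truth, px)
  }

  plaques <- data.frame(
    plaque_id = seq_len(np),
    x_um = centers[, 1][seq_len(np)], y_um = centers[, 2][seq_len(np)],
    core_radius_um = rep(spec$core_radius_um, np),
    halo_radius_um = rep(spec$halo_radius_um, np),
    area_core_um2 = rep(pi * spec$core_radius_um^2, np),
    area_total_um2 = rep(pi * spec$halo_radius_um^2, np))

  structure(list(channels = channels,
                 truth = list(plaques = plaques, microglia = microglia,
                              masks = masks),
                 spec = spec),
            class = "Scene")
}
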