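#' Thresholded Mander's colocalization coefficients on z-stacks
#'
#' M1 is the fraction of channel A's total supra-threshold intensity that
#' resides in voxels where channel B also exceeds its threshold; M2 is the
#' converse. Computed over every voxel of the full stack (no projection),
#' with fixed per-channel thresholds held constant across samples.
#' Comparisons are strict (`>`), so an all-zero channel yields a clean
#' missing value rather than a spurious coefficient.
#'
#' @param stackA,stackB aligned [zstack()]s (same shape and slice count) or
#'   3D arrays.
#' @param thrA,thrB per-channel intensity thresholds (>= 0).
#' @return list of class `ColocResult`: `M1`, `M2`, `thrA`, `thrB`,
#'   `n_voxels`, `n_coloc_voxels`. `M1`/`M2` are `NA` (with a warning) when
#'   the corresponding channel has no supra-threshold voxel.
#' @examples
#' a <- array(c(10, 0, 0, 10), c(2, 2, 1))
#' b <- array(c(10, 10, 0, 0), c(2, 2, 1))
#' manders(a, b, 0, 0)  # M1 = M2 = 0.5
#' @export
manders <- function(stackA, stackB, thrA, thrB) {
  a <- if (is_zstack(stackA)) stackA$data else stackA
  b <- if (is_zstack(stackB)) stackB$data else stackB
  if (!all(dim(a) == dim(b))) stop("stacks must be aligned (same shape and slices)")
  if (thrA < 0 || thrB < 0) stop("thresholds must be non-negative")
  selA <- a > thrA
  selB <- b > thrB
  both <- selA & selB
  sumA <- sum(a[selA]); sumB <- sum(b[selB])
  m1 <- if (sumA > 0) sum(a[both]) / sumA else NA_real_
  m2 <- if (sumB > 0) sum(b[both]) / sumB else NA_real_
  if (is.na(m1) || is.na(m2))
    warning("no voxel above threshold in one channel: coefficient is NA")
  structure(list(M1 = m1, M2 = m2, thrA = thrA, thrB = thrB,
                 n_voxels = length(a), n_coloc_voxels = sum(both)),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("Mander's coefficients: M1 = %.4f, M2 = %.4f (thresholds %g/%g, %d voxels)\n",
              x$M1, x$M2, x$thrA, x$thrB, x$n_voxels))
  invisible(x)
}
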