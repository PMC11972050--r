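#' Masked Pearson similarity of two maps
#'
#' Voxel-wise Pearson correlation between two perfusion maps, per slice
#' and pooled over all masked voxels. Slices with fewer than two masked
#' voxels are skipped and reported; slices with zero variance in either
#' map are marked undefined.
#'
#' @param map_a,map_b numeric matrices (one slice) or 3D arrays
#'   `(z, y, x)` of identical shape.
#' @param mask logical mask of the same shape; must already exclude
#'   undefined voxels (e.g. artifact regions, undefined MTT).
#' @return An object of class `map_comparison`: `per_slice` (correlation
#'   per slice, `NA` where undefined), `pooled`, `n_voxels`,
#'   `skipped_slices`.
#' @export
pearson_map_similarity <- function(map_a, map_b, mask) {
  if (!identical(dim(map_a), dim(map_b)) || !identical(dim(map_a), dim(mask)))
    stop("pearson_map_similarity: shapes differ", call. = FALSE)
  if (is.matrix(map_a)) {
    map_a <- array(map_a, c(1, dim(map_a)))
    map_b <- array(map_b, c(1, dim(map_b)))
    mask <- array(mask, c(1, dim(mask)))
  }
  nz <- dim(map_a)[1]
  per <- rep(NA_real_, nz)
  skipped <- integer(0)
  for (z in seq_len(nz)) {
    m <- mask[z, , ]
    a <- map_a[z, , ][m]; b <- map_b[z, , ][m]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) { skipped <- c(skipped, z); next }
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next  # undefined
    per[z] <- stats::cor(a[ok], b[ok])
  }
  a <- map_a[mask]; b <- map_b[mask]
  ok <- is.finite(a) & is.finite(b)
  pooled <- if (sum(ok) >= 2 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
    stats::cor(a[ok], b[ok]) else NA_real_
  structure(list(per_slice = per, pooled = pooled, n_voxels = sum(ok),
                 skipped_slices = skipped),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("Pearson similarity: pooled r = %.4f over %d voxels (%d slices, %d skipped)\n",
              x$pooled, x$n_voxels, length(x$per_slice), length(x$skipped_slices)))
  invisible(x)
}

#' Robust noise standard deviation of a map
#'
#' Donoho's wavelet-based estimator: the median absolute deviation of the
#' finest-scale diagonal Haar detail coefficients, scaled by 1/0.6745.
#' Only 2x2 blocks fully inside the mask contribute. For a slice stack
#' the per-slice estimates are averaged.
#'
#' @param map numeric matrix (slice) or 3D array `(z, y, x)`.
#' @param mask logical mask of the same shape (default: finite voxels).
#' @return Estimated noise standard deviation.
#' @export
estimate_noise_sigma <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(map) & !is.na(map)
  if (is.matrix(map)) {
    map <- array(map, c(1, dim(map)))
    mask <- array(mask, c(1, dim(mask)))
  }
  est_slice <- function(x, m) {
    ny <- nrow(x); nx <- ncol(x)
    i <- seq(1, ny - 1, by = 2); j <- seq(1, nx - 1, by = 2)
    a <- x[i, j, drop = FALSE];      b <- x[i + 1, j, drop = FALSE]
    c_ <- x[i, j + 1, drop = FALSE]; e <- x[i + 1, j + 1, drop = FALSE]
    inb <- m[i, j, drop = FALSE] & m[i + 1, j, drop = FALSE] &
           m[i, j + 1, drop = FALSE] & m[i + 1, j + 1, drop = FALSE]
    if (!any(inb))
      stop("estimate_noise_sigma: mask smaller than one wavelet block", call. = FALSE)
    d <- ((a - b - c_ + e) / 2)[inb]     # diagonal Haar detail, unit variance gain
    stats::median(abs(d)) / 0.6745
  }
  mean(vapply(seq_len(dim(map)[1]),
              function(z) est_slice(map[z, , ], mask[z, , ]), numeric(1)))
}
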