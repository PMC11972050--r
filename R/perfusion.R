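#' Deconvolution configuration
#'
#' Settings of the indicator-dilution deconvolution that turns voxel TACs
#' into perfusion parameters.
#'
#' @param lambda_rel relative truncation threshold: singular values of the
#'   AIF convolution matrix strictly larger than
#'   `lambda_rel * sigma_max` are inverted, all others zeroed. In `[0, 1]`;
#'   default 0.3.
#' @param n_points number of uniform time points the TACs are resampled to
#'   before deconvolution (default 100).
#' @param dt_scaling include the time-step factor in the convolution
#'   matrix and the blood-volume sum, giving unit-consistent,
#'   grid-convergent parameters (default). Turn off for the literal
#'   unscaled discrete-sum convention.
#' @param smoothing_sigma Gaussian blur width for [smooth_maps()], pixels
#'   (default 3).
#' @return An object of class `deconv_config`.
#' @export
deconv_config <- function(lambda_rel = 0.3, n_points = 100,
                          dt_scaling = TRUE, smoothing_sigma = 3.0) {
  if (lambda_rel < 0 || lambda_rel > 1)
    stop("deconv_config: lambda_rel must be in [0, 1]", call. = FALSE)
  if (n_points < 2) stop("deconv_config: n_points must be >= 2", call. = FALSE)
  structure(list(lambda_rel = lambda_rel, n_points = as.integer(n_points),
                 dt_scaling = isTRUE(dt_scaling), smoothing_sigma = smoothing_sigma),
            class = "deconv_config")
}

#' Extract the time-by-voxel TAC matrix of a volume series
#'
#' @param trv a [time_resolved_volume()].
#' @return Matrix `n_times` x `n_voxels` (voxels column-major).
#' @export
trv_tacs <- function(trv) {
  stopifnot(inherits(trv, "time_resolved_volume"))
  matrix(trv$values, nrow = dim(trv$values)[1])
}

#' Select the arterial input function
#'
#' Among the candidate voxels of an arterial region of interest, selects
#' the voxel whose baseline-subtracted TAC has the highest peak
#' enhancement; ties (within 1e-9) break to the earlier peak time, then
#' the lowest voxel index.
#'
#' @param tacs matrix `n_times` x `n_voxels` of TACs on a uniform grid,
#'   or a [time_resolved_volume()].
#' @param times sample times (ignored when `tacs` is a volume series).
#' @param roi integer voxel indices (column-major) of the candidate region.
#' @param average use the mean ROI TAC instead of a single voxel
#'   (off by default).
#' @return An object of class `aif_record`: `location`, `samples`
#'   (baseline-subtracted), `times`, `peak_value`, `peak_time`.
#' @export
select_aif <- function(tacs, times = NULL, roi, average = FALSE) {
  if (inherits(tacs, "time_resolved_volume")) {
    times <- tacs$time_grid
    tacs <- trv_tacs(tacs)
  }
  if (!length(roi)) stop("select_aif: empty ROI", call. = FALSE)
  cand <- subtract_baseline(tacs[, roi, drop = FALSE])
  if (average) {
    s <- rowMeans(cand)
    if (max(s) <= 0) stop("select_aif: ROI enhancement is not positive", call. = FALSE)
    return(structure(list(location = NA_integer_, samples = s, times = times,
                          peak_value = max(s), peak_time = times[which.max(s)]),
                     class = "aif_record"))
  }
  pk <- apply(cand, 2, max)
  if (max(pk) <= 0) stop("select_aif: ROI enhancement is not positive", call. = FALSE)
  pt <- times[apply(cand, 2, which.max)]
  best <- which(pk > max(pk) - 1e-9)
  best <- best[order(pt[best], roi[best])][1]
  structure(list(location = roi[best], samples = cand[, best],
                 times = times, peak_value = pk[best], peak_time = pt[best]),
            class = "aif_record")
}

#' @export
print.aif_record <- function(x, ...) {
  cat(sprintf("AIF: voxel %s, peak %.4g at %.2f s (%d samples)\n",
              as.character(x$location), x$peak_value, x$peak_time,
              length(x$samples)))
  invisible(x)
}

#' Lower-triangular AIF convolution matrix
#'
#' Discretizes the indicator-dilution convolution `tac = aif * k` as
#' `A[i, j] = aif[i - j + 1] * dt` for `i >= j` (Toeplitz). With
#' `dt_scaling = FALSE` the time-step factor is omitted.
#'
#' @param aif_samples discretized AIF on a uniform grid.
#' @param dt grid spacing, seconds.
#' @param dt_scaling include the `dt` factor (default `TRUE`).
#' @return `n` x `n` lower-triangular matrix.
#' @export
build_aif_matrix <- function(aif_samples, dt, dt_scaling = TRUE) {
  n <- length(aif_samples)
  if (n < 2) stop("build_aif_matrix: need >= 2 samples", call. = FALSE)
  idx <- outer(seq_len(n), seq_len(n), "-") + 1L
  A <- matrix(0, n, n)
  pos <- idx >= 1
  A[pos] <- aif_samples[idx[pos]]
  if (dt_scaling) A <- A * dt
  A
}

#' Truncated-SVD deconvolution of tissue TACs
#'
#' Computes the residue kernel `k'` from `tac = A k` by truncated SVD of
#' the AIF convolution matrix: singular values strictly larger than
#' `lambda_rel * sigma_max` are inverted, all others set to zero, and
#' `k' = V diag(sigma+) t(U) tac`.
#'
#' @param tac baseline-subtracted TAC samples on the AIF grid: a vector
#'   or a matrix `n` x `n_voxels`.
#' @param aif an [select_aif()] record on the same uniform grid.
#' @param cfg a [deconv_config()].
#' @return Residue kernel(s), same shape as `tac`.
#' @export
tsvd_deconvolve <- function(tac, aif, cfg = deconv_config()) {
  stopifnot(inherits(aif, "aif_record"))
  dt <- aif$times[2] - aif$times[1]
  A <- build_aif_matrix(aif$samples, dt, cfg$dt_scaling)
  dec <- svd(A)
  smax <- dec$d[1]
  if (smax == 0) stop("tsvd_deconvolve: zero AIF", call. = FALSE)
  inv <- ifelse(dec$d > cfg$lambda_rel * smax, 1 / dec$d, 0)
  vec <- is.null(dim(tac))
  tm <- if (vec) matrix(tac, ncol = 1) else tac
  k <- dec$v %*% (inv * crossprod(dec$u, tm))
  if (vec) as.numeric(k) else k
}

#' Compute perfusion maps by AIF deconvolution
#'
#' Per voxel: TACs are resampled (Akima) onto an `n_points` uniform grid
#' over the supported interval and baseline-subtracted; the residue
#' kernel `k'` follows by truncated-SVD deconvolution against the AIF;
#' then blood flow `BF = max(k')`, blood volume `BV = sum(k')` (times
#' `dt` under `dt_scaling`), mean transit time `MTT = BV / BF` where
#' `BF > 0`, and time to peak `TTP` is the grid time of the TAC maximum.
#' Voxels with nonpositive BF have MTT marked undefined (excluded from
#' masks downstream, never NaN-propagated).
#'
#' @param tacs `n_times` x `n_voxels` TAC matrix, or a
#'   [time_resolved_volume()].
#' @param times sample times (ignored for a volume series).
#' @param aif an [select_aif()] record (resampled internally to the
#'   analysis grid if needed).
#' @param cfg a [deconv_config()].
#' @param mask logical voxel mask (vector or matrix) limiting the
#'   computation to the organ; default all voxels.
#' @param shape optional `c(ny, nx)` to shape the output maps as images.
#' @return An object of class `perfusion_maps` with elements `BF` (1/s),
#'   `BV` (unitless), `MTT` (s), `TTP` (s), `mask`, `defined` (voxels
#'   with positive BF), `aif`, `cfg`.
#' @export
compute_perfusion_maps <- function(tacs, times = NULL, aif, cfg = deconv_config(),
                                   mask = NULL, shape = NULL) {
  if (inherits(tacs, "time_resolved_volume")) {
    if (is.null(shape)) shape <- dim(tacs$values)[2:3]
    times <- tacs$time_grid
    tacs <- trv_tacs(tacs)
  }
  nv <- ncol(tacs)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  mask <- as.vector(mask)
  tu <- seq(min(times), max(times), length.out = cfg$n_points)
  dt <- tu[2] - tu[1]
  tac_u <- subtract_baseline(resample_time_series(tacs[, mask, drop = FALSE], times, tu))
  aif_u <- aif
  if (length(aif$samples) != cfg$n_points ||
      max(abs(range(aif$times) - range(tu))) > 1e-9) {
    s <- resample_time_series(aif$samples, aif$times, pmin(pmax(tu, min(aif$times)), max(aif$times)))
    s <- s - s[1]
    aif_u <- structure(list(location = aif$location, samples = s, times = tu,
                            peak_value = max(s), peak_time = tu[which.max(s)]),
                       class = "aif_record")
  }
  k <- tsvd_deconvolve(tac_u, aif_u, cfg)
  bf <- apply(k, 2, max)
  bv <- colSums(k) * if (cfg$dt_scaling) dt else 1
  mtt <- ifelse(bf > 0, bv / bf, NA_real_)
  ttp <- tu[apply(tac_u, 2, which.max)]
  full <- function(x) { v <- rep(NA_real_, nv); v[mask] <- x; v }
  as_map <- function(v) if (is.null(shape)) v else matrix(v, shape[1], shape[2])
  defined <- rep(FALSE, nv); defined[mask] <- bf > 0
  structure(list(BF = as_map(full(bf)), BV = as_map(full(bv)),
                 MTT = as_map(full(mtt)), TTP = as_map(full(ttp)),
                 mask = as_map(mask), defined = as_map(defined),
                 aif = aif_u, cfg = cfg, time_range = range(tu)),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("Perfusion maps: %d voxels in mask (%d with defined MTT)\n",
              sum(x$mask), sum(x$defined, na.rm = TRUE)))
  for (nm in c("BF", "BV", "MTT", "TTP"))
    cat(sprintf("  %-3s median %.4g\n", nm,
                stats::median(x[[nm]][x$mask & x$defined], na.rm = TRUE)))
  invisible(x)
}

# mask-normalized separable Gaussian blur of one 2D map
gaussian_blur_masked <- function(img, sigma, mask) {
  if (sigma <= 0) return(img)
  band <- function(n) {
    r <- ceiling(4 * sigma)
    kern <- stats::dnorm(-r:r, sd = sigma)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- kern[o + r + 1]
    }
    K
  }
  Kr <- band(nrow(img)); Kc <- band(ncol(img))
  m <- mask * 1
  v <- img; v[!mask] <- 0
  num <- Kr %*% v %*% t(Kc)
  den <- Kr %*% m %*% t(Kc)
  out <- img
  inside <- mask & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' Smooth perfusion maps inside the organ mask
#'
#' Slice-wise Gaussian blur (`sigma = cfg$smoothing_sigma` pixels) applied
#' inside the organ mask only, using mask-normalized convolution so
#' background never bleeds across the organ boundary. Voxels with
#' undefined MTT are excluded from the MTT smoothing mask.
#'
#' @param maps a [compute_perfusion_maps()] result with image-shaped maps.
#' @param cfg a [deconv_config()] (defaults to the maps' own config).
#' @param mask optional logical image mask overriding the maps' mask.
#' @return A `perfusion_maps` object with smoothed maps.
#' @export
smooth_maps <- function(maps, cfg = maps$cfg, mask = maps$mask) {
  stopifnot(inherits(maps, "perfusion_maps"))
  if (!is.matrix(maps$BF))
    stop("smooth_maps: maps must be image-shaped (pass `shape` when computing)", call. = FALSE)
  s <- cfg$smoothing_sigma
  mask <- mask & !is.na(maps$BF)
  for (nm in c("BF", "BV", "TTP"))
    maps[[nm]] <- gaussian_blur_masked(maps[[nm]], s, mask)
  maps$MTT <- gaussian_blur_masked(maps$MTT, s, mask & maps$defined)
  maps
}
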