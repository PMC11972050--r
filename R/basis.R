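#' Temporal basis set
#'
#' A set of temporal functions sampled on a dense uniform grid, used to
#' model time attenuation curves. Orthonormality is defined with respect
#' to the trapezoidal-quadrature inner product on the sample grid
#' (`<f, g> = sum(w * f * g)` with trapezoid weights `w`), under which the
#' trigonometric set of [analytical_basis()] is orthonormal to machine
#' precision on a uniform grid.
#'
#' @param values `n_funcs` x `K` matrix; one function per row.
#' @param sample_grid `K` strictly increasing sample times, seconds.
#' @param support `c(t_begin, t_end)` interval on which the set models
#'   dynamics; must lie within the sample-grid span.
#' @param orthonormal logical; if `TRUE` the Gram matrix is checked
#'   against the identity (tolerance 1e-8).
#' @param provenance `"analytical"` or `"prior_knowledge"`.
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(values, sample_grid, support = range(sample_grid),
                      orthonormal = FALSE,
                      provenance = c("analytical", "prior_knowledge")) {
  provenance <- match.arg(provenance)
  values <- rbind(values)
  if (ncol(values) != length(sample_grid))
    stop("basis_set: values/sample_grid size mismatch", call. = FALSE)
  if (any(diff(sample_grid) <= 0))
    stop("basis_set: sample_grid must be strictly increasing", call. = FALSE)
  if (support[1] < sample_grid[1] - 1e-9 || support[2] > sample_grid[length(sample_grid)] + 1e-9)
    stop("basis_set: support must lie within the sample-grid span", call. = FALSE)
  b <- structure(list(values = values, sample_grid = sample_grid,
                      support = as.numeric(support), orthonormal = isTRUE(orthonormal),
                      provenance = provenance),
                 class = "basis_set")
  if (b$orthonormal) {
    dev <- max(abs(basis_gram(b) - diag(nrow(values))))
    if (dev > 1e-8)
      stop(sprintf("basis_set: declared orthonormal but Gram deviates from identity by %.2e", dev),
           call. = FALSE)
  }
  b
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set (%s): %d functions on [%.2f, %.2f] s, %d samples%s\n",
              x$provenance, nrow(x$values), x$support[1], x$support[2],
              length(x$sample_grid), if (x$orthonormal) ", orthonormal" else ""))
  invisible(x)
}

# trapezoidal quadrature weights for a (possibly nonuniform) grid
quad_weights <- function(grid) {
  d <- diff(grid)
  c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
}

#' Gram matrix of a basis set
#'
#' Pairwise trapezoidal-quadrature inner products of the basis functions
#' on their sample grid.
#'
#' @param basis a [basis_set()].
#' @return `n_funcs` x `n_funcs` symmetric matrix.
#' @export
basis_gram <- function(basis) {
  stopifnot(inherits(basis, "basis_set"))
  w <- quad_weights(basis$sample_grid)
  tcrossprod(basis$values * rep(sqrt(w), each = nrow(basis$values)))
}

#' Analytical trigonometric basis
#'
#' The five-function set `{1, sin(2*pi*t/T), cos(2*pi*t/T),
#' sin(4*pi*t/T), cos(4*pi*t/T)}` on `[0, T]`, truncated to `n_funcs` and
#' L2-normalized on the discrete grid. The constant first function models
#' the static anatomical background; the two Fourier pairs model the
#' contrast washin/washout. Only five functions are defined.
#'
#' @param T scan duration, seconds.
#' @param n_funcs number of functions to keep, 1..5.
#' @param sample_grid dense sample times (default 0.1 s spacing on `[0, T]`).
#' @return An orthonormal [basis_set()] with provenance `"analytical"`.
#' @export
analytical_basis <- function(T, n_funcs = 5, sample_grid = seq(0, T, by = 0.1)) {
  if (T <= 0) stop("analytical_basis: T must be positive", call. = FALSE)
  if (n_funcs < 1 || n_funcs > 5)
    stop("analytical_basis: n_funcs must be between 1 and 5 (only five functions are defined)",
         call. = FALSE)
  t <- sample_grid
  raw <- rbind(rep(1, length(t)),
               sin(2 * pi * t / T), cos(2 * pi * t / T),
               sin(4 * pi * t / T), cos(4 * pi * t / T))[seq_len(n_funcs), , drop = FALSE]
  w <- quad_weights(t)
  nrm <- sqrt(rowSums(raw^2 * rep(w, each = nrow(raw))))
  basis_set(raw / nrm, t, support = c(0, T), orthonormal = TRUE,
            provenance = "analytical")
}

#' Select the spectrum elbow
#'
#' Number of dominant modes in a descending singular-value spectrum. The
#' elbow point is the index maximizing the perpendicular distance of
#' `(i, log(sigma_i))` to the chord joining the first and last points.
#' When that point lies above the chord (a shoulder) it is the last
#' retained mode; when it lies below (the first point of a noise floor,
#' the common case for spectra with a long flat tail) the retained count
#' is the index before it. Values are floored at machine epsilon before
#' the log; ties break to the earliest index.
#'
#' @param singular_values nonnegative, nonincreasing values.
#' @return Integer count of retained modes.
#' @export
elbow_select <- function(singular_values) {
  sv <- as.numeric(singular_values)
  if (any(sv < 0) || any(diff(sv) > 1e-12 * max(sv, 1)))
    stop("elbow_select: values must be nonnegative and descending", call. = FALSE)
  n <- length(sv)
  if (n == 0) stop("elbow_select: empty spectrum", call. = FALSE)
  if (n == 1) return(1L)
  y <- log(pmax(sv, .Machine$double.eps))
  x <- seq_len(n)
  dx <- n - 1; dy <- y[n] - y[1]
  # signed perpendicular distance, positive above the chord
  dist <- (dx * (y - y[1]) - dy * (x - 1)) / sqrt(dx^2 + dy^2)
  idx <- which.max(abs(dist))  # which.max takes the earliest maximum
  if (dist[idx] < 0) max(1L, idx - 1L) else idx
}

#' Extract a prior-knowledge basis by SVD
#'
#' Stacks the organ-masked voxel TACs of one or more time-resolved volume
#' series into a voxels-by-time matrix and extracts its leading temporal
#' modes (right singular vectors). Series are first aligned in time at
#' their AIF peaks (by subtracting per-series `shifts`) and resampled
#' (Akima) onto a common dense grid covering the overlap of all aligned
#' spans, i.e. the duration of the shortest scan.
#'
#' The returned modes are re-orthonormalized under the trapezoidal inner
#' product (a negligible rotation on a uniform grid) so every delivered
#' basis satisfies the package's orthonormality contract.
#'
#' @param series list of [time_resolved_volume()] objects.
#' @param masks list of logical organ masks (`ny` x `nx`), one per series;
#'   excluding other organs, bone, vessels and artifacts is the caller's
#'   duty.
#' @param shifts per-series time shifts, seconds (AIF peak alignment);
#'   default zero.
#' @param n_max maximum number of modes to retain; the actual count is
#'   `min(n_max, elbow_select(sv))` unless `apply_elbow = FALSE`.
#' @param grid_step common-grid spacing, seconds (default 0.1).
#' @param apply_elbow cap the mode count at the spectrum elbow.
#' @return A list with `basis` (a [basis_set()], provenance
#'   `"prior_knowledge"`) and `singular_values` (full spectrum).
#' @export
extract_pk_basis <- function(series, masks, shifts = numeric(length(series)),
                             n_max = 4, grid_step = 0.1, apply_elbow = FALSE) {
  if (length(series) < 1) stop("extract_pk_basis: need at least one series", call. = FALSE)
  if (length(masks) != length(series) || length(shifts) != length(series))
    stop("extract_pk_basis: series, masks, shifts must have equal length", call. = FALSE)
  spans <- mapply(function(s, sh) range(s$time_grid) - sh, series, shifts)
  lo <- max(spans[1, ]); hi <- min(spans[2, ])
  if (hi - lo <= grid_step)
    stop("extract_pk_basis: aligned series have no common time span", call. = FALSE)
  grid <- seq(lo, hi, by = grid_step)
  tacs <- lapply(seq_along(series), function(k) {
    v <- series[[k]]$values
    m <- as.vector(masks[[k]])
    mat <- matrix(v, nrow = dim(v)[1])[, m, drop = FALSE]   # time x voxels
    resample_time_series(mat, series[[k]]$time_grid - shifts[k], grid)
  })
  X <- t(do.call(cbind, tacs))                              # voxels x time
  sv <- svd(X, nu = 0, nv = min(dim(X)))
  n_keep <- min(n_max, length(sv$d))
  if (apply_elbow) n_keep <- min(n_keep, elbow_select(sv$d))
  V <- t(sv$v[, seq_len(n_keep), drop = FALSE])             # modes x time
  sgn <- apply(V, 1, function(r) sign(r[which.max(abs(r))]))
  V <- V * sgn
  b <- basis_set(V, grid, support = c(lo, hi), orthonormal = FALSE,
                 provenance = "prior_knowledge")
  list(basis = reorthonormalize(b), singular_values = sv$d)
}

#' Time alignment of a basis set to a scan
#'
#' Aligns a basis interval to a scan by matching arterial-input-function
#' peaks: the basis is shifted by `scan_aif_peak - basis_aif_peak`. Scan
#' times falling outside the shifted basis support are marked for
#' exclusion from fitting; where the shifted basis extends beyond the scan
#' span, crop offsets are recorded.
#'
#' @param basis a [basis_set()].
#' @param basis_aif_peak AIF peak time in basis time, seconds.
#' @param scan_aif_peak AIF peak time in scan time, seconds.
#' @param scan_span `c(t_first_view, t_last_view)` of the scan, seconds.
#' @return An object of class `time_alignment` with elements `shift`,
#'   `excluded` (`c(start, end)` scan seconds unsupported by the basis),
#'   `crop` (`c(begin, end)` basis seconds beyond the scan), and the
#'   shifted `support`.
#' @export
align_basis_to_scan <- function(basis, basis_aif_peak, scan_aif_peak, scan_span) {
  stopifnot(inherits(basis, "basis_set"))
  sup <- basis$support
  if (basis_aif_peak < sup[1] || basis_aif_peak > sup[2])
    stop("align_basis_to_scan: basis_aif_peak outside basis support", call. = FALSE)
  if (scan_aif_peak < scan_span[1] || scan_aif_peak > scan_span[2])
    stop("align_basis_to_scan: scan_aif_peak outside scan span", call. = FALSE)
  shift <- scan_aif_peak - basis_aif_peak
  shifted <- sup + shift
  if (shifted[1] >= scan_span[2] || shifted[2] <= scan_span[1])
    stop("align_basis_to_scan: shifted basis support does not overlap the scan", call. = FALSE)
  structure(list(
    shift = shift,
    excluded = c(max(0, shifted[1] - scan_span[1]), max(0, scan_span[2] - shifted[2])),
    crop = c(max(0, scan_span[1] - shifted[1]), max(0, shifted[2] - scan_span[2])),
    support = shifted, scan_span = as.numeric(scan_span)
  ), class = "time_alignment")
}

#' @export
print.time_alignment <- function(x, ...) {
  cat(sprintf("Time alignment: shift %+.2f s; excluded %.2f/%.2f s at scan start/end; crop %.2f/%.2f s\n",
              x$shift, x$excluded[1], x$excluded[2], x$crop[1], x$crop[2]))
  invisible(x)
}

#' Resample basis functions at scan times
#'
#' Evaluates every basis function, shifted per the alignment, at the given
#' scan times by Akima interpolation of the stored samples. Times outside
#' the shifted support are flagged invalid (no extrapolation) and get zero
#' design rows.
#'
#' @param basis a [basis_set()].
#' @param times sorted scan times, seconds.
#' @param alignment a [align_basis_to_scan()] result, or `NULL` for the
#'   identity alignment.
#' @return List with `design` (`length(times)` x `n_funcs` matrix) and
#'   `valid` (logical mask).
#' @export
resample_basis <- function(basis, times, alignment = NULL) {
  stopifnot(inherits(basis, "basis_set"))
  if (is.unsorted(times)) stop("resample_basis: times must be sorted", call. = FALSE)
  shift <- if (is.null(alignment)) 0 else alignment$shift
  tb <- times - shift                      # basis-time coordinates
  sup <- basis$support
  valid <- tb >= sup[1] - 1e-9 & tb <= sup[2] + 1e-9
  g <- basis$sample_grid
  valid <- valid & tb >= g[1] - 1e-9 & tb <= g[length(g)] + 1e-9
  if (!any(valid)) stop("resample_basis: no valid times within the basis support", call. = FALSE)
  design <- matrix(0, length(times), nrow(basis$values))
  design[valid, ] <- resample_time_series(t(basis$values), g,
                                          pmin(pmax(tb[valid], g[1]), g[length(g)]))
  list(design = design, valid = valid)
}

#' Re-orthonormalize a basis set
#'
#' Orthonormalizes the functions under the trapezoidal inner product on
#' the current sample grid (QR with positive diagonal), preserving their
#' span. Needed after cropping a basis interval, which destroys
#' orthogonality. The first function's sign is fixed to a nonnegative
#' weighted mean. Rank-deficient input is rejected, naming the first
#' dependent function.
#'
#' @param basis a [basis_set()].
#' @return An orthonormal [basis_set()] with the same span and provenance.
#' @export
reorthonormalize <- function(basis) {
  stopifnot(inherits(basis, "basis_set"))
  w <- quad_weights(basis$sample_grid)
  M <- t(basis$values * rep(sqrt(w), each = nrow(basis$values)))  # K x N
  qrd <- qr(M)
  R <- qr.R(qrd)
  dg <- abs(diag(R))
  bad <- which(dg < 1e-10 * max(dg))
  if (qrd$rank < ncol(M) || length(bad))
    stop(sprintf("reorthonormalize: rank-deficient basis (function %d is dependent)",
                 if (length(bad)) bad[1] else qrd$rank + 1L), call. = FALSE)
  Q <- qr.Q(qrd) * rep(sign(diag(R)), each = nrow(M))
  vals <- t(Q / sqrt(w))
  if (sum(vals[1, ] * w) < 0) vals[1, ] <- -vals[1, ]
  basis_set(vals, basis$sample_grid, support = basis$support,
            orthonormal = TRUE, provenance = basis$provenance)
}

#' Crop a basis set to a subinterval
#'
#' Restricts the sample grid and support to `[t_begin, t_end]` (basis
#' time). The cropped set is generally no longer orthonormal; pass it
#' through [reorthonormalize()] before fitting, or fit with the raw
#' cropped set (the default pipeline path, which keeps the
#' prior-knowledge shapes intact).
#'
#' @param basis a [basis_set()].
#' @param t_begin,t_end new support bounds, seconds (basis time).
#' @return A [basis_set()] with `orthonormal = FALSE`.
#' @export
crop_basis <- function(basis, t_begin, t_end) {
  stopifnot(inherits(basis, "basis_set"))
  keep <- basis$sample_grid >= t_begin - 1e-9 & basis$sample_grid <= t_end + 1e-9
  if (sum(keep) < 5) stop("crop_basis: fewer than 5 samples retained", call. = FALSE)
  basis_set(basis$values[, keep, drop = FALSE], basis$sample_grid[keep],
            support = c(max(t_begin, basis$support[1]), min(t_end, basis$support[2])),
            orthonormal = FALSE, provenance = basis$provenance)
}

#' Write a basis set to CSV (plain-text serialization)
#'
#' First column `time_s`, then one column per basis function; support and
#' provenance are stored in a JSON sidecar `<path>.json`.
#'
#' @param basis a [basis_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_basis_csv <- function(basis, path) {
  df <- data.frame(time_s = basis$sample_grid, t(basis$values))
  names(df)[-1] <- paste0("psi", seq_len(nrow(basis$values)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(support = basis$support, provenance = basis$provenance,
                            orthonormal = basis$orthonormal),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a basis set written by [write_basis_csv()]
#'
#' @param path CSV path.
#' @return A [basis_set()].
#' @export
read_basis_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(vals) <- NULL
  basis_set(vals, df$time_s,
            support = meta$support, orthonormal = isTRUE(meta$orthonormal),
            provenance = meta$provenance)
}
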