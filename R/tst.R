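#' Conjugate-gradient least squares (CGLS)
#'
#' Krylov solver for `min_x ||A x - b||_2`, the workhorse behind both the
#' per-basis coefficient reconstructions and the sweep-wise static
#' reconstructions. Stops when the relative residual `||b - Ax|| / ||b||`
#' drops below `tol` or after `max_iter` iterations; a residual that
#' increases over five consecutive iterations raises an error with
#' diagnostics.
#'
#' @param A sparse or dense matrix (or `Matrix`), m x n.
#' @param b right-hand side, length m.
#' @param max_iter iteration cap.
#' @param tol relative-residual stopping tolerance.
#' @return List with `x`, `iterations`, `rel_residual`, `converged`, and
#'   the residual history `residuals`.
#' @export
cgls <- function(A, b, max_iter = 50, tol = 1e-6) {
  b <- as.numeric(b)
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    return(list(x = numeric(ncol(A)), iterations = 0L, rel_residual = 0,
                converged = TRUE, residuals = numeric(0)))
  }
  x <- numeric(ncol(A))
  r <- b
  s <- as.numeric(Matrix::crossprod(A, r))
  p <- s
  gamma <- sum(s^2)
  hist <- numeric(0)
  n_up <- 0L
  prev <- Inf
  for (it in seq_len(max_iter)) {
    q <- as.numeric(A %*% p)
    alpha <- gamma / sum(q^2)
    x <- x + alpha * p
    r <- r - alpha * q
    rel <- sqrt(sum(r^2)) / nb
    hist <- c(hist, rel)
    if (rel > prev) n_up <- n_up + 1L else n_up <- 0L
    if (n_up >= 5L)
      stop(sprintf("cgls: residual increased over 5 consecutive iterations (iter %d, rel %.3e)",
                   it, rel), call. = FALSE)
    if (rel < tol)
      return(list(x = x, iterations = it, rel_residual = rel, converged = TRUE,
                  residuals = hist))
    prev <- rel
    s <- as.numeric(Matrix::crossprod(A, r))
    gamma_new <- sum(s^2)
    p <- s + (gamma_new / gamma) * p
    gamma <- gamma_new
  }
  list(x = x, iterations = max_iter, rel_residual = hist[length(hist)],
       converged = FALSE, residuals = hist)
}

#' Reconstruction configuration
#'
#' @param max_iterations CGLS iteration cap.
#' @param relative_residual_tol stopping tolerance on `||b-Ax||/||b||`.
#' @param nonnegativity clamp the static reconstructions at zero
#'   (applies to static sweep reconstruction only).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(max_iterations = 50, relative_residual_tol = 1e-6,
                         nonnegativity = FALSE) {
  if (relative_residual_tol <= 0)
    stop("recon_config: relative_residual_tol must be positive", call. = FALSE)
  structure(list(max_iterations = as.integer(max_iterations),
                 relative_residual_tol = relative_residual_tol,
                 nonnegativity = isTRUE(nonnegativity)),
            class = "recon_config")
}

#' Fit per-pixel projection coefficients
#'
#' For every detector pixel (bin, angle) the acquired samples across
#' sweeps form a short time series; its expansion coefficients in the
#' temporal basis are obtained by linear least squares over that pixel's
#' valid sample times (one sample per sweep per angle). Views whose times
#' fall outside the aligned basis support are excluded from the fit.
#' Pixels with fewer valid samples than basis functions are marked
#' invalid, never silently zeroed.
#'
#' @param series a [simulate_projections()] result (or any
#'   `projection_series`).
#' @param basis a [basis_set()].
#' @param alignment optional [align_basis_to_scan()] result.
#' @return An object of class `projection_coefficients`: `c` (array
#'   `n_bins` x `n_angles` x `n_funcs`), `valid_angle` (logical per
#'   angle), `n_valid` samples per angle, `residual_norm`
#'   (`n_bins` x `n_angles`), and the forward angle list.
#' @export
fit_projection_coefficients <- function(series, basis, alignment = NULL) {
  stopifnot(inherits(series, "projection_series"), inherits(basis, "basis_set"))
  sched <- series$schedule
  fwd <- attr(sched, "forward_angles")
  nfun <- nrow(basis$values)
  nb <- series$n_bins
  na <- length(fwd)
  cf <- array(NA_real_, c(nb, na, nfun))
  resid <- matrix(NA_real_, nb, na)
  n_valid <- integer(na)
  for (k in seq_len(na)) {
    sel <- which(sched$angle_index == k)
    sel <- sel[order(sched$time_s[sel])]
    rb <- resample_basis(basis, sched$time_s[sel], alignment)
    keep <- rb$valid
    n_valid[k] <- sum(keep)
    if (n_valid[k] < nfun) next
    X <- rb$design[keep, , drop = FALSE]
    P <- t(series$values[, sel[keep], drop = FALSE])     # n_samples x n_bins
    qx <- qr(X)
    if (qx$rank < nfun) { n_valid[k] <- 0L; next }
    co <- qr.coef(qx, P)                                 # nfun x n_bins
    cf[, k, ] <- t(co)
    resid[, k] <- sqrt(colSums((X %*% co - P)^2))
  }
  structure(list(c = cf, valid_angle = n_valid >= nfun, n_valid = n_valid,
                 residual_norm = resid, angles = fwd, n_funcs = nfun),
            class = "projection_coefficients")
}

impute_invalid_angles <- function(coeffs) {
  bad <- which(!coeffs$valid_angle)
  if (!length(bad)) return(coeffs)
  good <- which(coeffs$valid_angle)
  if (!length(good))
    stop("impute_invalid_angles: no valid angles to impute from", call. = FALSE)
  message(sprintf("imputing coefficients at %d invalid angle(s) from nearest valid angles",
                  length(bad)))
  for (k in bad) {
    nn <- good[which.min(abs(coeffs$angles[good] - coeffs$angles[k]))]
    coeffs$c[, k, ] <- coeffs$c[, nn, ]
  }
  coeffs$valid_angle[bad] <- TRUE
  coeffs
}

#' Reconstruct one volume per basis function
#'
#' Solves the separated static CT problems `A w_i = c_i`, one per basis
#' function, by CGLS. Invalid fit pixels are first imputed by
#' angular nearest-neighbor interpolation of coefficients (logged).
#'
#' @param coeffs a [fit_projection_coefficients()] result.
#' @param spec a [projector_spec()].
#' @param cfg a [recon_config()].
#' @param A optional precomputed [system_matrix()] over `coeffs$angles`.
#' @return An object of class `coefficient_volumes`: `w` (array
#'   `ny` x `nx` x `n_funcs`), solver `diagnostics`, and the projector
#'   spec.
#' @export
reconstruct_coefficients <- function(coeffs, spec, cfg = recon_config(), A = NULL) {
  stopifnot(inherits(coeffs, "projection_coefficients"),
            inherits(spec, "projector_spec"))
  coeffs <- impute_invalid_angles(coeffs)
  if (is.null(A)) A <- system_matrix(spec, coeffs$angles)
  nfun <- coeffs$n_funcs
  w <- array(0, c(spec$ny, spec$nx, nfun))
  diag_list <- vector("list", nfun)
  for (i in seq_len(nfun)) {
    b <- as.vector(coeffs$c[, , i])    # bin-fastest, matches row ordering
    sol <- cgls(A, b, cfg$max_iterations, cfg$relative_residual_tol)
    w[, , i] <- matrix(sol$x, spec$ny)
    diag_list[[i]] <- sol[c("iterations", "rel_residual", "converged")]
  }
  structure(list(w = w, diagnostics = diag_list, spec = spec),
            class = "coefficient_volumes")
}

#' Synthesize a volume at an arbitrary time
#'
#' Evaluates the time separation model `v(t) = sum_i w_i * psi_i(t)`,
#' with the basis functions resampled (Akima) at `t` under the alignment.
#'
#' @param w a [reconstruct_coefficients()] result, or a plain
#'   `ny` x `nx` x `n_funcs` array.
#' @param basis a [basis_set()].
#' @param t time, seconds (must fall within the aligned basis support).
#' @param alignment optional [align_basis_to_scan()] result.
#' @return `ny` x `nx` matrix.
#' @export
synthesize_volume <- function(w, basis, t, alignment = NULL) {
  arr <- if (inherits(w, "coefficient_volumes")) w$w else w
  rb <- resample_basis(basis, t, alignment)
  if (!rb$valid[1])
    stop("synthesize_volume: t outside the aligned basis support", call. = FALSE)
  d <- dim(arr)
  matrix(matrix(arr, d[1] * d[2]) %*% as.numeric(rb$design[1, ]), d[1])
}

#' Synthesize a time-resolved volume series
#'
#' @inheritParams synthesize_volume
#' @param times sorted times, seconds (all within the aligned support).
#' @param voxel_size voxel edge for the returned series, mm.
#' @return A [time_resolved_volume()].
#' @export
synthesize_series <- function(w, basis, times, alignment = NULL, voxel_size = 1) {
  arr <- if (inherits(w, "coefficient_volumes")) w$w else w
  rb <- resample_basis(basis, times, alignment)
  if (!all(rb$valid))
    stop("synthesize_series: some times fall outside the aligned basis support", call. = FALSE)
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2]) %*% t(rb$design)     # voxels x times
  time_resolved_volume(aperm(array(flat, c(d[1], d[2], length(times))), c(3, 1, 2)),
                       times, voxel_size)
}

#' Subtract the baseline from TACs or a volume series
#'
#' Removes the static (anatomical) component: every TAC is shifted so its
#' first sample is zero. For a volume series this subtracts the first
#' frame (the mask-sweep/baseline frame) from all frames. Idempotent.
#'
#' @param x a numeric vector (one TAC), a matrix (time x voxels), or a
#'   [time_resolved_volume()].
#' @return Same shape as `x`, baseline-subtracted.
#' @export
subtract_baseline <- function(x) {
  if (inherits(x, "time_resolved_volume")) {
    if (dim(x$values)[1] < 2) stop("subtract_baseline: need >= 2 time samples", call. = FALSE)
    first <- x$values[1, , ]
    x$values <- sweep(x$values, c(2, 3), first)
    return(x)
  }
  if (is.matrix(x)) {
    if (nrow(x) < 2) stop("subtract_baseline: need >= 2 time samples", call. = FALSE)
    return(sweep(x, 2, x[1, ]))
  }
  if (length(x) < 2) stop("subtract_baseline: need >= 2 time samples", call. = FALSE)
  x - x[1]
}

#' Sweep-wise static reconstruction
#'
#' The straightforward comparator to the time separation model: each
#' sweep's views are reconstructed as a single static CGLS problem, as if
#' all had been acquired simultaneously. Each sweep volume is stamped
#' with the mid-sweep time, which is why dynamic features (e.g. the AIF
#' peak) appear displaced by up to half a sweep duration.
#'
#' @param series a `projection_series` covering complete sweeps.
#' @param spec a [projector_spec()].
#' @param cfg a [recon_config()]; with `nonnegativity = TRUE` the sweep
#'   volumes are clamped at zero.
#' @param A optional precomputed [system_matrix()] over the forward angle
#'   list.
#' @return A list with `volumes` (a [time_resolved_volume()] with one
#'   frame per sweep on mid-sweep timestamps) and per-sweep `diagnostics`.
#' @export
static_sweep_reconstruction <- function(series, spec, cfg = recon_config(), A = NULL) {
  stopifnot(inherits(series, "projection_series"), inherits(spec, "projector_spec"))
  sched <- series$schedule
  fwd <- attr(sched, "forward_angles")
  if (is.null(A)) A <- system_matrix(spec, fwd)
  sweeps <- sort(unique(sched$sweep))
  arr <- array(0, c(length(sweeps), spec$ny, spec$nx))
  mid <- numeric(length(sweeps))
  diag_list <- vector("list", length(sweeps))
  for (si in seq_along(sweeps)) {
    sel <- which(sched$sweep == sweeps[si])
    if (length(sel) != length(fwd))
      stop("static_sweep_reconstruction: incomplete sweep", call. = FALSE)
    sel <- sel[order(sched$angle_index[sel])]            # match A row blocks
    b <- as.vector(series$values[, sel])
    sol <- cgls(A, b, cfg$max_iterations, cfg$relative_residual_tol)
    x <- sol$x
    if (cfg$nonnegativity) x <- pmax(x, 0)
    arr[si, , ] <- matrix(x, spec$ny)
    mid[si] <- (min(sched$time_s[sel]) + max(sched$time_s[sel])) / 2
    diag_list[[si]] <- sol[c("iterations", "rel_residual", "converged")]
  }
  list(volumes = time_resolved_volume(arr, mid, spec$pixel_size),
       diagnostics = diag_list)
}
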