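#' Projection geometry specification
#'
#' Defines the 2D tomographic geometry used by every reconstruction stage.
#' The projector is realized as an explicit sparse system matrix (Joseph
#' ray-driven line integrals), so the forward operation is `A %*% x` and
#' the exact adjoint is `t(A) %*% y`. Geometry is desk-scale 2D (single
#' slice); the operator contract (linearity + exact adjoint) is what the
#' model-based reconstruction relies on, so any conforming backend could
#' replace it.
#'
#' Angles are measured in degrees, counterclockwise; at 0 degrees the
#' detector axis lies along +x and rays travel along +y. The image is an
#' `ny` x `nx` matrix of attenuation values (1/mm scale free); line
#' integrals are in attenuation times mm.
#'
#' @param nx,ny image grid size in pixels.
#' @param pixel_size pixel edge length, mm.
#' @param n_bins number of detector bins; default covers the grid diagonal.
#' @param bin_size detector bin width, mm (default `pixel_size`).
#' @param geometry `"parallel2d"` or `"fan2d"`.
#' @param sod,sdd source-origin and source-detector distances, mm
#'   (fan beam only).
#' @return An object of class `projector_spec`.
#' @export
projector_spec <- function(nx, ny = nx, pixel_size = 1,
                           n_bins = NULL, bin_size = pixel_size,
                           geometry = c("parallel2d", "fan2d"),
                           sod = NULL, sdd = NULL) {
  geometry <- match.arg(geometry)
  if (nx < 2 || ny < 2 || pixel_size <= 0 || bin_size <= 0)
    stop("projector_spec: invalid grid", call. = FALSE)
  if (is.null(n_bins))
    n_bins <- as.integer(ceiling(sqrt(nx^2 + ny^2) * pixel_size / bin_size)) + 1L
  if (geometry == "fan2d") {
    if (is.null(sod) || is.null(sdd) || sod <= 0 || sdd <= sod)
      stop("projector_spec: fan2d requires 0 < sod < sdd", call. = FALSE)
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, n_bins = as.integer(n_bins),
                 bin_size = bin_size, geometry = geometry,
                 sod = sod, sdd = sdd),
            class = "projector_spec")
}

#' @export
print.projector_spec <- function(x, ...) {
  cat(sprintf("Projector: %s, image %dx%d @ %.3g mm, detector %d bins @ %.3g mm\n",
              x$geometry, x$ny, x$nx, x$pixel_size, x$n_bins, x$bin_size))
  invisible(x)
}

# Joseph ray tracing for a group of rays sharing a driving axis.
# ox, oy: ray origins; dx, dy: unit directions. Returns triplets
# (row = ray id, col = pixel index, x = weight) for the sparse matrix.
joseph_trace <- function(ray_id, ox, oy, dx, dy, drive, spec) {
  h <- spec$pixel_size
  nx <- spec$nx; ny <- spec$ny
  if (drive == "y") {
    g <- (seq_len(ny) - 1 - (ny - 1) / 2) * h          # row centers
    t_par <- outer(g, oy, "-") / rep(dy, each = ny)    # ny x nrays
    cont <- (rep(ox, each = ny) + t_par * rep(dx, each = ny)) / h + (nx - 1) / 2
    w <- h / abs(dy)
    k_idx <- rep(seq_len(ny), times = length(ox))      # driven index (row i)
  } else {
    g <- (seq_len(nx) - 1 - (nx - 1) / 2) * h          # column centers
    t_par <- outer(g, ox, "-") / rep(dx, each = nx)
    cont <- (rep(oy, each = nx) + t_par * rep(dy, each = nx)) / h + (ny - 1) / 2
    w <- h / abs(dx)
    k_idx <- rep(seq_len(nx), times = length(oy))
  }
  rid <- rep(ray_id, each = length(g))
  wt <- rep(w, each = length(g))
  c0 <- floor(cont)
  fr <- as.vector(cont - c0)
  c0 <- as.vector(c0)
  # two bilinear neighbors along the non-driving axis (0-based c0, c0+1)
  res_i <- c(rid, rid)
  res_k <- c(k_idx, k_idx)
  res_c <- c(c0, c0 + 1)
  res_x <- c(wt * (1 - fr), wt * fr)
  if (drive == "y") {
    ok <- res_c >= 0 & res_c <= nx - 1
    pix <- res_c[ok] * ny + res_k[ok]                  # column-major (ny x nx)
  } else {
    ok <- res_c >= 0 & res_c <= ny - 1
    pix <- (res_k[ok] - 1) * ny + res_c[ok] + 1
  }
  list(i = res_i[ok], j = pix, x = res_x[ok])
}

rays_for_angle <- function(spec, angle) {
  a <- angle * pi / 180
  nvec <- c(cos(a), sin(a))         # detector axis
  dvec <- c(-sin(a), cos(a))        # ray direction
  u <- (seq_len(spec$n_bins) - 1 - (spec$n_bins - 1) / 2) * spec$bin_size
  if (spec$geometry == "parallel2d") {
    list(ox = u * nvec[1], oy = u * nvec[2],
         dx = rep(dvec[1], length(u)), dy = rep(dvec[2], length(u)))
  } else {
    src <- -spec$sod * dvec
    det <- (spec$sdd - spec$sod) * dvec
    px <- det[1] + u * nvec[1]; py <- det[2] + u * nvec[2]
    vx <- px - src[1]; vy <- py - src[2]
    nrm <- sqrt(vx^2 + vy^2)
    list(ox = rep(src[1], length(u)), oy = rep(src[2], length(u)),
         dx = vx / nrm, dy = vy / nrm)
  }
}

#' Assemble the sparse system matrix for a set of angles
#'
#' Rows are ordered detector-bin-fastest: row `(a-1)*n_bins + b` is bin `b`
#' of angle `a`. The matrix maps a flattened `ny` x `nx` image
#' (column-major) to line integrals in attenuation x mm.
#'
#' @param spec a [projector_spec()].
#' @param angles numeric vector of view angles, degrees.
#' @return A `dgCMatrix` of dimension `length(angles)*n_bins` by `nx*ny`.
#' @export
system_matrix <- function(spec, angles) {
  stopifnot(inherits(spec, "projector_spec"))
  n_bins <- spec$n_bins
  parts <- vector("list", length(angles))
  for (a in seq_along(angles)) {
    r <- rays_for_angle(spec, angles[a])
    ray_id <- (a - 1L) * n_bins + seq_len(n_bins)
    drive_y <- abs(r$dy) >= abs(r$dx)
    tri <- list(i = integer(0), j = integer(0), x = numeric(0))
    if (any(drive_y)) {
      s <- which(drive_y)
      tri1 <- joseph_trace(ray_id[s], r$ox[s], r$oy[s], r$dx[s], r$dy[s], "y", spec)
      tri <- Map(c, tri, tri1)
    }
    if (any(!drive_y)) {
      s <- which(!drive_y)
      tri2 <- joseph_trace(ray_id[s], r$ox[s], r$oy[s], r$dx[s], r$dy[s], "x", spec)
      tri <- Map(c, tri, tri2)
    }
    parts[[a]] <- tri
  }
  i <- unlist(lapply(parts, `[[`, "i"))
  j <- unlist(lapply(parts, `[[`, "j"))
  x <- unlist(lapply(parts, `[[`, "x"))
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(angles) * n_bins, spec$nx * spec$ny))
}

#' Forward project an image at one or more angles
#'
#' @param volume `ny` x `nx` numeric matrix matching `spec`.
#' @param spec a [projector_spec()].
#' @param angles view angles in degrees.
#' @param A optional precomputed [system_matrix()] for `angles`.
#' @return `n_bins` x `length(angles)` matrix of line integrals
#'   (attenuation x mm).
#' @export
forward_project <- function(volume, spec, angles, A = NULL) {
  stopifnot(inherits(spec, "projector_spec"))
  if (!is.matrix(volume) || nrow(volume) != spec$ny || ncol(volume) != spec$nx)
    stop("forward_project: volume does not match the image grid", call. = FALSE)
  if (is.null(A)) A <- system_matrix(spec, angles)
  p <- as.numeric(A %*% as.vector(volume))
  matrix(p, nrow = spec$n_bins)
}

#' Back project (adjoint of [forward_project()])
#'
#' @param projections `n_bins` x `n_angles` matrix.
#' @inheritParams forward_project
#' @return `ny` x `nx` image matrix.
#' @export
back_project <- function(projections, spec, angles, A = NULL) {
  stopifnot(inherits(spec, "projector_spec"))
  if (is.null(A)) A <- system_matrix(spec, angles)
  v <- as.numeric(Matrix::crossprod(A, as.vector(projections)))
  matrix(v, nrow = spec$ny)
}
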