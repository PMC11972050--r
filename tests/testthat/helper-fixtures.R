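# Shared fixtures: everything is generated in code at test time.

# Reduced-scale pipeline configuration (same physical phantom, coarser grid)
small_pipeline_cfg <- function(nx = 32L, pixel_size = 6, views = 60L,
                               fluence = "none", seed = 1L) {
  cfg <- read_pipeline_config()
  cfg$seed <- seed
  cfg$phantom$nx <- nx
  cfg$phantom$pixel_size <- pixel_size
  cfg$protocol$views_per_sweep <- views
  cfg$noise$fluence_per_mm2 <- fluence
  cfg
}

# Centered disk image
disk_image <- function(n, radius, value = 1, pixel_size = 1) {
  xc <- (col(matrix(0, n, n)) - 1 - (n - 1) / 2) * pixel_size
  yc <- (row(matrix(0, n, n)) - 1 - (n - 1) / 2) * pixel_size
  img <- matrix(0, n, n)
  img[xc^2 + yc^2 <= radius^2] <- value
  img
}

# Smooth Gaussian blob image (well suited to iterative reconstruction tests)
blob_image <- function(n, cx, cy, sd, amp = 1) {
  xc <- col(matrix(0, n, n)) - 1 - (n - 1) / 2
  yc <- row(matrix(0, n, n)) - 1 - (n - 1) / 2
  amp * exp(-((xc - cx)^2 + (yc - cy)^2) / (2 * sd^2))
}

# AIF record on an explicit grid (bypasses voxel selection)
make_aif <- function(samples, times) {
  samples <- samples - samples[1]
  structure(list(location = NA_integer_, samples = samples, times = times,
                 peak_value = max(samples), peak_time = times[which.max(samples)]),
            class = "aif_record")
}

# Principal angles (degrees) between the row spans of two function sets
principal_angles_deg <- function(A, B) {
  qa <- qr.Q(qr(t(A))); qb <- qr.Q(qr(t(B)))
  acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi
}

# Fabricate a projection_series from a schedule and a value matrix
fake_series <- function(values, schedule) {
  structure(list(values = values, schedule = schedule, n_bins = nrow(values)),
            class = "projection_series")
}

# Dense Moore-Penrose pseudo-inverse solve (independent oracle for CGLS)
pinv_solve <- function(A, b, tol = 1e-10) {
  s <- svd(as.matrix(A))
  keep <- s$d > tol * s$d[1]
  s$v[, keep] %*% ((1 / s$d[keep]) * crossprod(s$u[, keep], b))
}
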