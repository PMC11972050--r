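test_that("constant pixels are exactly represented by the constant basis", {
  protocol <- sweep_protocol(8, 5, 90, 3.9, 1.4, accel_fraction = 0)
  sched <- build_view_schedule(protocol)
  b <- analytical_basis(protocol$total_duration, 1)
  v <- 2.7
  series <- fake_series(matrix(v, 3, nrow(sched)), sched)
  fit <- fit_projection_coefficients(series, b)
  psi0 <- b$values[1, 1]              # constant function value (1/sqrt(T) normalization)
  expect_equal(fit$c[, , 1], matrix(v / psi0, 3, 5), tolerance = 1e-12)
  expect_lt(max(fit$residual_norm), 1e-10)
  expect_true(all(fit$valid_angle))
})

test_that("coefficients of basis-generated pixel TACs are recovered to high precision", {
  protocol <- sweep_protocol(8, 6, 120, 3.9, 1.4)
  sched <- build_view_schedule(protocol)
  b <- analytical_basis(protocol$total_duration, 4)
  n_bins <- 5; n_ang <- 6
  set.seed(8)
  c_true <- array(stats::rnorm(n_bins * n_ang * 4), c(n_bins, n_ang, 4))
  vals <- matrix(NA_real_, n_bins, nrow(sched))
  for (v in seq_len(nrow(sched))) {
    psi <- resample_basis(b, sched$time_s[v])$design[1, ]
    vals[, v] <- c_true[, sched$angle_index[v], ] %*% psi
  }
  series <- fake_series(vals, sched)
  fit <- fit_projection_coefficients(series, b)
  expect_equal(fit$c, c_true, tolerance = 1e-8)
  # independent normal-equations oracle for one pixel
  k <- 3
  sel <- which(sched$angle_index == k); sel <- sel[order(sched$time_s[sel])]
  X <- resample_basis(b, sched$time_s[sel])$design
  oracle <- solve(crossprod(X), crossprod(X, vals[2, sel]))
  expect_equal(fit$c[2, k, ], as.numeric(oracle), tolerance = 1e-8)
})

test_that("aligned fitting drops exactly the views acquired before the supported interval", {
  protocol <- sweep_protocol(8, 6, 120, 3.9, 1.4)
  sched <- build_view_schedule(protocol)
  b <- analytical_basis(protocol$total_duration, 4)
  al <- align_basis_to_scan(b, basis_aif_peak = 10, scan_aif_peak = 11.5,
                            scan_span = range(sched$time_s))
  series <- fake_series(matrix(1, 2, nrow(sched)), sched)
  fit <- fit_projection_coefficients(series, b, al)
  for (k in seq_len(6)) {
    tk <- sort(sched$time_s[sched$angle_index == k])
    expect_equal(fit$n_valid[k], sum(tk >= 1.5))
  }
})

test_that("pixels with too few samples are marked invalid and imputed from neighbors", {
  protocol <- sweep_protocol(2, 6, 120, 3.9, 1.4)   # 2 samples per angle < 4 functions
  sched <- build_view_schedule(protocol)
  b <- analytical_basis(protocol$total_duration, 4)
  series <- fake_series(matrix(1, 2, nrow(sched)), sched)
  fit <- fit_projection_coefficients(series, b)
  expect_false(any(fit$valid_angle))
  expect_true(all(is.na(fit$c)))
  expect_error(tstperf:::impute_invalid_angles(fit), "no valid")
})

test_that("CGLS matches a dense pseudo-inverse oracle on a consistent system", {
  spec <- projector_spec(24, pixel_size = 2)
  angles <- seq(0, 178, length.out = 72)
  A <- system_matrix(spec, angles)
  set.seed(6)
  x_true <- as.vector(blob_image(24, 3, -2, 5) + 0.5 * blob_image(24, -6, 4, 3))
  b <- as.numeric(A %*% x_true)
  sol <- cgls(A, b, max_iter = 1500, tol = 1e-13)
  x_or <- as.numeric(pinv_solve(A, b))
  expect_lt(sqrt(sum((sol$x - x_or)^2)) / sqrt(sum(x_or^2)), 1e-5)
  # zero data reconstructs to zero
  z <- cgls(A, numeric(nrow(A)))
  expect_identical(z$x, numeric(ncol(A)))
  expect_true(z$converged)
})

test_that("volume synthesis equals the brute-force per-voxel summation", {
  b <- analytical_basis(30, 4)
  set.seed(12)
  w <- array(stats::rnorm(10 * 11 * 4), c(10, 11, 4))
  t0 <- 13.37
  out <- synthesize_volume(w, b, t0)
  psi <- resample_basis(b, t0)$design[1, ]
  brute <- matrix(0, 10, 11)
  for (i in 1:10) for (j in 1:11) brute[i, j] <- sum(w[i, j, ] * psi)
  expect_equal(out, brute, tolerance = 1e-12)
  # single-term and linearity contracts
  ind <- array(0, c(10, 11, 4)); ind[3, 4, 1] <- 1
  expect_equal(synthesize_volume(ind, b, t0)[3, 4], psi[1], tolerance = 1e-12)
  expect_equal(synthesize_volume(2.5 * w, b, t0), 2.5 * out, tolerance = 1e-12)
  expect_error(synthesize_volume(w, b, 31.5), "support")
  ser <- synthesize_series(w, b, c(5, 10, 20))
  expect_equal(ser$values[2, , ], synthesize_volume(w, b, 10), tolerance = 1e-12)
})

test_that("baseline subtraction zeroes the first sample and is idempotent", {
  expect_equal(subtract_baseline(c(2, 5, 3)), c(0, 3, 1))
  expect_equal(subtract_baseline(c(4, 4, 4)), c(0, 0, 0))
  m <- cbind(c(2, 5, 3), c(1, 1, 2))
  expect_equal(subtract_baseline(subtract_baseline(m)), subtract_baseline(m))
  arr <- array(stats::runif(3 * 4 * 4), c(3, 4, 4))
  trv <- time_resolved_volume(arr, 1:3)
  sub <- subtract_baseline(trv)
  expect_equal(sub$values[1, , ], matrix(0, 4, 4))
  expect_equal(sub$values[3, , ], arr[3, , ] - arr[1, , ])
  expect_error(subtract_baseline(c(1)), ">= 2")
})

test_that("static reconstruction of a time-constant scene is sweep-invariant", {
  regions <- default_phantom_regions()
  for (k in seq_along(regions)) regions[[k]]$tac$amplitude <- 0
  ph <- build_phantom(phantom_spec(nx = 32, pixel_size = 6, regions = regions))
  spec <- projector_spec(32, pixel_size = 6)
  sched <- build_view_schedule(sweep_protocol(3, 50, 180, 3.9, 1.4))
  series <- simulate_projections(ph, sched, spec)
  st <- static_sweep_reconstruction(series, spec, recon_config(max_iterations = 40))
  v <- st$volumes$values
  expect_lt(max(abs(v[2, , ] - v[1, , ])), 2e-4 * max(abs(v[1, , ])))
  expect_lt(max(abs(v[3, , ] - v[1, , ])), 2e-4 * max(abs(v[1, , ])))
  # mid-sweep timestamps
  expect_equal(st$volumes$time_grid, c(1.95, 7.25, 12.55), tolerance = 1e-6)
})

test_that("a single dense sweep reconstructs a disk faithfully", {
  spec <- projector_spec(64, pixel_size = 3)
  regions <- list(list(label = "healthy", shape = c(0, 0, 60), baseline = 0.02,
                       tac = NULL, heterogeneity_sd = 0))
  ph <- build_phantom(phantom_spec(nx = 64, pixel_size = 3, regions = regions))
  sched <- build_view_schedule(sweep_protocol(1, 180, 180, 3.9, 0))
  series <- simulate_projections(ph, sched, spec)
  st <- static_sweep_reconstruction(series, spec, recon_config(max_iterations = 30))
  truth <- phantom_frame(ph, 0)
  expect_gt(stats::cor(as.vector(st$volumes$values[1, , ]), as.vector(truth)), 0.95)
})

test_that("the time separation model denoises relative to static reconstruction", {
  # high-noise acquisition; basis from the phantom's own noiseless series
  cfg <- small_pipeline_cfg(fluence = "high", seed = 3)
  res <- run_pipeline(cfg)
  organ <- as.vector(res$phantom$masks$healthy | res$phantom$masks$embolized |
                       res$phantom$masks$artery)
  tst_err <- trv_tacs(res$tst_series)[, organ] -
    phantom_tacs(res$phantom, res$tst_series$time_grid, which(organ))
  st_t <- res$static$volumes$time_grid
  st_err <- trv_tacs(res$static$volumes)[, organ] -
    phantom_tacs(res$phantom, st_t, which(organ))
  expect_lt(sqrt(mean(tst_err^2)), sqrt(mean(st_err^2)))
})
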