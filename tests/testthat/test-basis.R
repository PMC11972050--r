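test_that("the trigonometric basis is orthonormal on its grid", {
  b <- analytical_basis(42, 5)
  G <- basis_gram(b)
  expect_lt(max(abs(G - diag(5))), 1e-6)
  expect_true(b$orthonormal)
  # single constant function, unit norm
  b1 <- analytical_basis(10, 1)
  expect_equal(as.numeric(basis_gram(b1)), 1, tolerance = 1e-12)
  expect_equal(diff(range(b1$values)), 0)
  # periodicity of the first harmonic pair
  b5 <- analytical_basis(30, 5, seq(0, 30, by = 0.05))
  expect_equal(b5$values[3, 1], b5$values[3, ncol(b5$values)], tolerance = 1e-12)
  expect_error(analytical_basis(30, 6), "five")
  expect_error(analytical_basis(-1, 3), "positive")
})

test_that("elbow selection matches a brute-force chord-distance oracle", {
  oracle <- function(sv) {
    y <- log(pmax(sv, .Machine$double.eps))
    n <- length(y)
    p1 <- c(1, y[1]); p2 <- c(n, y[n])
    d <- vapply(seq_len(n), function(i) {
      v <- p2 - p1; u <- c(i, y[i]) - p1
      (v[1] * u[2] - v[2] * u[1]) / sqrt(sum(v^2))   # signed, above-chord positive
    }, numeric(1))
    i <- which.max(abs(d))
    if (d[i] < 0) max(1L, i - 1L) else i
  }
  expect_equal(elbow_select(c(100, 50, 25, 12, 0.1, 0.09, 0.08)), 4)
  expect_equal(elbow_select(rep(7, 9)), 1)      # degenerate spectrum, earliest index
  expect_equal(elbow_select(c(5, 0)), 1)        # log(0) floored at machine epsilon
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    sv <- sort(rexp(n, rate = runif(1, 0.1, 2)), decreasing = TRUE)
    expect_equal(elbow_select(sv), oracle(sv))
  }
  expect_error(elbow_select(c(1, 2, 3)), "descending")
  expect_error(elbow_select(numeric(0)), "empty")
})

test_that("prior-knowledge extraction recovers planted temporal modes", {
  tg <- seq(0, 42, by = 1)
  raw <- rbind(1,
               gamma_variate_tac(tg, 5, 3, 2),
               gamma_variate_tac(tg, 9, 4, 3),
               gamma_variate_tac(tg, 3, 2, 5))
  modes <- t(qr.Q(qr(t(raw))))            # 4 orthonormal temporal modes
  ny <- 12; nx <- 14
  nv <- ny * nx
  set.seed(33)
  W <- matrix(stats::rnorm(nv * 4), nv) %*% diag(c(4, 2, 1, 0.5))
  X <- W %*% modes                        # voxels x time
  X <- X + stats::rnorm(length(X), 0, 0.01 * sqrt(mean(X^2)))
  arr <- array(NA_real_, c(length(tg), ny, nx))
  for (i in seq_along(tg)) arr[i, , ] <- matrix(X[, i], ny, nx)
  trv <- time_resolved_volume(arr, tg)
  mask <- matrix(TRUE, ny, nx)
  pk <- extract_pk_basis(list(trv), list(mask), n_max = 4, grid_step = 1)
  expect_equal(elbow_select(pk$singular_values), 4)
  ang <- principal_angles_deg(pk$basis$values,
                              t(resample_time_series(t(modes), tg, pk$basis$sample_grid)))
  expect_lt(max(ang), 2)
  expect_lt(max(abs(basis_gram(pk$basis) - diag(4))), 1e-8)
})

test_that("rank-one input yields a single dominant mode, invariant to masking", {
  tg <- seq(0, 20, by = 0.5)
  mode <- gamma_variate_tac(tg, 3, 3, 2, 1) + 0.5
  ny <- 8; nx <- 8
  arr <- array(0, c(length(tg), ny, nx))
  set.seed(4)
  amps <- matrix(runif(ny * nx, 0.5, 2), ny, nx)
  for (i in seq_along(tg)) arr[i, , ] <- amps * mode[i]
  trv <- time_resolved_volume(arr, tg)
  m1 <- matrix(TRUE, ny, nx)
  m2 <- m1; m2[, 1:4] <- FALSE
  pk1 <- extract_pk_basis(list(trv), list(m1), n_max = 2, grid_step = 0.5)
  pk2 <- extract_pk_basis(list(trv), list(m2), n_max = 2, grid_step = 0.5)
  expect_lt(pk1$singular_values[2] / pk1$singular_values[1], 1e-8)
  # leading modes agree up to sign regardless of the mask
  v1 <- pk1$basis$values[1, ]; v2 <- pk2$basis$values[1, ]
  expect_gt(abs(sum(v1 * v2)) / sqrt(sum(v1^2) * sum(v2^2)), 1 - 1e-8)
})

test_that("time alignment records shifts, exclusions and crops per contract", {
  b <- analytical_basis(40, 4)
  # identity alignment
  al0 <- align_basis_to_scan(b, basis_aif_peak = 10, scan_aif_peak = 10,
                             scan_span = c(0, 40))
  expect_equal(al0$shift, 0)
  expect_equal(al0$excluded, c(0, 0))
  expect_equal(al0$crop, c(0, 0))
  # bolus arrives 1.5 s later in the scan: first 1.5 s unsupported
  al1 <- align_basis_to_scan(b, 10, 11.5, c(0, 40))
  expect_equal(al1$shift, 1.5)
  expect_equal(al1$excluded[1], 1.5)
  expect_equal(al1$crop[2], 1.5)
  # basis 10 s longer than the scan: cropped, nothing excluded
  b2 <- analytical_basis(50, 4)
  al2 <- align_basis_to_scan(b2, 10, 10, c(0, 40))
  expect_equal(al2$crop, c(0, 10))
  expect_equal(al2$excluded, c(0, 0))
  # peaks must lie inside their respective intervals
  expect_error(align_basis_to_scan(b, 50, 10, c(0, 40)), "basis support")
  expect_error(align_basis_to_scan(b, 10, 50, c(0, 40)), "scan span")
})

test_that("basis resampling is exact on-grid and accurate off-grid", {
  b <- analytical_basis(30, 4, seq(0, 30, length.out = 1000))
  # grid coincidence: stored values returned exactly
  sub <- seq(1, 1000, by = 37)
  rb <- resample_basis(b, b$sample_grid[sub])
  expect_equal(rb$design, t(b$values[, sub]), tolerance = 1e-12)
  expect_true(all(rb$valid))
  # off-grid sine against the closed form
  tq <- seq(0.013, 29.9, length.out = 500)
  rb2 <- resample_basis(b, tq)
  nrm <- sqrt(sum(sin(2 * pi * b$sample_grid / 30)^2 * tstperf:::quad_weights(b$sample_grid)))
  expect_lt(max(abs(rb2$design[, 2] - sin(2 * pi * tq / 30) / nrm)), 1e-4)
  # times before the shifted support are masked out, not extrapolated
  al <- align_basis_to_scan(b, 10, 12, c(0, 30))
  rb3 <- resample_basis(b, seq(0, 10, by = 0.5), al)
  expect_equal(rb3$valid, seq(0, 10, by = 0.5) >= 2)
  expect_true(all(rb3$design[!rb3$valid, ] == 0))
  expect_error(resample_basis(b, c(-50, -40), al), "valid")
})

test_that("re-orthonormalization preserves the span and is idempotent", {
  b <- analytical_basis(40, 4)
  again <- reorthonormalize(b)
  expect_equal(again$values, b$values, tolerance = 1e-10)
  # cropping destroys orthonormality; re-orthonormalization restores it on the same span
  cr <- crop_basis(b, 8, 32)
  expect_gt(max(abs(basis_gram(cr) - diag(4))), 1e-3)
  ro <- reorthonormalize(cr)
  expect_lt(max(abs(basis_gram(ro) - diag(4))), 1e-10)
  # span projector comparison against an independent QR oracle
  w <- tstperf:::quad_weights(cr$sample_grid)
  M <- t(cr$values * rep(sqrt(w), each = 4))
  Q <- qr.Q(qr(M))
  P_oracle <- tcrossprod(Q)
  Mr <- t(ro$values * rep(sqrt(w), each = 4))
  P_ro <- tcrossprod(Mr)
  expect_lt(max(abs(P_ro - P_oracle)), 1e-8)
  # duplicated function is rank deficient
  dup <- basis_set(rbind(b$values, b$values[2, ]), b$sample_grid, b$support)
  expect_error(reorthonormalize(dup), "dependent")
})

test_that("basis sets round-trip through CSV", {
  b <- analytical_basis(20, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_basis_csv(b, path)
  back <- read_basis_csv(path)
  expect_equal(back$values, b$values, tolerance = 1e-12)
  expect_equal(back$support, b$support)
  expect_equal(back$provenance, b$provenance)
})
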