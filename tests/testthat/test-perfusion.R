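test_that("AIF selection follows peak value then earliest peak then lowest index", {
  tt <- seq(0, 20, length.out = 50)
  base <- gamma_variate_tac(tt, 2, 3, 1.5, 1)
  tacs <- cbind(5 * base,                                   # peak 5
                10 * base,                                  # peak 10, earlier index
                10 * gamma_variate_tac(tt, 3, 3, 1.5, 1))   # peak 10, later peak time
  # forced choice
  one <- select_aif(tacs, tt, roi = 1L)
  expect_equal(one$location, 1L)
  # dominance by peak value
  expect_equal(select_aif(tacs, tt, roi = c(1L, 2L))$location, 2L)
  # tie on peak value: earlier peak wins
  tie <- select_aif(tacs, tt, roi = c(3L, 2L))
  expect_equal(tie$location, 2L)
  expect_equal(tie$samples[1], 0)                           # baseline-subtracted
  expect_equal(tie$peak_value, max(tie$samples))
  expect_error(select_aif(matrix(0, 50, 2), tt, roi = 1:2), "positive")
  # ROI averaging option
  avg <- select_aif(tacs, tt, roi = 1:2, average = TRUE)
  expect_equal(avg$peak_value, 7.5 * max(base), tolerance = 1e-9)
})

test_that("the AIF convolution matrix is Toeplitz and matches direct convolution", {
  set.seed(9)
  aif <- c(0, runif(7))
  dt <- 0.5
  A <- build_aif_matrix(aif, dt)
  # delta kernel: identity (times dt)
  expect_equal(build_aif_matrix(c(1, 0, 0, 0), 1), diag(4))
  # Toeplitz structure
  for (i in 1:7) for (j in 1:7) expect_equal(A[i + 1, j + 1], A[i, j])
  # A %*% k equals brute-force discrete convolution
  k <- rnorm(8)
  conv <- sapply(1:8, function(i) sum(aif[1:i] * rev(k[1:i])) * dt)
  expect_equal(as.numeric(A %*% k), conv, tolerance = 1e-12)
  # dt_scaling off: plain unscaled discrete sums
  expect_equal(build_aif_matrix(aif, dt, dt_scaling = FALSE), A / dt)
})

test_that("truncated-SVD deconvolution recovers a planted kernel and is linear", {
  n <- 100
  tu <- seq(0, 30, length.out = n)
  dt <- tu[2] - tu[1]
  # steep bolus from t = 0 keeps the convolution matrix well conditioned
  # (its last column is structurally zero, so the final sample is unrecoverable)
  aif <- make_aif(gamma_variate_tac(tu, 0, 2, 1.5, 50), tu)
  k_true <- 0.08 * exp(-tu / 5)
  tac <- as.numeric(build_aif_matrix(aif$samples, dt) %*% k_true)
  kp <- tsvd_deconvolve(tac, aif, deconv_config(lambda_rel = 1e-12))
  expect_lt(max(abs(kp - k_true)[1:(n - 1)]), 1e-6 * max(k_true))
  # lambda_rel = 1: nothing is strictly larger than sigma_max -> zero kernel
  expect_equal(tsvd_deconvolve(tac, aif, deconv_config(lambda_rel = 1)),
               rep(0, n))
  # linearity
  k2 <- tsvd_deconvolve(3 * tac, aif, deconv_config(lambda_rel = 0.3))
  k1 <- tsvd_deconvolve(tac, aif, deconv_config(lambda_rel = 0.3))
  expect_equal(k2, 3 * k1, tolerance = 1e-10)
  expect_error(tsvd_deconvolve(tac, make_aif(rep(0, n), tu), deconv_config()),
               "zero AIF")
})

test_that("perfusion parameters match the closed form of an exponential residue kernel", {
  n <- 100
  tu <- seq(0, 30, length.out = n)
  dt <- tu[2] - tu[1]
  k0 <- 0.08; tau <- 5
  aif <- make_aif(gamma_variate_tac(tu, 1, 2, 1.5, 50), tu)
  k_true <- k0 * exp(-tu / tau)
  tac <- as.numeric(build_aif_matrix(aif$samples, dt) %*% k_true)
  maps <- compute_perfusion_maps(matrix(tac, ncol = 1), tu, aif,
                                 deconv_config(lambda_rel = 1e-12))
  bv_closed <- k0 * tau * (1 - exp(-30 / tau))
  expect_equal(maps$BF[1], k0, tolerance = 0.05)
  expect_equal(maps$BV[1], bv_closed, tolerance = 0.05)
  expect_equal(maps$MTT[1], bv_closed / k0, tolerance = 0.05)
  # algebraic identity at the working regularization
  maps2 <- compute_perfusion_maps(matrix(tac, ncol = 1), tu, aif,
                                  deconv_config(lambda_rel = 0.3))
  expect_equal(maps2$MTT[1] * maps2$BF[1], maps2$BV[1], tolerance = 1e-12)
})

test_that("TTP is the grid time of the TAC maximum", {
  n <- 100
  tu <- seq(0, 30, length.out = n)
  tac <- c(seq(0, 1, length.out = 40), seq(1, 0.2, length.out = 60))[1:n]
  aif <- make_aif(gamma_variate_tac(tu, 1, 2, 1.5, 50), tu)
  maps <- compute_perfusion_maps(matrix(tac, ncol = 1), tu, aif, deconv_config())
  expect_equal(maps$TTP[1], tu[40])
})

test_that("regularization is monotone in the number of inverted singular values", {
  n <- 80
  tu <- seq(0, 25, length.out = n)
  dt <- tu[2] - tu[1]
  aif <- make_aif(gamma_variate_tac(tu, 1, 2, 1.5, 50), tu)
  A <- build_aif_matrix(aif$samples, dt)
  sv <- svd(A)$d
  n_inv <- sapply(c(0, 1e-6, 0.01, 0.1, 0.3, 0.6, 1), function(l) sum(sv > l * sv[1]))
  expect_true(all(diff(n_inv) <= 0))
  # BF nonincreasing in lambda_rel on the planted-kernel fixture
  k_true <- 0.08 * exp(-tu / 5)
  tac <- as.numeric(A %*% k_true)
  bf <- sapply(c(1e-12, 0.05, 0.15, 0.3, 0.6),
               function(l) max(tsvd_deconvolve(tac, aif, deconv_config(lambda_rel = l))))
  expect_true(all(diff(bf) <= 1e-12))
})

test_that("BV and MTT are stable under grid refinement with dt scaling on", {
  tt <- seq(0, 41, by = 0.5)
  ph <- build_phantom(phantom_spec(nx = 32, pixel_size = 6))
  voxels <- which(as.vector(ph$masks$healthy))[c(10, 80)]
  tacs <- phantom_tacs(ph, tt, voxels)
  art <- phantom_tacs(ph, tt, which(as.vector(ph$masks$artery))[1])
  for (np in c(100, 200)) {
    cfgd <- deconv_config(n_points = np)
    aif <- make_aif(as.numeric(art), tt)
    m <- compute_perfusion_maps(tacs, tt, aif, cfgd)
    assign(paste0("m", np), m)
  }
  expect_equal(m100$BV, m200$BV, tolerance = 0.02)
  expect_equal(m100$MTT, m200$MTT, tolerance = 0.02)
})

test_that("masked Gaussian smoothing matches a brute-force convolution oracle", {
  set.seed(14)
  img <- matrix(stats::rnorm(32 * 32), 32)
  mask <- matrix(TRUE, 32, 32)
  sig <- 2.5
  out <- tstperf:::gaussian_blur_masked(img, sig, mask)
  # brute force: full 2D kernel, normalized over in-image support
  r <- ceiling(4 * sig)
  k1 <- stats::dnorm(-r:r, sd = sig)
  K2 <- outer(k1, k1)
  brute <- matrix(NA_real_, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    ii <- (i - r):(i + r); jj <- (j - r):(j + r)
    ok_i <- ii >= 1 & ii <= 32; ok_j <- jj >= 1 & jj <= 32
    W <- K2[ok_i, ok_j]
    brute[i, j] <- sum(W * img[ii[ok_i], jj[ok_j]]) / sum(W)
  }
  expect_equal(out, brute, tolerance = 1e-8)
  # constant map invariance inside an irregular mask
  m2 <- matrix(FALSE, 32, 32); m2[5:25, 8:30] <- TRUE
  cimg <- matrix(7, 32, 32)
  sm <- tstperf:::gaussian_blur_masked(cimg, 3, m2)
  expect_equal(sm[m2], rep(7, sum(m2)), tolerance = 1e-10)
  # sigma 0 is the identity
  expect_identical(tstperf:::gaussian_blur_masked(img, 0, mask), img)
})

test_that("smooth_maps smooths inside the organ only and keeps MTT voxels defined", {
  tt <- seq(0, 41, length.out = 60)
  ph <- build_phantom(phantom_spec(nx = 32, pixel_size = 6))
  tacs <- phantom_tacs(ph, tt)
  aif <- select_aif(tacs, tt, which(as.vector(ph$masks$artery)))
  tissue <- ph$masks$healthy | ph$masks$embolized
  maps <- compute_perfusion_maps(tacs, tt, aif, deconv_config(), mask = tissue,
                                 shape = c(32, 32))
  sm <- smooth_maps(maps)
  expect_equal(sm$BF[!tissue], maps$BF[!tissue])   # background untouched
  expect_false(any(is.na(sm$BF[tissue & maps$defined])))
})
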