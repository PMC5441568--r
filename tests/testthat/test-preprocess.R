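# Preprocessing chain contracts: volume trim, global scaling, zero-phase
# band-pass (periodogram oracle), nuisance regression (least-squares
# oracle), Gaussian smoothing (impulse-response fit), and the composed
# chain.

test_that("drop_initial_volumes trims exactly and validates", {
  scan <- tiny_scan(n_volumes = 240)
  out <- drop_initial_volumes(scan, 6)
  expect_equal(dim(out)[4], 234L)
  expect_identical(out$data, scan$data[, , , -(1:6)])
  expect_identical(drop_initial_volumes(scan, 0), scan)
  short <- tiny_scan(grid = c(8, 8, 4), n_volumes = 35)
  short$data <- short$data[, , , 1:5, drop = FALSE]
  expect_error(drop_initial_volumes(short, 6), "cannot drop")
})

test_that("intensity_scale hits the target mean with one positive factor", {
  scan <- tiny_scan(n_volumes = 40)
  scan$data <- scan$data / mean(scan$data) * 500      # mean exactly 500
  out <- intensity_scale(scan)
  expect_equal(mean(out$data), 10000, tolerance = 1e-6)
  expect_equal(attr(out, "scale_factor"), 20, tolerance = 1e-9)
  again <- intensity_scale(out)
  expect_equal(attr(again, "scale_factor"), 1, tolerance = 1e-9)
  zero <- scan; zero$data[] <- 0
  expect_error(intensity_scale(zero), "positive")
})

test_that("bandpass attenuates/retains on-grid sinusoids (periodogram oracle)", {
  grid <- c(4, 4, 2); n <- 100; tr <- 2
  tt <- seq_len(n)
  mk <- function(freq) {
    Y <- matrix(rep(sin(2 * pi * freq * tt * tr), each = prod(grid)), prod(grid), n)
    new_scan(array(Y, c(grid, n)), tr_seconds = tr)
  }
  hi <- bandpass(mk(0.2))                 # out of band
  expect_lt(max(abs(hi$data)) / 1, 0.1)
  lo <- bandpass(mk(0.04))                # in band
  v_in <- mk(0.04)$data[1, 1, 1, ]
  v_out <- lo$data[1, 1, 1, ]
  expect_gt(max(abs(v_out)) / max(abs(v_in)), 0.9)
  # zero phase: in-band sinusoid not shifted (correlation ~ 1)
  expect_gt(cor(v_in, v_out), 0.999)
  cst <- mk(0); cst$data[] <- 7
  expect_lt(max(abs(bandpass(cst)$data)), 1e-10)
  expect_error(bandpass(mk(0.04), low_hz = 0.01, high_hz = 0.3), "Nyquist")
})

test_that("bandpass is idempotent to < 1% RMS", {
  scan <- tiny_scan(n_volumes = 120, seed = 5)
  once <- bandpass(scan)
  twice <- bandpass(once)
  rel <- sqrt(mean((twice$data - once$data)^2)) / sqrt(mean(once$data^2))
  expect_lt(rel, 0.01)
})

test_that("regress_nuisance residuals are orthogonal to the design", {
  n <- 60
  scan <- tiny_scan(grid = c(8, 8, 4), n_volumes = n, seed = 3)
  nus <- tiny_nuisance(n, seed = 3)
  out <- regress_nuisance(scan, nus)
  tt <- seq_len(n) / n
  X <- cbind(1, tt, tt^2, nus$motion, nus$wm, nus$csf)
  Xn <- sweep(X, 2, sqrt(colSums(X^2)), "/")       # unit-norm columns
  R <- t(matrix(out$data, prod(dim(out)[1:3]), n))
  expect_lt(max(abs(crossprod(Xn, R))), 1e-8 * max(abs(scan$data)))
  # a voxel equal to a motion regressor vanishes
  scan2 <- scan; scan2$data[1, 1, 1, ] <- nus$motion[, 3]
  out2 <- regress_nuisance(scan2, nus)
  expect_lt(max(abs(out2$data[1, 1, 1, ])), 1e-8)
  # pure quadratic trend vanishes
  scan3 <- scan; scan3$data[2, 1, 1, ] <- (seq_len(n) / n)^2
  expect_lt(var(regress_nuisance(scan3, nus)$data[2, 1, 1, ]), 1e-10)
  # independent noise: residual correlation with each regressor ~ 0
  set.seed(9); scan4 <- scan; scan4$data[3, 1, 1, ] <- rnorm(n)
  r4 <- regress_nuisance(scan4, nus)$data[3, 1, 1, ]
  expect_lt(max(abs(cor(X[, -1], r4))), 1e-6)
  bad <- nus; bad$wm <- bad$wm[-1]
  expect_error(regress_nuisance(scan, bad), "length")
})

test_that("smoothing has the stated FWHM and conserves interior mass", {
  grid <- c(21, 21, 15)                             # >= 6 sigma of edge margin
  arr <- array(0, c(grid, 1)); arr[11, 11, 8, 1] <- 1
  scan <- new_scan(arr, voxel_size_mm = c(3, 3, 3))
  sm <- smooth_scan(scan, fwhm_mm = 6)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)   # impulse far from edges
  prof <- sm$data[, 11, 8, 1]
  # Gaussian width from the profile's second moment (independent oracle)
  s_hat <- sqrt(sum(prof * (1:21 - 11)^2) / sum(prof))
  fwhm_vox <- 2 * sqrt(2 * log(2)) * s_hat
  expect_lt(abs(fwhm_vox - 2), 2 * 0.05)            # 6 mm / 3 mm = 2 voxels, +-5%
  expect_identical(smooth_scan(scan, 0), scan)
  cst <- scan; cst$data[] <- 3.5
  expect_equal(smooth_scan(cst, 6)$data, cst$data, tolerance = 1e-12)
  expect_error(smooth_scan(scan, -1), "fwhm")
})

test_that("the full chain composes in order and is configurable", {
  n <- 240
  scan <- tiny_scan(grid = c(8, 8, 4), n_volumes = n, seed = 11)
  nus <- tiny_nuisance(n, seed = 11)
  out <- preprocess_scan(scan, nus)
  expect_equal(dim(out)[4], 234L)
  expect_length(attr(out, "provenance"), 5L)
  # out-of-band power < 10% after the chain (on a high-variance voxel)
  v <- out$data[3, 3, 2, ]
  expect_gt(band_fraction(v, tr = 2), 0.9)
  # disabling smoothing equals the chain without it
  no_sm <- preprocess_scan(scan, nus, params = list(do_smooth = FALSE))
  manual <- regress_nuisance(
    bandpass(intensity_scale(drop_initial_volumes(scan, 6))),
    lapply(list(motion = nus$motion[-(1:6), , drop = FALSE],
                wm = nus$wm[-(1:6)], csf = nus$csf[-(1:6)]), identity))
  expect_scan_equal(no_sm, manual, tol = 1e-9)
  bad <- tiny_nuisance(100)
  expect_error(preprocess_scan(scan, bad), "length")
  expect_error(preprocess_scan(scan, NULL), "nuisance")
})

test_that("bandpass/regress/smooth are linear in the input", {
  n <- 80
  scan <- tiny_scan(grid = c(8, 8, 4), n_volumes = n, seed = 13)
  nus <- tiny_nuisance(n, seed = 13)
  chain <- function(s) smooth_scan(regress_nuisance(bandpass(s), nus), 6)
  s2 <- scan; s2$data <- 3 * s2$data
  expect_scan_equal(chain(s2), {
    r <- chain(scan); r$data <- 3 * r$data; r
  }, tol = 1e-8 * max(abs(scan$data)))
})
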