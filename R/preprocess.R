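# Temporal/spatial cleaning chain for pre-aligned 4-D scans:
# drop initial volumes -> global intensity scaling -> zero-phase band-pass ->
# nuisance + polynomial-trend regression -> Gaussian smoothing.
# Slice-timing, motion correction and spatial normalization are out of scope:
# the generator emits aligned data.

#' Discard initial volumes
#'
#' Removes the first `k` volumes (magnetization-equilibration scrub).
#'
#' @param scan an `icn_scan`.
#' @param k number of volumes to discard (default 6).
#' @return the trimmed scan.
#' @export
drop_initial_volumes <- function(scan, k = 6) {
  stopifnot(inherits(scan, "icn_scan"))
  k <- .chk_count(k, "k", min = 0L)
  if (n_volumes(scan) <= k)
    stop(sprintf("invalid input: scan has %d volumes, cannot drop %d",
                 n_volumes(scan), k), call. = FALSE)
  if (k == 0L) return(scan)
  scan$data <- scan$data[, , , -seq_len(k), drop = FALSE]
  scan
}

#' Scale a scan to a target global mean
#'
#' Multiplies the whole 4-D grid by a single positive factor so the global
#' mean equals `target` (default 10,000).
#'
#' @param scan an `icn_scan`.
#' @param target target whole-scan mean intensity.
#' @return list-free: the scaled scan with attribute `scale_factor`.
#' @export
intensity_scale <- function(scan, target = 10000) {
  stopifnot(inherits(scan, "icn_scan"))
  m <- mean(scan$data)
  if (!is.finite(m) || m <= 0)
    stop("invalid input: whole-scan mean must be positive for intensity scaling",
         call. = FALSE)
  factor <- target / m
  scan$data <- scan$data * factor
  attr(scan, "scale_factor") <- factor
  scan
}

#' Zero-phase temporal band-pass filter
#'
#' Frequency-domain masking with a raised-cosine transition of width
#' `transition_hz` on each band edge.  The mask is real and applied
#' symmetrically, so the filter is exactly zero-phase; DC is always removed.
#'
#' @param scan an `icn_scan`.
#' @param low_hz,high_hz pass-band edges in Hz (default 0.01-0.08).
#' @param transition_hz half-width of the raised-cosine roll-off.
#' @return the filtered scan.
#' @export
bandpass <- function(scan, low_hz = 0.01, high_hz = 0.08, transition_hz = 0.002) {
  stopifnot(inherits(scan, "icn_scan"))
  nyq <- 1 / (2 * scan$tr_seconds)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    stop(sprintf("invalid configuration: band (%g, %g) Hz must lie inside (0, Nyquist = %g) Hz",
                 low_hz, high_hz, nyq), call. = FALSE)
  Tn <- n_volumes(scan)
  freqs <- seq(0, Tn - 1) / (Tn * scan$tr_seconds)
  freqs <- pmin(freqs, 1 / scan$tr_seconds - freqs)   # fold to [0, Nyquist]
  mask <- .bp_mask(freqs, low_hz, high_hz, transition_hz)
  Y <- scan_matrix(scan)
  mu <- rowMeans(Y)
  spec <- mvfft(t(Y - mu))                            # time x voxel
  filt <- Re(mvfft(spec * mask, inverse = TRUE)) / Tn
  matrix_to_scan(t(filt), scan)
}

.bp_mask <- function(f, lo, hi, tw) {
  m <- numeric(length(f))
  m[f >= lo & f <= hi] <- 1
  if (tw > 0) {
    lo_band <- f > lo - tw & f < lo
    m[lo_band] <- 0.5 * (1 + cos(pi * (lo - f[lo_band]) / tw))
    hi_band <- f > hi & f < hi + tw
    m[hi_band] <- 0.5 * (1 + cos(pi * (f[hi_band] - hi) / tw))
  }
  m[f == 0] <- 0
  m
}

#' Regress nuisance series and polynomial trends out of a scan
#'
#' Projects every voxel time series onto the orthogonal complement of the
#' span of {intercept, linear trend, quadratic trend, six motion parameters,
#' WM mean, CSF mean}.  Residuals are orthogonal to that span at machine
#' precision.
#'
#' @param scan an `icn_scan`.
#' @param nuisance list with `motion` (T x 6 matrix), `wm` and `csf`
#'   (length-T vectors); series lengths must match the volume count.
#' @param detrend include linear and quadratic trend columns (default TRUE).
#' @return the residual scan.
#' @export
regress_nuisance <- function(scan, nuisance, detrend = TRUE) {
  stopifnot(inherits(scan, "icn_scan"))
  Tn <- n_volumes(scan)
  motion <- as.matrix(nuisance$motion)
  if (nrow(motion) != Tn || length(nuisance$wm) != Tn || length(nuisance$csf) != Tn)
    stop(sprintf("invalid input: nuisance length(s) do not match %d volumes", Tn),
         call. = FALSE)
  if (ncol(motion) != 6L)
    stop("invalid input: motion must have 6 columns", call. = FALSE)
  tt <- seq_len(Tn) / Tn
  X <- cbind(1, if (detrend) cbind(tt, tt^2), motion, nuisance$wm, nuisance$csf)
  qrX <- qr(X)
  Y <- t(scan_matrix(scan))                 # time x voxel
  res <- qr.resid(qrX, Y)
  matrix_to_scan(t(res), scan)
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with the kernel width given as
#' full-width-at-half-maximum in mm, converted to voxels via the scan's
#' voxel size.  Edges use renormalized (truncated-kernel) weights, so
#' constant volumes are preserved exactly.
#'
#' @param scan an `icn_scan`.
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @return the smoothed scan.
#' @export
smooth_scan <- function(scan, fwhm_mm = 6) {
  stopifnot(inherits(scan, "icn_scan"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("invalid configuration: fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(scan)
  d <- dim(scan$data)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / scan$voxel_size_mm[1:3]
  Ks <- lapply(1:3, function(ax) .gauss_matrix(d[ax], sig[ax]))
  Y <- scan$data
  Y <- array(Ks[[1]] %*% matrix(Y, d[1], prod(d[-1])), d)                      # x
  Y <- aperm(array(Ks[[2]] %*% matrix(aperm(Y, c(2, 1, 3, 4)), d[2], prod(d[-2])),
                   c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4))                  # y
  Y <- aperm(array(Ks[[3]] %*% matrix(aperm(Y, c(3, 1, 2, 4)), d[3], prod(d[-3])),
                   c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))                  # z
  scan$data <- Y
  scan
}

# Row-renormalized 1-D Gaussian convolution matrix.
.gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) dnorm(j - i, sd = sigma))
  K / rowSums(K)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: volume drop, intensity scaling, band-pass, nuisance +
#' trend regression, spatial smoothing.  Each stage can be disabled through
#' `params`; provenance of the applied steps is attached as an attribute.
#'
#' @param scan an `icn_scan`.
#' @param nuisance nuisance set (see [regress_nuisance()]); required when
#'   the regression stage is enabled.
#' @param params list of stage parameters: `k_drop` (6), `target_mean`
#'   (10000), `band` (c(0.01, 0.08)), `fwhm_mm` (6), and logical switches
#'   `do_drop`, `do_scale`, `do_bandpass`, `do_regress`, `do_smooth`.
#' @return the preprocessed scan with attribute `provenance` (character
#'   vector of applied steps).
#' @export
preprocess_scan <- function(scan, nuisance = NULL, params = list()) {
  p <- modifyList(list(k_drop = 6, target_mean = 10000, band = c(0.01, 0.08),
                       fwhm_mm = 6, do_drop = TRUE, do_scale = TRUE,
                       do_bandpass = TRUE, do_regress = TRUE, do_smooth = TRUE),
                  params)
  steps <- character(0)
  if (p$do_drop) {
    scan <- drop_initial_volumes(scan, p$k_drop)
    if (!is.null(nuisance) && p$k_drop > 0) {
      keep <- -seq_len(p$k_drop)
      nuisance <- list(motion = nuisance$motion[keep, , drop = FALSE],
                       wm = nuisance$wm[keep], csf = nuisance$csf[keep])
    }
    steps <- c(steps, sprintf("drop_initial_volumes(k=%d)", p$k_drop))
  }
  if (p$do_scale) {
    scan <- intensity_scale(scan, p$target_mean)
    steps <- c(steps, sprintf("intensity_scale(target=%g)", p$target_mean))
  }
  if (p$do_bandpass) {
    scan <- bandpass(scan, p$band[1], p$band[2])
    steps <- c(steps, sprintf("bandpass(%g-%g Hz)", p$band[1], p$band[2]))
  }
  if (p$do_regress) {
    if (is.null(nuisance))
      stop("invalid input: nuisance set required for the regression stage", call. = FALSE)
    scan <- regress_nuisance(scan, nuisance)
    steps <- c(steps, "regress_nuisance(motion6+wm+csf+trends)")
  }
  if (p$do_smooth) {
    scan <- smooth_scan(scan, p$fwhm_mm)
    steps <- c(steps, sprintf("smooth(fwhm=%gmm)", p$fwhm_mm))
  }
  attr(scan, "provenance") <- steps
  scan
}
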