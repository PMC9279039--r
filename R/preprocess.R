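# Voxelwise series live in a (voxels x T) matrix throughout this file;
# helpers convert from/to the 4D array once per call.
asVoxelMatrix <- function(vol) {
  d <- dim(vol@data)
  matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4])
}
fromVoxelMatrix <- function(m, vol) {
  new("TimeSeriesVolume", data = array(m, dim = dim(vol@data)),
      trSeconds = vol@trSeconds)
}

#' Remove the per-voxel linear trend
#'
#' Fits and subtracts an ordinary-least-squares line over time for every
#' voxel. Output series have zero mean and zero linear trend; the operation
#' is idempotent.
#'
#' @param vol a \linkS4class{TimeSeriesVolume} with >= 3 time points.
#' @return A detrended \linkS4class{TimeSeriesVolume}.
#' @export
detrendLinear <- function(vol) {
  stopifnot(is(vol, "TimeSeriesVolume"))
  T <- dim(vol@data)[4]
  if (T < 3L) stop("detrendLinear requires >= 3 time points")
  X <- asVoxelMatrix(vol)
  tc <- seq_len(T) - (T + 1) / 2           # centred time covariate
  slope <- (X %*% tc) / sum(tc * tc)
  res <- X - rowMeans(X) - slope %*% t(tc)
  fromVoxelMatrix(res, vol)
}

#' Frequency-domain band-pass filter
#'
#' Forward DFT per voxel, zeroing of every bin whose frequency lies outside
#' [lowHz, highHz] (conjugate symmetry preserved, so the inverse transform
#' is exactly real), inverse DFT. A bin at frequency f = min(k, T-k) * fs/T
#' is kept iff lowHz <= f <= highHz; the boxcar transfer function makes the
#' filter idempotent. The DC bin is removed whenever lowHz > 0.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param lowHz,highHz band edges in Hz, 0 <= lowHz < highHz <= fs/2.
#' @return A filtered \linkS4class{TimeSeriesVolume}.
#' @export
bandpassFilter <- function(vol, lowHz = 0.01, highHz = 0.08) {
  stopifnot(is(vol, "TimeSeriesVolume"))
  fs <- 1 / vol@trSeconds
  if (!(lowHz >= 0 && lowHz < highHz && highHz <= fs / 2 + 1e-12))
    stop(sprintf("band [%g, %g] Hz invalid for fs = %g Hz (need 0 <= low < high <= fs/2)",
                 lowHz, highHz, fs))
  T <- dim(vol@data)[4]
  freq <- pmin(0:(T - 1), T - (0:(T - 1))) * fs / T
  keep <- freq >= lowHz & freq <= highHz
  X <- asVoxelMatrix(vol)
  F <- t(mvfft(t(X)))
  F[, !keep] <- 0
  Y <- Re(t(mvfft(t(F), inverse = TRUE))) / T
  fromVoxelMatrix(Y, vol)
}

# truncated discrete Gaussian kernel, renormalised to sum 1
gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D renormalised convolution along one axis of a 3D array: border weights
# are rescaled by the in-grid kernel mass so constants are preserved exactly
convolveAxis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, d); wsum <- array(0, d)
  for (o in (-r):r) {
    w <- kernel[o + r + 1L]
    n <- d[axis]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    idxTo <- which(ok); idxFrom <- src[ok]
    if (axis == 1L) {
      out[idxTo, , ] <- out[idxTo, , , drop = FALSE] + w * a[idxFrom, , , drop = FALSE]
      wsum[idxTo, , ] <- wsum[idxTo, , , drop = FALSE] + w
    } else if (axis == 2L) {
      out[, idxTo, ] <- out[, idxTo, , drop = FALSE] + w * a[, idxFrom, , drop = FALSE]
      wsum[, idxTo, ] <- wsum[, idxTo, , drop = FALSE] + w
    } else {
      out[, , idxTo] <- out[, , idxTo, drop = FALSE] + w * a[, , idxFrom, drop = FALSE]
      wsum[, , idxTo] <- wsum[, , idxTo, drop = FALSE] + w
    }
  }
  out / wsum
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution of each time point, with border weights
#' renormalised (constants are preserved). \code{fwhmVoxels = 0} is the
#' identity. sigma = fwhm / (2 sqrt(2 log 2)). Smoothing defaults to off in
#' the feature pipeline: the concordance feature explicitly requires
#' unsmoothed input, and the other features do their own spatial pooling.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param fwhmVoxels kernel full width at half maximum, in voxels (>= 0).
#' @return A smoothed \linkS4class{TimeSeriesVolume}.
#' @export
smoothGaussian <- function(vol, fwhmVoxels) {
  stopifnot(is(vol, "TimeSeriesVolume"))
  if (fwhmVoxels < 0) stop("fwhmVoxels must be >= 0")
  if (fwhmVoxels == 0) return(vol)
  sigma <- fwhmVoxels / (2 * sqrt(2 * log(2)))
  k <- gaussKernel1d(sigma)
  d <- dim(vol@data)
  out <- vol@data
  for (tt in seq_len(d[4])) {
    sl <- out[, , , tt, drop = FALSE]
    dim(sl) <- d[1:3]
    for (ax in 1:3) if (d[ax] > 1L) sl <- convolveAxis(sl, k, ax)
    out[, , , tt] <- sl
  }
  fromVoxelMatrix(matrix(out, nrow = prod(d[1:3])), vol)
}

#' Preprocess a volume for a given feature family
#'
#' Fixed pipeline wiring: the spectral features (ALFF, fALFF) consume
#' detrended but UNfiltered series — their fractional variant needs the
#' full spectrum in its denominator — while the correlation features (FC,
#' DC, ReHo) consume detrended, band-passed series. Optional smoothing is
#' applied to every family except ReHo, which requires unsmoothed input.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param feature one of "ALFF", "fALFF", "FC", "DC", "ReHo".
#' @param detrend "linear" (default) or "none".
#' @param bandLowHz,bandHighHz pass band in Hz for the correlation features.
#' @param smoothFwhmVoxels Gaussian FWHM in voxels; 0 (default) disables.
#' @return A preprocessed \linkS4class{TimeSeriesVolume}.
#' @export
preprocessFor <- function(vol, feature, detrend = "linear",
                          bandLowHz = 0.01, bandHighHz = 0.08,
                          smoothFwhmVoxels = 0) {
  feature <- match.arg(feature, c("ALFF", "fALFF", "FC", "DC", "ReHo"))
  detrend <- match.arg(detrend, c("linear", "none"))
  if (detrend == "linear") vol <- detrendLinear(vol)
  if (feature %in% c("FC", "DC", "ReHo"))
    vol <- bandpassFilter(vol, bandLowHz, bandHighHz)
  if (smoothFwhmVoxels > 0 && feature != "ReHo")
    vol <- smoothGaussian(vol, smoothFwhmVoxels)
  vol
}
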