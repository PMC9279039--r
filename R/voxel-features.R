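# neighbourhood offset table: 7 = faces, 19 = faces+edges, 27 = full cube
# (each includes the centre voxel, as is conventional for ReHo)
neighbourhoodOffsets <- function(k) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(g))
  switch(as.character(k),
         "7"  = g[man <= 1, , drop = FALSE],
         "19" = g[man <= 2, , drop = FALSE],
         "27" = g,
         stop("neighbourhood must be 7, 19 or 27"))
}

#' Voxelwise degree centrality
#'
#' For every voxel, the number of other voxels whose time-series Pearson
#' correlation exceeds \code{threshold}. The threshold applies to the
#' SIGNED correlation (strictly greater): a voxel anticorrelated with all
#' others has degree 0. \code{absolute = TRUE} switches to |r| > threshold.
#' Zero-variance voxels get degree 0 and are flagged in the
#' \code{"flaggedVoxels"} attribute of the returned values. Input is
#' expected to be band-passed.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param threshold correlation threshold in (-1, 1); default 0.25.
#' @param absolute threshold |r| instead of r.
#' @param subjectId subject id stored in the map.
#' @return A \linkS4class{FeatureMap} of integer counts.
#' @export
degreeCentrality <- function(vol, threshold = 0.25, absolute = FALSE,
                             subjectId = "") {
  stopifnot(is(vol, "TimeSeriesVolume"))
  if (threshold <= -1 || threshold >= 1)
    stop("threshold must lie strictly inside (-1, 1)")
  X <- t(asVoxelMatrix(vol))                 # T x V
  sds <- apply(X, 2, sd)
  ok <- sds > 0
  if (sum(ok) < 2L) stop("need >= 2 voxels with nonzero variance")
  Z <- scale(X[, ok, drop = FALSE])          # centred, unit sd
  R <- crossprod(Z) / (nrow(X) - 1)
  hit <- if (absolute) abs(R) > threshold else R > threshold
  deg <- colSums(hit) - (if (absolute) 1L else as.integer(1 > threshold))
  vals <- numeric(ncol(X)); vals[ok] <- deg
  out <- array(vals, dim = dim(vol@data)[1:3])
  map <- new("FeatureMap", values = out, featureName = "DC",
             subjectId = subjectId)
  attr(map@values, "flaggedVoxels") <- which(!ok)
  map
}

#' Regional homogeneity (Kendall's coefficient of concordance)
#'
#' For every voxel, Kendall's W across the K time series of the voxel and
#' its spatial neighbours:
#' W = (sum_t R_t^2 - T Rbar^2) / ((1/12) K^2 (T^3 - T)),
#' where R_t is the rank sum over the K series at time t. Ranks are
#' midranks (ties averaged) with no tie-correction term. Boundary voxels
#' use the truncated neighbourhood actually inside the grid. W lies in
#' [0, 1]: 1 for perfectly synchronised rankings. Input should be
#' band-passed and UNsmoothed.
#'
#' @param vol a \linkS4class{TimeSeriesVolume} with >= 4 time points.
#' @param neighbourhood 7, 19 or 27 voxels (including the centre).
#' @param subjectId subject id stored in the map.
#' @return A \linkS4class{FeatureMap} with values in [0, 1].
#' @export
regionalHomogeneity <- function(vol, neighbourhood = 27, subjectId = "") {
  stopifnot(is(vol, "TimeSeriesVolume"))
  d <- dim(vol@data)
  if (d[4] < 4L) stop("regionalHomogeneity requires >= 4 time points")
  off <- neighbourhoodOffsets(neighbourhood)
  T <- d[4]
  # per-voxel midranks over time
  X <- asVoxelMatrix(vol)
  Rk <- t(apply(X, 1, rank))                 # V x T
  rks <- array(Rk, dim = c(d[1:3], T))
  sumR <- array(0, dim = c(d[1:3], T))
  K <- array(0, dim = d[1:3])
  for (o in seq_len(nrow(off))) {
    ox <- off[o, 1]; oy <- off[o, 2]; oz <- off[o, 3]
    xs <- seq_len(d[1]) + ox; ys <- seq_len(d[2]) + oy; zs <- seq_len(d[3]) + oz
    vx <- xs >= 1 & xs <= d[1]; vy <- ys >= 1 & ys <= d[2]; vz <- zs >= 1 & zs <= d[3]
    sumR[vx, vy, vz, ] <- sumR[vx, vy, vz, , drop = FALSE] +
      rks[xs[vx], ys[vy], zs[vz], , drop = FALSE]
    K[vx, vy, vz] <- K[vx, vy, vz] + 1
  }
  M <- matrix(sumR, nrow = prod(d[1:3]), ncol = T)
  S2 <- rowSums(M^2)
  Sbar <- rowSums(M) / T
  W <- array((S2 - T * Sbar^2), dim = d[1:3]) /
    ((1 / 12) * K^2 * (T^3 - T))
  W[W < 0] <- 0; W[W > 1] <- 1               # guard rounding at the ends
  new("FeatureMap", values = W, featureName = "ReHo", subjectId = subjectId)
}

#' One-sided DFT amplitude spectrum
#'
#' |X[h]| for h = 0..floor(T/2); bin h maps to frequency h * fs / T. The
#' names of the returned vector are the bin frequencies in Hz.
#'
#' @param series numeric vector, length >= 8.
#' @param fs sampling frequency in Hz.
#' @return Named numeric vector of amplitudes.
#' @export
amplitudeSpectrum <- function(series, fs) {
  T <- length(series)
  if (T < 8L) stop("series must have length >= 8")
  h <- 0:(T %/% 2)
  a <- Mod(fft(series))[h + 1]
  setNames(a, format(h * fs / T, trim = TRUE))
}

# shared bin bookkeeping for the spectral maps: one-sided amplitude matrix
# (V x H) plus the in-band bin mask
spectralAmplitudes <- function(vol) {
  T <- dim(vol@data)[4]
  X <- asVoxelMatrix(vol)
  F <- t(mvfft(t(X)))
  h <- 0:(T %/% 2)
  list(amp = Mod(F[, h + 1, drop = FALSE]),
       freq = h * (1 / vol@trSeconds) / T)
}

bandBins <- function(freq, lowHz, highHz) {
  keep <- freq >= lowHz & freq <= highHz
  if (!any(keep))
    stop(sprintf(
      "band [%g, %g] Hz contains no DFT bin; bin spacing is %g Hz (bins at %s...)",
      lowHz, highHz, freq[2] - freq[1],
      paste(signif(freq[1:min(4, length(freq))], 3), collapse = ", ")))
  keep
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Per voxel, the sum of one-sided spectral amplitudes |X[h]| over bins
#' whose frequency lies in the closed band [bandLowHz, bandHighHz]
#' (default 0.01-0.08 Hz). \code{powerMode = TRUE} sums |X[h]|^2 instead.
#' Input should be detrended but NOT band-pass filtered.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param bandLowHz,bandHighHz band edges in Hz.
#' @param powerMode sum squared amplitudes instead of amplitudes.
#' @param subjectId subject id stored in the map.
#' @return A \linkS4class{FeatureMap} of non-negative values.
#' @export
alffMap <- function(vol, bandLowHz = 0.01, bandHighHz = 0.08,
                    powerMode = FALSE, subjectId = "") {
  stopifnot(is(vol, "TimeSeriesVolume"))
  sp <- spectralAmplitudes(vol)
  keep <- bandBins(sp$freq, bandLowHz, bandHighHz)
  a <- if (powerMode) sp$amp^2 else sp$amp
  vals <- rowSums(a[, keep, drop = FALSE])
  new("FeatureMap", values = array(vals, dim = dim(vol@data)[1:3]),
      featureName = "ALFF", subjectId = subjectId)
}

#' Fractional ALFF
#'
#' Per voxel, the in-band amplitude sum divided by the amplitude sum over
#' all bins (the DC bin h = 0 is excluded by default from both numerator
#' context and denominator). Values lie in [0, 1]. Voxels with zero total
#' amplitude (constant series) are set to 0 and flagged in the
#' \code{"flaggedVoxels"} attribute.
#'
#' @inheritParams alffMap
#' @param excludeDcBin drop bin 0 from the denominator (default TRUE).
#' @return A \linkS4class{FeatureMap} with values in [0, 1].
#' @export
falffMap <- function(vol, bandLowHz = 0.01, bandHighHz = 0.08,
                     excludeDcBin = TRUE, powerMode = FALSE, subjectId = "") {
  stopifnot(is(vol, "TimeSeriesVolume"))
  sp <- spectralAmplitudes(vol)
  keep <- bandBins(sp$freq, bandLowHz, bandHighHz)
  a <- if (powerMode) sp$amp^2 else sp$amp
  denomBins <- if (excludeDcBin) sp$freq > 0 else rep(TRUE, length(sp$freq))
  num <- rowSums(a[, keep & denomBins, drop = FALSE])
  den <- rowSums(a[, denomBins, drop = FALSE])
  flagged <- which(den == 0)
  vals <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  vals[vals > 1] <- 1
  map <- new("FeatureMap", values = array(vals, dim = dim(vol@data)[1:3]),
             featureName = "fALFF", subjectId = subjectId)
  if (length(flagged) > 0) {
    warning(sprintf("%d constant voxel(s) have undefined fALFF, set to 0",
                    length(flagged)))
    attr(map@values, "flaggedVoxels") <- flagged
  }
  map
}
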