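#' Region-averaged time series
#'
#' For each atlas region (sorted region id), the arithmetic mean over the
#' region's voxels at every time point. Background voxels (label 0) are
#' excluded.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param atlas an \linkS4class{AtlasParcellation} on the same grid.
#' @return A \linkS4class{RegionTimeSeries} (N x T).
#' @export
regionMeans <- function(vol, atlas) {
  stopifnot(is(vol, "TimeSeriesVolume"), is(atlas, "AtlasParcellation"))
  if (!identical(dim(vol@data)[1:3], dim(atlas@labels)))
    stop(sprintf("volume grid %s does not match atlas grid %s",
                 paste(dim(vol@data)[1:3], collapse = "x"),
                 paste(dim(atlas@labels), collapse = "x")))
  lab <- as.integer(atlas@labels)
  X <- asVoxelMatrix(vol)
  sel <- lab > 0L
  sums <- rowsum(X[sel, , drop = FALSE], group = lab[sel], reorder = TRUE)
  counts <- as.vector(table(factor(lab[sel], levels = atlas@regionIds)))
  new("RegionTimeSeries", series = sums / counts, regionIds = atlas@regionIds)
}

#' Sample Pearson correlation between two series
#'
#' The textbook product-moment coefficient
#' r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2)).
#' Zero-variance input is an error, never a silent 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("series must have length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for zero-variance series")
  r <- cor(x, y)
  max(-1, min(1, r))
}

#' Pearson functional-connectivity matrix
#'
#' N x N matrix of pairwise Pearson correlations between the region series,
#' symmetrised exactly with unit diagonal. A constant region series is an
#' error naming the region: its correlations are undefined.
#'
#' @param rts a \linkS4class{RegionTimeSeries}.
#' @return An \linkS4class{FCMatrix}.
#' @export
fcMatrix <- function(rts) {
  stopifnot(is(rts, "RegionTimeSeries"))
  s <- rts@series
  sds <- apply(s, 1, sd)
  if (any(sds == 0))
    stop(sprintf("region %d has a constant time series; correlation undefined",
                 rts@regionIds[which(sds == 0)[1]]))
  r <- cor(t(s))
  r <- (r + t(r)) / 2            # enforce exact symmetry
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- NULL
  new("FCMatrix", r = r, regionIds = rts@regionIds)
}

#' Lower-triangle feature vector of an FC matrix
#'
#' The strictly-lower-triangle entries in row-major order (i > j): (2,1),
#' (3,1), (3,2), (4,1), ... Length N(N-1)/2. Together with symmetry and the
#' unit diagonal this is a lossless encoding of the matrix
#' (\code{\link{fcFromFeatures}} inverts it).
#'
#' @param m an \linkS4class{FCMatrix}.
#' @return Numeric vector of length N(N-1)/2.
#' @export
fcFeatures <- function(m) {
  stopifnot(is(m, "FCMatrix"))
  tm <- t(m@r)
  tm[upper.tri(tm)]    # column-major upper triangle of t(m) = row-major lower of m
}

#' Rebuild an FC matrix from its lower-triangle feature vector
#'
#' @param v feature vector as produced by \code{\link{fcFeatures}}.
#' @param regionIds region ids of the original matrix.
#' @return An \linkS4class{FCMatrix}.
#' @export
fcFromFeatures <- function(v, regionIds) {
  n <- length(regionIds)
  if (length(v) != n * (n - 1) / 2)
    stop("feature vector length does not match N(N-1)/2")
  tm <- diag(n)
  tm[upper.tri(tm)] <- v
  r <- t(tm)
  r[upper.tri(r)] <- tm[upper.tri(tm)]
  new("FCMatrix", r = r, regionIds = as.integer(regionIds))
}
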