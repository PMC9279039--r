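#' Voxelwise two-sample t statistic
#'
#' Per voxel, the two-sample t statistic (group A minus group B) on any
#' per-subject scalar maps, with the pooled-variance formula by default or
#' Welch's unequal-variance variant. Voxels with zero variance in both
#' groups are set to NA and flagged.
#'
#' @param mapsA,mapsB lists of \linkS4class{FeatureMap}s (or 3D arrays) on
#'   one grid; >= 2 subjects per group.
#' @param welch use Welch's t instead of pooled-variance t.
#' @return List with \code{t} (3D array, NA at degenerate voxels),
#'   \code{df} (scalar for pooled, 3D array for Welch) and
#'   \code{flagged} (indices of degenerate voxels).
#' @export
voxelwiseTTest <- function(mapsA, mapsB, welch = FALSE) {
  toArr <- function(m) if (is(m, "FeatureMap")) m@values else m
  A <- lapply(mapsA, toArr); B <- lapply(mapsB, toArr)
  nA <- length(A); nB <- length(B)
  if (nA < 2L || nB < 2L) stop("need >= 2 subjects per group")
  d <- dim(A[[1]])
  for (m in c(A, B))
    if (!identical(dim(m), d)) stop("all maps must share one grid")
  MA <- vapply(A, as.vector, numeric(prod(d)))
  MB <- vapply(B, as.vector, numeric(prod(d)))
  mA <- rowMeans(MA); mB <- rowMeans(MB)
  vA <- rowSums((MA - mA)^2) / (nA - 1)
  vB <- rowSums((MB - mB)^2) / (nB - 1)
  if (welch) {
    se2 <- vA / nA + vB / nB
    tv <- (mA - mB) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    flagged <- which(se2 == 0)
    tv[flagged] <- NA_real_; df[flagged] <- NA_real_
    list(t = array(tv, d), df = array(df, d), flagged = flagged)
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    tv <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
    flagged <- which(sp2 == 0)
    tv[flagged] <- NA_real_
    list(t = array(tv, d), df = nA + nB - 2, flagged = flagged)
  }
}

#' Map t statistics to standard-normal Z scores
#'
#' Two-sided tail probability of |t| mapped to the standard-normal
#' quantile, signed by t: Z = sign(t) * qnorm(P(T <= |t|)). Computed on the
#' log scale so large |t| do not saturate. Monotone in t with Z(0) = 0.
#'
#' @param t numeric vector/array of t statistics.
#' @param df degrees of freedom (scalar or same shape as t).
#' @return Z scores with the shape of \code{t}.
#' @export
tToZ <- function(t, df) {
  lp <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z <- sign(t) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z[!is.na(t) & t == 0] <- 0
  z
}

# 6/18/26-connected neighbour offsets (excluding the centre)
connectivityOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  man <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6"  = g[man == 1, , drop = FALSE],
         "18" = g[man <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# label connected components of a logical 3D mask by BFS flood fill
labelComponents <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- connectivityOffsets(connectivity)
  lab <- array(0L, d)
  nxt <- 0L
  idxAll <- which(mask)
  for (start in idxAll) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer()
      coords <- arrayInd(cur, d)
      for (o in seq_len(nrow(off))) {
        nb <- coords + matrix(off[o, ], nrow(coords), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] +
          nb[ok, 1]
        hit <- lin[mask[lin] & lab[lin] == 0L]
        if (length(hit) > 0) {
          lab[hit] <- nxt
          queue <- c(queue, hit)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Extract suprathreshold clusters from a t map
#'
#' Thresholds the map at |t| > tThreshold, splits the suprathreshold set by
#' sign, labels connected components under the requested connectivity,
#' drops components smaller than \code{minExtent}, and reports each
#' surviving cluster's voxel count, peak T (at the max-|t| voxel), peak Z
#' (via \code{\link{tToZ}}), peak coordinates (1-based voxel indices) and
#' sign. Clusters are ordered by decreasing voxel count.
#'
#' @param tmap 3D t array (NA allowed; treated as subthreshold) or the
#'   list returned by \code{\link{voxelwiseTTest}}.
#' @param df degrees of freedom (ignored if \code{tmap} carries its own).
#' @param tThreshold positive t threshold.
#' @param minExtent minimum cluster size in voxels.
#' @param connectivity 6, 18 or 26.
#' @return data.frame with columns cluster_id, voxel_count, peak_T, peak_Z,
#'   peak_x, peak_y, peak_z, sign ("increase"/"decrease"), p (two-sided
#'   peak p value). Zero rows if nothing survives.
#' @export
extractClusters <- function(tmap, df = NULL, tThreshold = 3.0,
                            minExtent = 10L, connectivity = 26) {
  if (is.list(tmap) && !is.null(tmap$t)) {
    if (is.null(df)) df <- tmap$df
    tmap <- tmap$t
  }
  if (is.null(df)) stop("df is required")
  if (!is.finite(tThreshold) || tThreshold <= 0)
    stop("tThreshold must be a finite positive number")
  d <- dim(tmap)
  records <- list()
  for (sgn in c(1, -1)) {
    mask <- !is.na(tmap) & (sgn * tmap > tThreshold)
    if (!any(mask)) next
    lab <- labelComponents(mask, connectivity)
    for (cl in seq_len(max(lab))) {
      vox <- which(lab == cl)
      if (length(vox) < minExtent) next
      peak <- vox[which.max(abs(tmap[vox]))]
      peakT <- tmap[peak]
      peakDf <- if (length(df) > 1) df[peak] else df
      co <- arrayInd(peak, d)
      records[[length(records) + 1]] <- data.frame(
        voxel_count = length(vox), peak_T = peakT,
        peak_Z = tToZ(peakT, peakDf),
        peak_x = co[1], peak_y = co[2], peak_z = co[3],
        sign = if (sgn > 0) "increase" else "decrease",
        p = 2 * pt(abs(peakT), peakDf, lower.tail = FALSE),
        voxels = I(list(vox)))
    }
  }
  if (length(records) == 0)
    return(data.frame(cluster_id = integer(), voxel_count = integer(),
                      peak_T = numeric(), peak_Z = numeric(),
                      peak_x = integer(), peak_y = integer(),
                      peak_z = integer(), sign = character(), p = numeric()))
  out <- do.call(rbind, records)
  out <- out[order(-out$voxel_count, -abs(out$peak_T)), , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Voxelwise FDR-adjusted p values
#'
#' Two-sided p values of the t map adjusted by Benjamini-Hochberg, for the
#' corrected reporting path (the default cluster table is uncorrected).
#'
#' @param tt list returned by \code{\link{voxelwiseTTest}}.
#' @return 3D array of FDR-adjusted p values (NA at degenerate voxels).
#' @export
voxelwiseFdr <- function(tt) {
  p <- 2 * pt(abs(tt$t), tt$df, lower.tail = FALSE)
  array(stats::p.adjust(as.vector(p), method = "BH"), dim(tt$t))
}

#' Cluster table for two groups of maps
#'
#' Convenience wrapper: voxelwise t test, cluster extraction, optional CSV
#' in the conventional report layout (cluster id, voxel count, Z, T, p).
#'
#' @param mapsA,mapsB per-subject maps (patient group first, so "increase"
#'   means A > B).
#' @param tThreshold,minExtent,connectivity see
#'   \code{\link{extractClusters}}.
#' @param welch use Welch's t.
#' @param voxelSizeMm optional voxel edge lengths in mm (length 1 or 3);
#'   when given, a volume_mm3 column is added.
#' @param csvPath optional output CSV path.
#' @return The cluster data.frame (without the voxel-index list column in
#'   the CSV).
#' @export
clusterTable <- function(mapsA, mapsB, tThreshold = 3.0, minExtent = 10L,
                         connectivity = 26, welch = FALSE,
                         voxelSizeMm = NULL, csvPath = NULL) {
  tt <- voxelwiseTTest(mapsA, mapsB, welch = welch)
  tab <- extractClusters(tt, tThreshold = tThreshold, minExtent = minExtent,
                         connectivity = connectivity)
  if (!is.null(voxelSizeMm) && nrow(tab) > 0)
    tab$volume_mm3 <- tab$voxel_count * prod(rep(voxelSizeMm, length.out = 3))
  if (!is.null(csvPath)) {
    keep <- intersect(c("cluster_id", "voxel_count", "volume_mm3", "peak_Z",
                        "peak_T", "p", "sign", "peak_x", "peak_y", "peak_z"),
                      names(tab))
    write.csv(tab[, keep, drop = FALSE], csvPath, row.names = FALSE,
              quote = FALSE)
  }
  tab
}
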