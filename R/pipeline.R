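#' Extract the voxelwise feature maps for one subject
#'
#' Runs the fixed preprocessing wiring (\code{\link{preprocessFor}}) and
#' computes the requested maps: "ALFF" and "fALFF" from detrended
#' unfiltered series, "DC" and "ReHo" from detrended band-passed series
#' (ReHo additionally unsmoothed).
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param features character subset of c("ALFF", "fALFF", "DC", "ReHo").
#' @param bandLowHz,bandHighHz spectral band / filter band in Hz.
#' @param dcThreshold degree-centrality correlation threshold.
#' @param rehoNeighbourhood 7, 19 or 27.
#' @param detrend "linear" or "none".
#' @param smoothFwhmVoxels optional Gaussian FWHM (never applied to ReHo).
#' @param subjectId subject id stamped on the maps.
#' @return Named list of \linkS4class{FeatureMap} objects.
#' @export
extractFeatureMaps <- function(vol, features = c("ALFF", "fALFF", "DC", "ReHo"),
                               bandLowHz = 0.01, bandHighHz = 0.08,
                               dcThreshold = 0.25, rehoNeighbourhood = 27,
                               detrend = "linear", smoothFwhmVoxels = 0,
                               subjectId = "") {
  features <- match.arg(features, c("ALFF", "fALFF", "DC", "ReHo"),
                        several.ok = TRUE)
  out <- list()
  if (any(features %in% c("ALFF", "fALFF"))) {
    spectralVol <- preprocessFor(vol, "ALFF", detrend = detrend,
                                 smoothFwhmVoxels = smoothFwhmVoxels)
    if ("ALFF" %in% features)
      out$ALFF <- alffMap(spectralVol, bandLowHz, bandHighHz,
                          subjectId = subjectId)
    if ("fALFF" %in% features)
      out$fALFF <- falffMap(spectralVol, bandLowHz, bandHighHz,
                            subjectId = subjectId)
  }
  if (any(features %in% c("DC", "ReHo"))) {
    bpVol <- preprocessFor(vol, "DC", detrend = detrend,
                           bandLowHz = bandLowHz, bandHighHz = bandHighHz)
    if ("DC" %in% features)
      out$DC <- degreeCentrality(bpVol, threshold = dcThreshold,
                                 subjectId = subjectId)
    if ("ReHo" %in% features)
      out$ReHo <- regionalHomogeneity(bpVol,
                                      neighbourhood = rehoNeighbourhood,
                                      subjectId = subjectId)
  }
  out[features]
}

#' Extract feature maps and summaries for a whole cohort
#'
#' For each manifest subject: reads the volume, computes the requested
#' maps, writes each as \code{\{subject_id\}_\{feature\}.nii.gz} under
#' \code{outDir}, and appends region-mean summaries (plus, optionally, the
#' lower-triangle FC features) to a per-subject feature table written as
#' \code{features.csv}.
#'
#' @param manifest a \linkS4class{CohortManifest}.
#' @param atlas an \linkS4class{AtlasParcellation}.
#' @param outDir output directory for maps and the feature table.
#' @param features voxelwise features to compute.
#' @param includeFc also compute the FC matrix and append its
#'   lower-triangle features (and write each matrix as
#'   \code{\{subject_id\}_fc.csv}).
#' @param ... passed to \code{\link{extractFeatureMaps}}.
#' @return Invisibly, the feature table data.frame.
#' @export
extractCohortFeatures <- function(manifest, atlas, outDir,
                                  features = c("ALFF", "fALFF", "DC", "ReHo"),
                                  includeFc = FALSE, ...) {
  stopifnot(is(manifest, "CohortManifest"), is(atlas, "AtlasParcellation"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ids <- subjectIds(manifest)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    vol <- readVolume(volumePaths(manifest)[i])
    maps <- extractFeatureMaps(vol, features, subjectId = ids[i], ...)
    row <- list(subject_id = ids[i], label = cohortLabels(manifest)[i])
    for (f in names(maps)) {
      writeFeatureMap(maps[[f]], file.path(outDir,
                                           sprintf("%s_%s.nii.gz", ids[i], f)))
      rm <- regionMeansOfMap(maps[[f]], atlas)
      names(rm) <- sprintf("%s_region%d", f, regionIds(atlas))
      row <- c(row, as.list(rm))
    }
    if (includeFc) {
      fc <- fcMatrix(regionMeans(preprocessFor(vol, "FC"), atlas))
      writeFcMatrix(fc, file.path(outDir, sprintf("%s_fc.csv", ids[i])))
      v <- fcFeatures(fc)
      names(v) <- sprintf("fc_%d", seq_along(v))
      row <- c(row, as.list(v))
    }
    rows[[i]] <- as.data.frame(row, check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(outDir, "features.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(tab)
}

#' Region means of a scalar feature map
#' @param map a \linkS4class{FeatureMap}.
#' @param atlas an \linkS4class{AtlasParcellation} on the same grid.
#' @return Named numeric vector, one mean per region.
#' @export
regionMeansOfMap <- function(map, atlas) {
  stopifnot(is(map, "FeatureMap"), is(atlas, "AtlasParcellation"))
  if (!identical(dim(map@values), dim(atlas@labels)))
    stop("feature map grid does not match atlas grid")
  lab <- as.integer(atlas@labels)
  v <- as.vector(map@values)
  sel <- lab > 0L
  m <- tapply(v[sel], factor(lab[sel], levels = atlas@regionIds), mean)
  setNames(as.numeric(m), atlas@regionIds)
}

#' Write an FC matrix as CSV with a region-id header
#' @param fc an \linkS4class{FCMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFcMatrix <- function(fc, path) {
  stopifnot(is(fc, "FCMatrix"))
  m <- fc@r
  colnames(m) <- sprintf("region%d", fc@regionIds)
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build one subject's network input from feature maps
#'
#' Reduces each 3D map to its mid-grid slice(s) and stacks them as
#' channels: the default is the axial mid-slice (z = floor(Z/2) + 1); with
#' \code{slices = c("axial", "coronal", "sagittal")} the three orthogonal
#' mid-slices of each map are stacked (grids must then be cubic). Each
#' channel is z-scored within subject (mean 0, sd 1; constant channels
#' become all-zero) so no feature's physical scale dominates.
#'
#' @param maps list of \linkS4class{FeatureMap} objects (channel order).
#' @param slices subset of c("axial", "coronal", "sagittal").
#' @param zscore z-score each channel (default TRUE).
#' @return Numeric array (H, W, nChannels).
#' @export
buildSubjectInput <- function(maps, slices = "axial", zscore = TRUE) {
  slices <- match.arg(slices, c("axial", "coronal", "sagittal"),
                      several.ok = TRUE)
  chans <- list()
  for (map in maps) {
    v <- featureValues(map)
    d <- dim(v)
    for (s in slices) {
      sl <- switch(s,
                   axial = v[, , d[3] %/% 2 + 1],
                   coronal = v[, d[2] %/% 2 + 1, ],
                   sagittal = v[d[1] %/% 2 + 1, , ])
      sl <- matrix(sl, nrow = dim(v)[if (s == "sagittal") 2 else 1])
      if (zscore) {
        s2 <- sd(sl)
        sl <- if (s2 > 0) (sl - mean(sl)) / s2 else sl * 0
      }
      chans[[length(chans) + 1]] <- sl
    }
  }
  dims <- vapply(chans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share one 2D shape; use a cubic grid for multi-view input")
  array(unlist(chans), dim = c(dim(chans[[1]]), length(chans)))
}

#' Load per-subject maps and train a capsule model
#'
#' Expects maps written by \code{\link{extractCohortFeatures}} under
#' \code{mapsDir} as \code{\{subject_id\}_\{feature\}.nii.gz}. The manifest
#' must contain both classes. A missing map file is an error naming the
#' subject.
#'
#' @param manifest a \linkS4class{CohortManifest}.
#' @param features feature names consumed as channels, in order.
#' @param mapsDir directory holding the map files.
#' @param cfg a \linkS4class{CapsNetConfig}, or NULL for
#'   \code{\link{defaultCapsConfig}} matched to the map shape.
#' @param slices passed to \code{\link{buildSubjectInput}}.
#' @param seed seed used when cfg is NULL.
#' @param ... passed to \code{\link{defaultCapsConfig}} when cfg is NULL.
#' @return A \linkS4class{CapsNetModel}.
#' @export
trainFromManifest <- function(manifest, features, mapsDir, cfg = NULL,
                              slices = "axial", seed = 1L, ...) {
  stopifnot(is(manifest, "CohortManifest"))
  labs <- cohortLabels(manifest)
  if (length(unique(labs)) < 2L)
    stop("manifest must contain both classes for training")
  xs <- loadSubjectInputs(manifest, features, mapsDir, slices)
  if (is.null(cfg))
    cfg <- defaultCapsConfig(dim(xs[[1]]), seed = seed, ...)
  trainCapsNet(xs, labs, cfg, featureNames = features)
}

loadSubjectInputs <- function(manifest, features, mapsDir, slices = "axial",
                              zscore = TRUE) {
  lapply(seq_along(subjectIds(manifest)), function(i) {
    sid <- subjectIds(manifest)[i]
    maps <- lapply(features, function(f) {
      p <- file.path(mapsDir, sprintf("%s_%s.nii.gz", sid, f))
      if (!file.exists(p))
        stop(sprintf("missing %s feature map for subject '%s' (%s)", f, sid, p))
      readFeatureMap(p, f, sid)
    })
    buildSubjectInput(maps, slices = slices, zscore = zscore)
  })
}
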