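#' Read a 4D NIfTI time-series volume
#'
#' Loads a 4D NIfTI file into a \linkS4class{TimeSeriesVolume}. The
#' repetition time is taken from the 4th pixdim entry of the header unless
#' \code{trSeconds} overrides it. Volumes with fewer than 4 dimensions, a
#' non-positive header TR without override, or any non-finite voxel are
#' rejected.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param trSeconds optional TR override in seconds.
#' @return A \linkS4class{TimeSeriesVolume}.
#' @examples
#' \dontrun{vol <- readVolume("sub01.nii.gz")}
#' @export
readVolume <- function(path, trSeconds = NULL) {
  if (!file.exists(path)) stop(sprintf("volume file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected 4D volume, got %dD in '%s'", length(dim(arr)), path))
  if (is.null(trSeconds)) {
    pd <- RNifti::pixdim(img)
    trSeconds <- if (length(pd) >= 4) pd[4] else NA_real_
    if (!is.finite(trSeconds) || trSeconds <= 0)
      stop(sprintf("no valid TR in header of '%s'; pass trSeconds", path))
  }
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop(sprintf("volume '%s' has %d non-finite voxel values", path, nbad))
  new("TimeSeriesVolume", data = arr, trSeconds = as.numeric(trSeconds))
}

#' Write a time-series volume to NIfTI
#'
#' The TR is stored in the header's 4th pixdim so \code{\link{readVolume}}
#' round-trips it.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "TimeSeriesVolume"))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- c(1, 1, 1, vol@trSeconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an atlas parcellation
#'
#' Loads a 3D integer-labelled NIfTI and checks it against a reference
#' volume: the spatial grids must be identical, labels must be non-negative
#' integers, and at least two regions (distinct positive labels) must be
#' present. Voxel (x, y, z) of the atlas corresponds to voxel (x, y, z, .)
#' of the volume; axes are never reordered.
#'
#' @param path path to a 3D label NIfTI.
#' @param reference a \linkS4class{TimeSeriesVolume} sharing the grid, or
#'   NULL to skip the shape check.
#' @return An \linkS4class{AtlasParcellation}.
#' @export
readAtlas <- function(path, reference = NULL) {
  if (!file.exists(path)) stop(sprintf("atlas file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected 3D atlas, got %dD in '%s'", length(dim(arr)), path))
  if (!is.null(reference)) {
    ref <- dim(volData(reference))[1:3]
    if (!identical(as.integer(dim(arr)), as.integer(ref)))
      stop(sprintf("atlas grid %s does not match volume grid %s",
                   paste(dim(arr), collapse = "x"),
                   paste(ref, collapse = "x")))
  }
  if (any(arr < 0)) stop("atlas contains negative labels")
  if (any(arr != round(arr))) stop("atlas labels must be integers")
  storage.mode(arr) <- "integer"
  ids <- sort(unique(as.integer(arr[arr > 0L])))
  if (length(ids) < 2L)
    stop(sprintf("atlas must define >= 2 regions, found %d", length(ids)))
  new("AtlasParcellation", labels = arr, regionIds = ids)
}

#' Write an atlas parcellation to NIfTI
#' @param atlas an \linkS4class{AtlasParcellation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "AtlasParcellation"))
  RNifti::writeNifti(RNifti::asNifti(atlas@labels, datatype = "int32"), path)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' The file must have the exact header \code{subject_id,volume_path,label}.
#' Labels are coerced to integer and must be 0 (control) or 1 (patient);
#' subject ids must be unique. Violations report the offending CSV line.
#'
#' @param path CSV path.
#' @return A \linkS4class{CohortManifest}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), c("subject_id", "volume_path", "label")))
    stop("manifest header must be exactly 'subject_id,volume_path,label'")
  lab <- suppressWarnings(as.integer(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad) > 0L)
    stop(sprintf("invalid label '%s' at manifest line %d (labels must be 0 or 1)",
                 df$label[bad[1]], bad[1] + 1L))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate subject id '%s' in manifest", dup[1]))
  new("CohortManifest", subjectId = df$subject_id,
      volumePath = df$volume_path, label = lab)
}

#' Write a cohort manifest CSV
#' @param manifest a \linkS4class{CohortManifest}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "CohortManifest"))
  df <- data.frame(subject_id = manifest@subjectId,
                   volume_path = manifest@volumePath,
                   label = manifest@label)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature map to NIfTI
#' @param map a \linkS4class{FeatureMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMap <- function(map, path) {
  stopifnot(is(map, "FeatureMap"))
  RNifti::writeNifti(RNifti::asNifti(map@values), path)
  invisible(path)
}

#' Read a feature map from NIfTI
#' @param path path to a 3D NIfTI.
#' @param featureName feature name for the returned object.
#' @param subjectId subject id for the returned object.
#' @return A \linkS4class{FeatureMap}.
#' @export
readFeatureMap <- function(path, featureName, subjectId = "") {
  if (!file.exists(path)) stop(sprintf("feature map not found: '%s'", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  new("FeatureMap", values = arr, featureName = featureName,
      subjectId = subjectId)
}
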