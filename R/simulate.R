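#' Simulation configuration constructor
#'
#' Builds a validated \linkS4class{SimulationConfig}. Defaults emulate the
#' study scale this package targets: a 70-patient / 30-control two-class
#' cohort in atlas space, with class differences carried by three signal
#' channels that the downstream features detect — in-band (0.01–0.08 Hz)
#' oscillation amplitude (ALFF/fALFF), inter-region coupling (FC/DC) and
#' within-region synchrony (ReHo/DC).
#'
#' Each subject's voxel series is white Gaussian noise plus a per-region
#' low-frequency oscillation (a sum of \code{nOscillations} sinusoids with
#' frequencies drawn uniformly in [0.01, 0.08] Hz and random phases). For
#' patients only: amplitude in \code{affectedRegions} is multiplied by
#' \code{1 + effectAlff}; affected regions share a common oscillation mixed
#' in with weight \code{effectFc}; and a fraction \code{effectReho} of each
#' affected voxel's noise is replaced by a region-shared component. All
#' random draws are made in a fixed order regardless of label, so a control
#' and a patient with the same subject seed differ only through the effects.
#'
#' @param gridShape,nRegions,nTimepoints,trSeconds,nPatients,nControls,effectAlff,effectFc,effectReho,affectedRegions,noiseSd,oscAmplitude,nOscillations,seed
#'   see \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(gridShape = c(12L, 12L, 12L), nRegions = 8L,
                             nTimepoints = 128L, trSeconds = 2.0,
                             nPatients = 70L, nControls = 30L,
                             effectAlff = 0, effectFc = 0, effectReho = 0,
                             affectedRegions = c(5L, 6L), noiseSd = 1.0,
                             oscAmplitude = 0.5, nOscillations = 3L,
                             seed = 1L) {
  new("SimulationConfig", gridShape = as.integer(gridShape),
      nRegions = as.integer(nRegions), nTimepoints = as.integer(nTimepoints),
      trSeconds = as.numeric(trSeconds), nPatients = as.integer(nPatients),
      nControls = as.integer(nControls), effectAlff = as.numeric(effectAlff),
      effectFc = as.numeric(effectFc), effectReho = as.numeric(effectReho),
      affectedRegions = as.integer(affectedRegions),
      noiseSd = as.numeric(noiseSd), oscAmplitude = as.numeric(oscAmplitude),
      nOscillations = as.integer(nOscillations), seed = as.integer(seed))
}

# near-cubic factorisation nx*ny*nz = n with nx<=dx etc.; prefers balanced blocks
blockFactorisation <- function(n, gridShape) {
  best <- NULL; bestScore <- Inf
  for (nx in 1:n) {
    if (n %% nx != 0L || nx > gridShape[1]) next
    m <- n %/% nx
    for (ny in 1:m) {
      if (m %% ny != 0L || ny > gridShape[2]) next
      nz <- m %/% ny
      if (nz > gridShape[3]) next
      score <- stats::var(c(nx, ny, nz))
      if (score < bestScore) { bestScore <- score; best <- c(nx, ny, nz) }
    }
  }
  if (is.null(best))
    stop(sprintf("cannot partition grid %s into %d contiguous blocks",
                 paste(gridShape, collapse = "x"), n))
  best
}

#' Build a contiguous block-region atlas
#'
#' Partitions the grid into \code{nRegions} contiguous rectangular blocks,
#' a geometric stand-in for an anatomical parcellation. Each axis is cut
#' into near-equal intervals; labels run 1..nRegions with x varying fastest
#' (for 8 regions on an even cube this gives the eight octants). The
#' partition is deterministic; \code{seed} is accepted for interface
#' symmetry with the other generators.
#'
#' @param gridShape integer length-3 grid dimensions.
#' @param nRegions number of regions (2 <= nRegions <= voxel count).
#' @param seed unused; kept so all generator calls take a seed.
#' @return An \linkS4class{AtlasParcellation}.
#' @export
makeBlockAtlas <- function(gridShape = c(12L, 12L, 12L), nRegions = 8L,
                           seed = 1L) {
  gridShape <- as.integer(gridShape); nRegions <- as.integer(nRegions)
  if (nRegions > prod(gridShape))
    stop(sprintf("nRegions (%d) exceeds voxel count (%d)", nRegions,
                 prod(gridShape)))
  if (nRegions < 2L) stop("nRegions must be >= 2")
  f <- blockFactorisation(nRegions, gridShape)
  cut1 <- function(len, k) {
    # floor of an arithmetic grid with spacing >= 1 is strictly increasing,
    # so every block is non-empty
    cuts <- floor(seq(0, len, length.out = k + 1)); cuts[k + 1] <- len
    rep(seq_len(k), times = diff(cuts))
  }
  bx <- cut1(gridShape[1], f[1]); by <- cut1(gridShape[2], f[2])
  bz <- cut1(gridShape[3], f[3])
  lab <- array(0L, gridShape)
  lab[] <- as.integer(outer(outer(bx - 1L, (by - 1L) * f[1], "+"),
                            (bz - 1L) * f[1] * f[2], "+") + 1L)
  new("AtlasParcellation", labels = lab,
      regionIds = seq_len(nRegions))
}

# one region's oscillation: sum of sinusoids, freqs ~ U(0.01, 0.08) Hz
drawOscillation <- function(tGrid, nOsc, amplitude) {
  f <- runif(nOsc, 0.01, 0.08)
  ph <- runif(nOsc, 0, 2 * pi)
  colSums(amplitude * sin(outer(2 * pi * f, tGrid) + ph))
}

#' Simulate one subject's 4D volume
#'
#' Deterministic given (config, atlas, label, subjectSeed). See
#' \code{\link{simulationConfig}} for the signal model. Background voxels
#' (atlas label 0) receive noise only.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param atlas an \linkS4class{AtlasParcellation} on \code{config@gridShape}.
#' @param label 0 (control) or 1 (patient).
#' @param subjectSeed integer RNG seed for this subject.
#' @return A \linkS4class{TimeSeriesVolume}.
#' @export
simulateSubject <- function(config, atlas, label, subjectSeed) {
  stopifnot(is(config, "SimulationConfig"), is(atlas, "AtlasParcellation"),
            label %in% c(0L, 1L))
  validObject(config)
  set.seed(as.integer(subjectSeed))
  T <- config@nTimepoints
  tGrid <- (seq_len(T) - 1) * config@trSeconds
  ids <- regionIds(atlas)
  nReg <- length(ids)
  aff <- config@affectedRegions

  # fixed draw order, independent of label and effect sizes
  osc <- t(vapply(seq_len(nReg), function(i)
    drawOscillation(tGrid, config@nOscillations, config@oscAmplitude),
    numeric(T)))
  shared <- drawOscillation(tGrid, config@nOscillations, config@oscAmplitude)
  affIdx <- match(aff, ids)
  etaShared <- matrix(rnorm(T * length(aff), sd = config@noiseSd), nrow = T)
  labArr <- as.integer(atlasLabels(atlas))
  nVox <- length(labArr)
  eps <- matrix(rnorm(nVox * T, sd = config@noiseSd), nrow = nVox)

  if (label == 1L) {
    w <- config@effectFc
    if (w != 0)
      osc[affIdx, ] <- (1 - abs(w)) * osc[affIdx, , drop = FALSE] +
        w * matrix(shared, nrow = length(affIdx), ncol = T, byrow = TRUE)
    if (config@effectAlff > 0)
      osc[affIdx, ] <- (1 + config@effectAlff) * osc[affIdx, , drop = FALSE]
    rho <- config@effectReho
    if (rho > 0) {
      for (k in seq_along(affIdx)) {
        vsel <- which(labArr == aff[k])
        eps[vsel, ] <- (1 - rho) * eps[vsel, , drop = FALSE] +
          rho * matrix(etaShared[, k], nrow = length(vsel), ncol = T,
                       byrow = TRUE)
      }
    }
  }

  signal <- matrix(0, nrow = nVox, ncol = T)
  inReg <- labArr > 0L
  signal[inReg, ] <- osc[match(labArr[inReg], ids), , drop = FALSE]
  arr <- array(eps + signal, dim = c(config@gridShape, T))
  new("TimeSeriesVolume", data = arr, trSeconds = config@trSeconds)
}

subjectSeedFor <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 100003 * index) %% 2147483629)
}

#' Simulate and write a full two-class cohort
#'
#' Writes \code{nPatients + nControls} NIfTI volumes, the atlas, a manifest
#' CSV (header \code{subject_id,volume_path,label}) and a ground-truth JSON
#' recording each subject's label, seed and injected effects. Regeneration
#' with the same configuration is byte-identical.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir writable output directory (created if missing).
#' @return A \linkS4class{SimulatedCohort}.
#' @export
simulateCohort <- function(config, outDir) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop(sprintf("cannot create directory '%s'", outDir))
  atlas <- makeBlockAtlas(config@gridShape, config@nRegions, config@seed)
  writeAtlas(atlas, file.path(outDir, "atlas.nii.gz"))
  n <- config@nPatients + config@nControls
  labels <- c(rep(1L, config@nPatients), rep(0L, config@nControls))
  ids <- sprintf("sub%03d", seq_len(n))
  paths <- file.path(outDir, paste0(ids, ".nii.gz"))
  gt <- vector("list", n); names(gt) <- ids
  for (i in seq_len(n)) {
    sseed <- subjectSeedFor(config@seed, i)
    vol <- simulateSubject(config, atlas, labels[i], sseed)
    writeVolume(vol, paths[i])
    gt[[i]] <- list(subject_id = ids[i], label = labels[i],
                    subject_seed = sseed,
                    affected_regions = config@affectedRegions,
                    effect_alff = if (labels[i] == 1L) config@effectAlff else 0,
                    effect_fc = if (labels[i] == 1L) config@effectFc else 0,
                    effect_reho = if (labels[i] == 1L) config@effectReho else 0)
  }
  manifest <- new("CohortManifest", subjectId = ids, volumePath = paths,
                  label = labels)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  jsonlite::write_json(gt, file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  new("SimulatedCohort", manifest = manifest, atlas = atlas,
      groundTruth = gt, dir = outDir)
}
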