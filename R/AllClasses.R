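#' @import methods
#' @importFrom stats cor fft mvfft pt qnorm rnorm runif sd setNames rbinom
#' @importFrom utils read.csv write.csv
NULL

#' Four-dimensional resting-state time-series volume
#'
#' Container for one subject's 4D scan: a real array indexed (x, y, z, t)
#' plus the sampling interval. The time axis is always the last axis and all
#' indexing in this package is 1-based. The sampling frequency is
#' \code{1 / trSeconds} Hz and fixes the DFT bin grid used by the spectral
#' features.
#'
#' Volumes containing any non-finite value are rejected at construction:
#' the variance-normalised correlations and concordance statistics computed
#' downstream are undefined for missing data, so the package fails fast
#' rather than masking.
#'
#' @slot data 4D numeric array (x, y, z, t); all values finite, t >= 8.
#' @slot trSeconds positive scalar, repetition time in seconds.
#' @export
setClass("TimeSeriesVolume",
  representation(data = "array", trSeconds = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array (x, y, z, t)")
    if (any(d[1:3] < 1L)) return("all spatial dimensions must be >= 1")
    if (d[4] < 8L) return("time dimension must have >= 8 points")
    if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
        object@trSeconds <= 0) return("trSeconds must be a positive scalar")
    nbad <- sum(!is.finite(object@data))
    if (nbad > 0L) return(sprintf("volume contains %d non-finite voxel values", nbad))
    TRUE
  })

#' Integer-labelled atlas parcellation
#'
#' A 3D integer label volume assigning each voxel to one of N brain regions.
#' Label 0 is background and is excluded from every region statistic; the
#' distinct positive labels are the region ids and N is their count (e.g. 116
#' or 246 for the anatomical atlases commonly used in resting-state work).
#'
#' @slot labels 3D integer array of non-negative labels.
#' @slot regionIds sorted integer vector of distinct positive labels.
#' @export
setClass("AtlasParcellation",
  representation(labels = "array", regionIds = "integer"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (any(!is.finite(object@labels)) || any(object@labels < 0) ||
        any(object@labels != round(object@labels)))
      return("labels must be non-negative integers")
    ids <- sort(unique(as.integer(object@labels[object@labels > 0])))
    if (!identical(ids, object@regionIds))
      return("regionIds must equal the sorted distinct positive labels")
    TRUE
  })

#' Cohort manifest
#'
#' Maps subject ids to on-disk volumes and class labels (0 = control,
#' 1 = patient). Subject ids must be unique.
#'
#' @slot subjectId character vector of unique subject ids.
#' @slot volumePath character vector of NIfTI paths, parallel to subjectId.
#' @slot label integer vector in \{0, 1\}, parallel to subjectId.
#' @export
setClass("CohortManifest",
  representation(subjectId = "character", volumePath = "character",
                 label = "integer"),
  validity = function(object) {
    n <- length(object@subjectId)
    if (length(object@volumePath) != n || length(object@label) != n)
      return("subjectId, volumePath and label must have equal length")
    if (anyDuplicated(object@subjectId)) {
      dup <- object@subjectId[duplicated(object@subjectId)][1]
      return(sprintf("duplicate subject id '%s'", dup))
    }
    if (!all(object@label %in% c(0L, 1L)))
      return("labels must be 0 (control) or 1 (patient)")
    TRUE
  })

#' Region-averaged time series
#'
#' One row per atlas region (sorted by region id), one column per time point;
#' row i holds the arithmetic mean over the region's voxels at each time.
#'
#' @slot series N x T numeric matrix.
#' @slot regionIds integer vector of region ids in row order.
#' @export
setClass("RegionTimeSeries",
  representation(series = "matrix", regionIds = "integer"),
  validity = function(object) {
    if (nrow(object@series) != length(object@regionIds))
      return("one series row per region id required")
    if (is.unsorted(object@regionIds, strictly = TRUE))
      return("regionIds must be strictly increasing")
    TRUE
  })

#' Functional-connectivity matrix
#'
#' Symmetric N x N matrix of Pearson correlations between region-averaged
#' time series, with unit diagonal and entries in [-1, 1].
#'
#' @slot r N x N numeric matrix.
#' @slot regionIds integer vector of region ids in row/column order.
#' @export
setClass("FCMatrix",
  representation(r = "matrix", regionIds = "integer"),
  validity = function(object) {
    m <- object@r
    if (nrow(m) != ncol(m)) return("r must be square")
    if (nrow(m) != length(object@regionIds))
      return("regionIds length must match matrix order")
    if (!identical(m, t(m))) return("r must be exactly symmetric")
    if (any(abs(m) > 1 + 1e-12)) return("entries must lie in [-1, 1]")
    if (any(abs(diag(m) - 1) > 1e-12)) return("diagonal must be 1")
    TRUE
  })

#' Per-voxel scalar feature map
#'
#' One subject's 3D map of a voxelwise feature: DC (degree centrality, a
#' non-negative integer count), ReHo (Kendall concordance, in [0, 1]), ALFF
#' (summed low-frequency spectral amplitude, >= 0) or fALFF (fractional
#' ALFF, in [0, 1]).
#'
#' @slot values 3D numeric array.
#' @slot featureName one of "DC", "ReHo", "ALFF", "fALFF".
#' @slot subjectId subject identifier (may be empty).
#' @export
setClass("FeatureMap",
  representation(values = "array", featureName = "character",
                 subjectId = "character"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (!object@featureName %in% c("DC", "ReHo", "ALFF", "fALFF"))
      return("featureName must be one of DC, ReHo, ALFF, fALFF")
    if (any(!is.finite(object@values)))
      return("feature map contains non-finite values")
    TRUE
  })

#' Capsule-network configuration
#'
#' Architecture and training hyper-parameters for the capsule classifier:
#' a ReLU convolutional stem, a convolutional primary-capsule layer whose
#' activations are grouped into short vectors and squashed, and one class
#' capsule per class whose output length in [0, 1) scores class presence.
#' Coupling between primary and class capsules is set by dynamic routing.
#' The margin loss uses margins \code{mPlus} = 0.9 (true class) and
#' \code{mMinus} = 0.1 (other classes) with down-weight \code{lambda}.
#'
#' @slot inputShape integer c(H, W, C): slice height, width, channels.
#' @slot conv1Channels,conv1Kernel,conv1Stride stem convolution geometry.
#' @slot primaryKernel,primaryStride,primaryCapsChannels,primaryDim
#'   primary-capsule convolution geometry; the conv layer emits
#'   \code{primaryCapsChannels * primaryDim} channels read as
#'   \code{primaryDim}-vectors.
#' @slot nClasses,classDim number and dimension of class capsules.
#' @slot routingIters dynamic-routing iterations (>= 1).
#' @slot mPlus,mMinus,lambda margin-loss constants, 0 < mMinus < mPlus < 1.
#' @slot epochs,batchSize,learningRate,seed training schedule; Adam optimiser.
#' @slot zscore z-score each input channel within subject before the network.
#' @export
setClass("CapsNetConfig",
  representation(inputShape = "integer",
                 conv1Channels = "integer", conv1Kernel = "integer",
                 conv1Stride = "integer",
                 primaryKernel = "integer", primaryStride = "integer",
                 primaryCapsChannels = "integer", primaryDim = "integer",
                 nClasses = "integer", classDim = "integer",
                 routingIters = "integer",
                 mPlus = "numeric", mMinus = "numeric", lambda = "numeric",
                 epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer",
                 zscore = "logical"),
  validity = function(object) {
    if (object@nClasses < 2L) return("nClasses must be >= 2")
    if (object@routingIters < 1L) return("routingIters must be >= 1")
    if (!(object@mMinus > 0 && object@mMinus < object@mPlus && object@mPlus < 1))
      return("need 0 < mMinus < mPlus < 1")
    g <- capsGeometry(object)
    if (!is.null(g$error)) return(g$error)
    TRUE
  })

#' Trained capsule-network model
#'
#' Learned tensors plus the configuration and per-epoch training history.
#'
#' @slot params named list of weight/bias arrays.
#' @slot config the \linkS4class{CapsNetConfig} used.
#' @slot history data.frame with columns epoch, loss, trainAcc.
#' @slot featureNames feature maps the model consumes, in channel order.
#' @export
setClass("CapsNetModel",
  representation(params = "list", config = "CapsNetConfig",
                 history = "data.frame", featureNames = "character"),
  validity = function(object) {
    if (nrow(object@history) > 0 && any(!is.finite(object@history$loss)))
      return("training loss history contains non-finite values")
    TRUE
  })

#' Classification evaluation report
#'
#' Confusion counts and the three summary metrics used for two-class
#' depression classification: correct rate (TP+TN)/n, recall TP/(TP+FN) and
#' precision TP/(TP+FP), with class 1 ("patient") as the positive class.
#' Ratios with zero denominator are NA, never silently 0.
#'
#' @slot tp,fp,fn,tn confusion counts.
#' @slot correctRate,recall,precision metrics in [0, 1] (or NA).
#' @slot predictions data.frame of per-subject predictions.
#' @export
setClass("EvalReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer", correctRate = "numeric", recall = "numeric",
                 precision = "numeric", predictions = "data.frame"),
  validity = function(object) {
    n <- object@tp + object@fp + object@fn + object@tn
    if (nrow(object@predictions) > 0 && n != nrow(object@predictions))
      return("confusion counts must sum to the number of subjects")
    TRUE
  })

#' Synthetic-cohort simulation configuration
#'
#' Parameters of the two-class generator. Classes can differ in three
#' independent channels: in-band oscillation amplitude in affected regions
#' (\code{effectAlff}), coupling between affected regions (\code{effectFc}),
#' and within-region voxel synchrony (\code{effectReho}); each effect is
#' applied to patients (label 1) only. Defaults emulate a 70-patient /
#' 30-control cohort on a 12x12x12 grid of 8 block regions, 128 time points
#' at TR = 2 s.
#'
#' @slot gridShape integer length-3 grid dimensions.
#' @slot nRegions number of block regions (>= 2).
#' @slot nTimepoints time points (>= 16); @slot trSeconds repetition time.
#' @slot nPatients,nControls group sizes.
#' @slot effectAlff amplitude multiplier increment (>= 0) in affected regions.
#' @slot effectFc shared-oscillation mixing weight in [-1, 1].
#' @slot effectReho region-shared noise fraction in [0, 1].
#' @slot affectedRegions integer region ids carrying the effects.
#' @slot noiseSd white-noise standard deviation (> 0).
#' @slot oscAmplitude per-sinusoid base amplitude; @slot nOscillations
#'   sinusoids per region.
#' @slot seed master RNG seed.
#' @export
setClass("SimulationConfig",
  representation(gridShape = "integer", nRegions = "integer",
                 nTimepoints = "integer", trSeconds = "numeric",
                 nPatients = "integer", nControls = "integer",
                 effectAlff = "numeric", effectFc = "numeric",
                 effectReho = "numeric", affectedRegions = "integer",
                 noiseSd = "numeric", oscAmplitude = "numeric",
                 nOscillations = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      return("gridShape must be 3 positive integers")
    if (object@nRegions < 2L) return("nRegions must be >= 2")
    if (object@nRegions > prod(object@gridShape))
      return("nRegions cannot exceed the voxel count")
    if (object@nTimepoints < 16L) return("nTimepoints must be >= 16")
    if (object@trSeconds <= 0) return("trSeconds must be positive")
    if (object@effectAlff < 0 || !is.finite(object@effectAlff))
      return("effectAlff must be finite and >= 0")
    if (abs(object@effectFc) > 1) return("effectFc must lie in [-1, 1]")
    if (object@effectReho < 0 || object@effectReho > 1)
      return("effectReho must lie in [0, 1]")
    if (length(object@affectedRegions) < 1L)
      return("at least one affected region is required")
    if (any(object@affectedRegions < 1L) ||
        any(object@affectedRegions > object@nRegions))
      return("affectedRegions must be valid region ids")
    if (object@noiseSd <= 0) return("noiseSd must be positive")
    TRUE
  })

#' Simulated cohort handle
#'
#' What \code{\link{simulateCohort}} wrote: the manifest, the atlas, the
#' per-subject ground-truth effect record, and the output directory.
#'
#' @slot manifest \linkS4class{CohortManifest}.
#' @slot atlas \linkS4class{AtlasParcellation}.
#' @slot groundTruth named list, one record per subject.
#' @slot dir output directory.
#' @export
setClass("SimulatedCohort",
  representation(manifest = "CohortManifest", atlas = "AtlasParcellation",
                 groundTruth = "list", dir = "character"))
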