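#' @name accessors
#' @title Accessor generics
#' @description Slot accessors for the package's data classes; user code
#'   should use these rather than reaching into slots with \code{@}.
#' @param x an object.
#' @return The slot contents (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("samplingFrequency", function(x) standardGeneric("samplingFrequency"))
#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))
#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("regionSeries", function(x) standardGeneric("regionSeries"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("volumePaths", function(x) standardGeneric("volumePaths"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

setMethod("volData", "TimeSeriesVolume", function(x) x@data)
setMethod("trSeconds", "TimeSeriesVolume", function(x) x@trSeconds)
setMethod("samplingFrequency", "TimeSeriesVolume", function(x) 1 / x@trSeconds)
setMethod("atlasLabels", "AtlasParcellation", function(x) x@labels)
setMethod("regionIds", "AtlasParcellation", function(x) x@regionIds)
setMethod("nRegions", "AtlasParcellation", function(x) length(x@regionIds))
setMethod("regionIds", "RegionTimeSeries", function(x) x@regionIds)
setMethod("regionSeries", "RegionTimeSeries", function(x) x@series)
setMethod("regionIds", "FCMatrix", function(x) x@regionIds)
setMethod("nRegions", "FCMatrix", function(x) length(x@regionIds))
setMethod("fcValues", "FCMatrix", function(x) x@r)
setMethod("featureValues", "FeatureMap", function(x) x@values)
setMethod("featureName", "FeatureMap", function(x) x@featureName)
setMethod("subjectIds", "CohortManifest", function(x) x@subjectId)
setMethod("volumePaths", "CohortManifest", function(x) x@volumePath)
setMethod("cohortLabels", "CohortManifest", function(x) x@label)
setMethod("trainingHistory", "CapsNetModel", function(x) x@history)
setMethod("confusionCounts", "EvalReport", function(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))
setMethod("metrics", "EvalReport", function(x)
  c(correct_rate = x@correctRate, recall = x@recall, precision = x@precision))

#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
setMethod("predictions", "EvalReport", function(x) x@predictions)

setMethod("show", "TimeSeriesVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("TimeSeriesVolume %dx%dx%d, %d time points, TR = %g s (fs = %g Hz)\n",
              d[1], d[2], d[3], d[4], object@trSeconds, 1 / object@trSeconds))
})
setMethod("show", "AtlasParcellation", function(object) {
  d <- dim(object@labels)
  cat(sprintf("AtlasParcellation %dx%dx%d, N = %d regions (label 0 = background)\n",
              d[1], d[2], d[3], length(object@regionIds)))
})
setMethod("show", "CohortManifest", function(object) {
  cat(sprintf("CohortManifest: %d subjects (%d patients, %d controls)\n",
              length(object@subjectId), sum(object@label == 1L),
              sum(object@label == 0L)))
})
setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix: %d x %d Pearson correlations, %d lower-triangle features\n",
              nrow(object@r), ncol(object@r),
              nrow(object@r) * (nrow(object@r) - 1) / 2))
})
setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureMap '%s' %dx%dx%d%s, range [%.4g, %.4g]\n",
              object@featureName, d[1], d[2], d[3],
              if (nzchar(object@subjectId))
                sprintf(" (subject %s)", object@subjectId) else "",
              min(object@values), max(object@values)))
})
setMethod("show", "CapsNetModel", function(object) {
  cfg <- object@config
  cat(sprintf("CapsNetModel: input %s, %d classes, %d routing iterations\n",
              paste(cfg@inputShape, collapse = "x"), cfg@nClasses,
              cfg@routingIters))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d epochs, final loss %.4g, train acc %.3f\n",
                max(object@history$epoch), utils::tail(object@history$loss, 1),
                utils::tail(object@history$trainAcc, 1)))
})
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: TP=%d FP=%d FN=%d TN=%d | correct rate %.4f, recall %s, precision %s\n",
              object@tp, object@fp, object@fn, object@tn, object@correctRate,
              format(object@recall, digits = 4),
              format(object@precision, digits = 4)))
})
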