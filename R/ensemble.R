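#' Weighted-average ensemble fusion
#'
#' Fuses the class-score matrices of several member models: each member's
#' per-subject score vector is first normalised to sum to 1 (capsule
#' lengths do not), then the fused vector is the weight-averaged sum and
#' the prediction is its argmax, ties broken toward the lower class index
#' (so an exactly split vote yields class 0). An all-zero member score
#' vector is treated as uninformative (uniform).
#'
#' @param scoreList list of n x K numeric score matrices, one per member.
#' @param weights non-negative member weights; default uniform. They are
#'   renormalised to sum to 1.
#' @return data.frame with fused score columns \code{score_0..} and
#'   \code{predicted}.
#' @export
ensemblePredict <- function(scoreList, weights = NULL) {
  stopifnot(is.list(scoreList), length(scoreList) >= 1L)
  mats <- lapply(scoreList, as.matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all member score matrices must have identical dimensions")
  if (is.null(weights)) weights <- rep(1, length(mats))
  if (length(weights) != length(mats))
    stop("need one weight per member")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  weights <- weights / sum(weights)
  K <- ncol(mats[[1]])
  fused <- matrix(0, nrow(mats[[1]]), K)
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    rs <- rowSums(m)
    norm <- m / ifelse(rs > 0, rs, 1)
    norm[rs == 0, ] <- 1 / K
    fused <- fused + weights[k] * norm
  }
  out <- as.data.frame(fused)
  names(out) <- paste0("score_", seq_len(K) - 1L)
  out$predicted <- apply(fused, 1, which.max) - 1L
  out
}

#' Evaluate two-class predictions
#'
#' Confusion counts with class 1 (patient) positive, and the three metrics
#' this package reports: correct rate (TP+TN)/n, recall TP/(TP+FN) and
#' precision TP/(TP+FP). A zero-denominator ratio is NA with a warning,
#' never silently 0.
#'
#' @param predicted integer vector of predicted labels in \{0, 1\}.
#' @param labels integer vector of true labels in \{0, 1\}.
#' @param subjectIds optional ids stored with the per-subject predictions.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateClassification <- function(predicted, labels, subjectIds = NULL) {
  if (length(predicted) != length(labels))
    stop("predicted and labels must have equal length")
  if (!all(labels %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stop("labels and predictions must be 0 or 1")
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  n <- tp + fp + fn + tn
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what))
      return(NA_real_)
    }
    num / den
  }
  if (is.null(subjectIds)) subjectIds <- sprintf("s%03d", seq_len(n))
  new("EvalReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      correctRate = ratio(tp + tn, n, "correct rate"),
      recall = ratio(tp, tp + fn, "recall"),
      precision = ratio(tp, tp + fp, "precision"),
      predictions = data.frame(subject_id = subjectIds, label = labels,
                               predicted = predicted))
}

#' Stratified train/test split
#'
#' Samples \code{testFraction} of each class (rounded) into the test set,
#' preserving class proportions within one subject.
#'
#' @param labels integer class labels.
#' @param testFraction held-out fraction in (0, 1).
#' @param seed RNG seed for the split.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, testFraction = 0.2, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1)
  set.seed(as.integer(seed))
  test <- integer()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    nTest <- max(1L, round(length(idx) * testFraction))
    test <- c(test, sort(sample(idx, nTest)))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Train per-feature capsule models and evaluate them plus their ensemble
#'
#' The single-split experiment protocol of this package: one stratified
#' held-out split, one capsule model per feature (each consuming that
#' feature's map as its only channel), member evaluation on the common
#' held-out set, and weighted-average fusion of the members evaluated on
#' the same set. All seeds derive from \code{seed} so the experiment is
#' reproducible end to end.
#'
#' @param manifest a \linkS4class{CohortManifest} containing both classes.
#' @param features feature names, e.g. c("fALFF", "DC", "ALFF").
#' @param mapsDir directory of per-subject maps
#'   (\code{\{subject_id\}_\{feature\}.nii.gz}).
#' @param cfg a \linkS4class{CapsNetConfig} template applied to every
#'   member (its seed is offset per member), or NULL for
#'   \code{\link{defaultCapsConfig}}.
#' @param testFraction held-out fraction (default 0.2).
#' @param seed master seed for split and training.
#' @param weights ensemble weights (default uniform).
#' @param slices passed to \code{\link{buildSubjectInput}}.
#' @return List with per-feature \linkS4class{EvalReport}s
#'   (\code{$members}), the ensemble report (\code{$ensemble}), the fitted
#'   models (\code{$models}) and the split indices (\code{$split}).
#' @export
runExperiment <- function(manifest, features, mapsDir, cfg = NULL,
                          testFraction = 0.2, seed = 1L, weights = NULL,
                          slices = "axial") {
  stopifnot(is(manifest, "CohortManifest"), length(features) >= 1L)
  labs <- cohortLabels(manifest)
  if (length(unique(labs)) < 2L)
    stop("manifest must contain both classes")
  split <- stratifiedSplit(labs, testFraction, seed)
  ids <- subjectIds(manifest)
  models <- list(); memberReports <- list(); testScores <- list()
  for (k in seq_along(features)) {
    f <- features[k]
    xs <- loadSubjectInputs(manifest, f, mapsDir, slices)
    cfgK <- if (is.null(cfg))
      defaultCapsConfig(dim(xs[[1]]), seed = as.integer(seed + k))
    else {
      ck <- cfg; ck@seed <- as.integer(cfg@seed + k)
      ck@inputShape <- as.integer(dim(xs[[1]])); validObject(ck); ck
    }
    models[[f]] <- trainCapsNet(xs[split$train], labs[split$train], cfgK,
                                featureNames = f)
    pr <- predictCapsNet(models[[f]], xs[split$test])
    testScores[[f]] <- as.matrix(pr[, seq_len(cfgK@nClasses)])
    memberReports[[f]] <- evaluateClassification(pr$predicted,
                                                 labs[split$test],
                                                 ids[split$test])
  }
  fused <- ensemblePredict(testScores, weights)
  ensembleReport <- evaluateClassification(fused$predicted, labs[split$test],
                                           ids[split$test])
  list(members = memberReports, ensemble = ensembleReport, models = models,
       split = split)
}

#' Write an experiment report to JSON and CSV
#'
#' JSON carries the metric summary per member and for the ensemble; the
#' CSV holds per-subject held-out predictions of the ensemble.
#'
#' @param result list returned by \code{\link{runExperiment}}.
#' @param jsonPath,csvPath output paths (NULL to skip either).
#' @return Invisibly, the summary list written to JSON.
#' @export
writeExperimentReport <- function(result, jsonPath = NULL, csvPath = NULL) {
  summ <- list(
    members = lapply(result$members, function(r)
      c(as.list(confusionCounts(r)), as.list(metrics(r)))),
    ensemble = c(as.list(confusionCounts(result$ensemble)),
                 as.list(metrics(result$ensemble))))
  if (!is.null(jsonPath))
    jsonlite::write_json(summ, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(csvPath))
    write.csv(predictions(result$ensemble), csvPath, row.names = FALSE,
              quote = FALSE)
  invisible(summ)
}
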