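# ---- geometry -------------------------------------------------------------

# layer size bookkeeping; returns $error string instead of stopping so the
# class validity method can report it
capsGeometry <- function(cfg) {
  H <- cfg@inputShape[1]; W <- cfg@inputShape[2]; C <- cfg@inputShape[3]
  convOut <- function(n, k, s) {
    if (k > n) return(NA_integer_)
    if ((n - k) %% s != 0L) return(NA_integer_)
    (n - k) %/% s + 1L
  }
  o1H <- convOut(H, cfg@conv1Kernel, cfg@conv1Stride)
  o1W <- convOut(W, cfg@conv1Kernel, cfg@conv1Stride)
  if (is.na(o1H) || is.na(o1W) || o1H < 1L || o1W < 1L)
    return(list(error = sprintf(
      "conv1 kernel %d / stride %d does not tile a %dx%d input",
      cfg@conv1Kernel, cfg@conv1Stride, H, W)))
  o2H <- convOut(o1H, cfg@primaryKernel, cfg@primaryStride)
  o2W <- convOut(o1W, cfg@primaryKernel, cfg@primaryStride)
  if (is.na(o2H) || is.na(o2W) || o2H < 1L || o2W < 1L)
    return(list(error = sprintf(
      "primary-capsule kernel %d / stride %d does not tile the %dx%d conv1 output",
      cfg@primaryKernel, cfg@primaryStride, o1H, o1W)))
  list(o1H = o1H, o1W = o1W, o2H = o2H, o2W = o2W,
       L1 = o1H * o1W, L2 = o2H * o2W,
       nIn = o2H * o2W * cfg@primaryCapsChannels,
       M = cfg@primaryCapsChannels * cfg@primaryDim, error = NULL)
}

# flat patch-index matrix for im2col: rows ordered (dx, dy, channel),
# columns ordered (out-x fastest, then out-y)
makeIm2colIndex <- function(H, W, C, k, s) {
  oH <- (H - k) %/% s + 1L; oW <- (W - k) %/% s + 1L
  patch <- as.matrix(expand.grid(dx = 0:(k - 1), dy = 0:(k - 1),
                                 c = 0:(C - 1)))
  pOff <- patch[, 1] + patch[, 2] * H + patch[, 3] * H * W
  tl <- as.matrix(expand.grid(i = seq(1, by = s, length.out = oH),
                              j = seq(1, by = s, length.out = oW)))
  tOff <- (tl[, 1] - 1) + (tl[, 2] - 1) * H
  matrix(outer(pOff, tOff, "+") + 1L, nrow = length(pOff))
}

#' Capsule-network configuration constructor
#'
#' The literal architecture defaults follow the classic capsule design: a
#' stride-1 ReLU convolution producing 256 channels, a stride-2 primary
#' capsule convolution read as 32 channels of 8-dimensional capsules, and
#' 16-dimensional class capsules coupled by 3 rounds of dynamic routing.
#' Margin-loss margins are mPlus = 0.9 and mMinus = 0.1 with lambda = 0.5.
#' Kernel sizes and channel counts are free parameters; the configuration
#' is rejected if the kernels do not tile the requested input, in which
#' case pick a smaller stem (see \code{\link{defaultCapsConfig}} for one
#' matched to small synthetic slices).
#'
#' @param inputShape integer c(H, W, C).
#' @param conv1Channels,conv1Kernel,conv1Stride,primaryKernel,primaryStride,primaryCapsChannels,primaryDim,nClasses,classDim,routingIters,mPlus,mMinus,lambda,epochs,batchSize,learningRate,seed,zscore
#'   see \linkS4class{CapsNetConfig}.
#' @return A \linkS4class{CapsNetConfig}.
#' @export
capsNetConfig <- function(inputShape,
                          conv1Channels = 256L, conv1Kernel = 9L,
                          conv1Stride = 1L,
                          primaryKernel = 9L, primaryStride = 2L,
                          primaryCapsChannels = 32L, primaryDim = 8L,
                          nClasses = 2L, classDim = 16L, routingIters = 3L,
                          mPlus = 0.9, mMinus = 0.1, lambda = 0.5,
                          epochs = 50L, batchSize = 16L,
                          learningRate = 1e-3, seed = 1L, zscore = TRUE) {
  new("CapsNetConfig", inputShape = as.integer(inputShape),
      conv1Channels = as.integer(conv1Channels),
      conv1Kernel = as.integer(conv1Kernel),
      conv1Stride = as.integer(conv1Stride),
      primaryKernel = as.integer(primaryKernel),
      primaryStride = as.integer(primaryStride),
      primaryCapsChannels = as.integer(primaryCapsChannels),
      primaryDim = as.integer(primaryDim), nClasses = as.integer(nClasses),
      classDim = as.integer(classDim), routingIters = as.integer(routingIters),
      mPlus = mPlus, mMinus = mMinus, lambda = lambda,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate, seed = as.integer(seed), zscore = zscore)
}

#' Desk-scale capsule configuration for small feature slices
#'
#' Picks a stem that tiles small inputs (e.g. 12x12 synthetic atlas slices):
#' a 32-channel conv1 and 4 primary-capsule channels of dimension 8, with
#' kernel sizes chosen automatically so the strides fit.
#'
#' @param inputShape integer c(H, W, C).
#' @param epochs,batchSize,learningRate,seed training schedule.
#' @param ... further arguments passed to \code{\link{capsNetConfig}}.
#' @return A \linkS4class{CapsNetConfig}.
#' @export
defaultCapsConfig <- function(inputShape, epochs = 30L, batchSize = 16L,
                              learningRate = 2e-3, seed = 1L, ...) {
  H <- inputShape[1]; W <- inputShape[2]
  n <- min(H, W)
  k1 <- max(2L, min(5L, n - 3L))
  o1 <- n - k1 + 1L
  k2 <- NA_integer_
  for (k in c(4L, 3L, 2L, 5L)) {
    if (k <= o1 && (o1 - k) %% 2L == 0L && (o1 - k) %/% 2L + 1L >= 2L) {
      k2 <- k; break
    }
  }
  if (is.na(k2)) { k2 <- o1; s2 <- 1L } else s2 <- 2L
  capsNetConfig(inputShape, conv1Channels = 32L, conv1Kernel = k1,
                conv1Stride = 1L, primaryKernel = k2, primaryStride = s2,
                primaryCapsChannels = 4L, primaryDim = 8L,
                epochs = epochs, batchSize = batchSize,
                learningRate = learningRate, seed = seed, ...)
}

# ---- capsule primitives ---------------------------------------------------

#' Squash nonlinearity
#'
#' Rescales a vector to length ||s||^2 / (1 + ||s||^2) without changing its
#' direction, mapping any input into the open unit ball. The zero vector
#' maps to itself.
#'
#' @param s numeric vector.
#' @return Squashed vector of the same length.
#' @export
squash <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s)
  s * sqrt(n2) / (1 + n2)
}

squashCols <- function(S) {
  n2 <- colSums(S^2)
  f <- ifelse(n2 > 0, sqrt(n2) / (1 + n2), 0)
  S * rep(f, each = nrow(S))
}

# d/dS of squashCols, given upstream dV
squashBackCols <- function(S, dV) {
  n2 <- colSums(S^2); n <- sqrt(n2)
  h <- ifelse(n2 > 0, n / (1 + n2), 0)
  hp <- (1 - n2) / (1 + n2)^2
  dot <- colSums(S * dV)
  coef <- ifelse(n > 0, hp * dot / n, 0)
  dV * rep(h, each = nrow(S)) + S * rep(coef, each = nrow(S))
}

#' Dynamic routing by agreement
#'
#' Routing between a layer of input capsules and the class capsules.
#' Logits start at zero; each iteration sets the coupling coefficients to
#' the per-input-capsule softmax of the logits, forms each class capsule as
#' the squashed coupling-weighted vote sum, and increments the logits by
#' the vote/output scalar agreement.
#'
#' @param votes array of vote vectors, dim c(classDim, nInputCapsules,
#'   nClasses): \code{votes[, i, j]} is capsule i's vote for class j.
#' @param iters number of routing iterations (>= 1).
#' @param trace if TRUE, attach the per-iteration coupling matrices as the
#'   \code{"couplingTrace"} attribute of the result.
#' @return List with \code{v} (classDim x nClasses output capsules),
#'   \code{coupling} (nIn x nClasses final coupling coefficients) and
#'   \code{logits}.
#' @export
dynamicRouting <- function(votes, iters = 3L, trace = FALSE) {
  stopifnot(length(dim(votes)) == 3L, iters >= 1L)
  cd <- dim(votes)[1]; nIn <- dim(votes)[2]; K <- dim(votes)[3]
  b <- matrix(0, nIn, K)
  hist <- if (trace) vector("list", iters) else NULL
  cmat <- NULL; V <- NULL
  for (it in seq_len(iters)) {
    e <- exp(b - apply(b, 1, max))
    cmat <- e / rowSums(e)
    if (trace) hist[[it]] <- cmat
    S <- vapply(seq_len(K),
                function(j) (matrix(votes[, , j], nrow = cd) %*% cmat[, j])[, 1],
                numeric(cd))
    S <- matrix(S, nrow = cd)
    V <- squashCols(S)
    if (it < iters) {
      agree <- vapply(seq_len(K),
                      function(j) crossprod(matrix(votes[, , j], nrow = cd),
                                            V[, j])[, 1],
                      numeric(nIn))
      b <- b + matrix(agree, nrow = nIn)
    }
  }
  out <- list(v = V, coupling = cmat, logits = b)
  if (trace) attr(out, "couplingTrace") <- hist
  out
}

#' Margin loss on class-capsule lengths
#'
#' L = sum_p [ T_p max(0, mPlus - a_p)^2
#'           + lambda (1 - T_p) max(0, a_p - mMinus)^2 ],
#' where a_p is class p's capsule length and T_p indicates the true class.
#' Zero exactly when the true score reaches mPlus and every other score is
#' at most mMinus.
#'
#' @param scores numeric vector of capsule lengths in [0, 1].
#' @param trueClass true class label in 0..(length(scores) - 1).
#' @param mPlus,mMinus,lambda margin constants.
#' @return Non-negative scalar loss.
#' @export
marginLoss <- function(scores, trueClass, mPlus = 0.9, mMinus = 0.1,
                       lambda = 0.5) {
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  if (trueClass < 0 || trueClass >= length(scores))
    stop("trueClass out of range")
  Tp <- as.numeric(seq_along(scores) - 1 == trueClass)
  sum(Tp * pmax(0, mPlus - scores)^2 +
        lambda * (1 - Tp) * pmax(0, scores - mMinus)^2)
}

#' Gradient of the margin loss with respect to the scores
#' @inheritParams marginLoss
#' @return Numeric vector dL/dscores.
#' @export
marginLossGrad <- function(scores, trueClass, mPlus = 0.9, mMinus = 0.1,
                           lambda = 0.5) {
  Tp <- as.numeric(seq_along(scores) - 1 == trueClass)
  -2 * Tp * pmax(0, mPlus - scores) +
    2 * lambda * (1 - Tp) * pmax(0, scores - mMinus)
}

# ---- forward / backward ---------------------------------------------------

initCapsParams <- function(cfg, geom) {
  k1 <- cfg@conv1Kernel; C <- cfg@inputShape[3]
  k2 <- cfg@primaryKernel
  p <- list()
  p$W1 <- matrix(rnorm(cfg@conv1Channels * k1 * k1 * C,
                       sd = sqrt(2 / (k1 * k1 * C))),
                 nrow = cfg@conv1Channels)
  p$b1 <- numeric(cfg@conv1Channels)
  p$W2 <- matrix(rnorm(geom$M * k2 * k2 * cfg@conv1Channels,
                       sd = sqrt(2 / (k2 * k2 * cfg@conv1Channels))),
                 nrow = geom$M)
  p$b2 <- numeric(geom$M)
  for (j in seq_len(cfg@nClasses))
    p[[paste0("Wt", j)]] <- matrix(rnorm(geom$nIn * cfg@classDim * cfg@primaryDim,
                                         sd = 0.1),
                                   nrow = geom$nIn * cfg@classDim)
  p
}

capsForward <- function(params, cfg, geom, idx1, idx2, x, keepCache = FALSE) {
  cd <- cfg@classDim; D1 <- cfg@primaryDim; K <- cfg@nClasses
  nIn <- geom$nIn
  xvec <- as.vector(x)
  P1 <- matrix(xvec[idx1], nrow = nrow(idx1))
  A1pre <- params$W1 %*% P1 + params$b1
  A1 <- pmax(A1pre, 0)
  v1 <- as.vector(t(A1))
  P2 <- matrix(v1[idx2], nrow = nrow(idx2))
  A2 <- params$W2 %*% P2 + params$b2
  U <- matrix(A2, nrow = D1)                       # D1 x nIn, pre-squash
  Usq <- squashCols(U)
  Urep <- t(Usq)[rep(seq_len(nIn), each = cd), , drop = FALSE]
  votes <- array(0, dim = c(cd, nIn, K))
  for (j in seq_len(K))
    votes[, , j] <- matrix(rowSums(params[[paste0("Wt", j)]] * Urep),
                           nrow = cd)
  rt <- dynamicRouting(votes, cfg@routingIters)
  scores <- sqrt(colSums(rt$v^2))
  out <- list(scores = scores)
  if (keepCache)
    out$cache <- list(P1 = P1, A1pre = A1pre, P2 = P2, U = U, Usq = Usq,
                      Urep = Urep, votes = votes, coupling = rt$coupling,
                      V = rt$v)
  out
}

capsBackward <- function(params, cfg, geom, idx2, cache, dscores) {
  cd <- cfg@classDim; D1 <- cfg@primaryDim; K <- cfg@nClasses
  nIn <- geom$nIn
  V <- cache$V
  lens <- sqrt(colSums(V^2))
  dV <- V * rep(ifelse(lens > 0, dscores / lens, 0), each = cd)
  # squash backward: V = squash(S) where S is the coupled vote sum; the
  # coupling coefficients are treated as constants of the backward pass
  SB <- vapply(seq_len(K),
               function(j) (matrix(cache$votes[, , j], nrow = cd) %*%
                              cache$coupling[, j])[, 1],
               numeric(cd))
  SB <- matrix(SB, nrow = cd)
  dS <- squashBackCols(SB, dV)
  grads <- list()
  dUsq <- matrix(0, D1, nIn)
  grp <- rep(seq_len(nIn), each = cd)
  for (j in seq_len(K)) {
    dvotes <- outer(dS[, j], cache$coupling[, j])      # cd x nIn
    dvf <- as.vector(dvotes)
    grads[[paste0("Wt", j)]] <- dvf * cache$Urep
    Mj <- params[[paste0("Wt", j)]] * dvf
    dUsq <- dUsq + t(rowsum(Mj, grp, reorder = TRUE))
  }
  dU <- squashBackCols(cache$U, dUsq)
  dA2 <- matrix(dU, nrow = geom$M)
  grads$W2 <- dA2 %*% t(cache$P2)
  grads$b2 <- rowSums(dA2)
  dP2 <- crossprod(params$W2, dA2)
  dv1 <- numeric(geom$L1 * cfg@conv1Channels)
  rs <- rowsum(as.vector(dP2), as.vector(idx2), reorder = TRUE)
  dv1[as.integer(rownames(rs))] <- rs[, 1]
  dA1 <- t(matrix(dv1, nrow = geom$L1))
  dA1pre <- dA1 * (cache$A1pre > 0)
  grads$W1 <- dA1pre %*% t(cache$P1)
  grads$b1 <- rowSums(dA1pre)
  grads
}

# ---- training -------------------------------------------------------------

asInputList <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4L)
    return(lapply(seq_len(dim(x)[1]), function(i) {
      a <- x[i, , , , drop = FALSE]; dim(a) <- dim(x)[2:4]; a
    }))
  stop("x must be a list of (H, W, C) arrays or an (n, H, W, C) array")
}

#' Train a capsule network
#'
#' Mini-batch Adam on the mean margin loss. Deterministic given
#' \code{cfg@seed}: initialisation, shuffling and every update are driven
#' by one seeded RNG stream. Per-epoch mean loss and training accuracy are
#' recorded in the model's history.
#'
#' @param x inputs: list of (H, W, C) arrays or an (n, H, W, C) array.
#'   Channels should already be z-scored (see
#'   \code{\link{buildSubjectInput}}).
#' @param y integer class labels in 0..(nClasses - 1).
#' @param cfg a \linkS4class{CapsNetConfig}; its inputShape must match x.
#' @param featureNames optional channel names stored with the model.
#' @param verbose print per-epoch loss.
#' @return A \linkS4class{CapsNetModel}.
#' @export
trainCapsNet <- function(x, y, cfg, featureNames = character(), verbose = FALSE) {
  xs <- asInputList(x)
  n <- length(xs)
  y <- as.integer(y)
  stopifnot(n == length(y), all(y >= 0L & y < cfg@nClasses))
  if (!identical(as.integer(dim(xs[[1]])), cfg@inputShape))
    stop(sprintf("input shape %s does not match config inputShape %s",
                 paste(dim(xs[[1]]), collapse = "x"),
                 paste(cfg@inputShape, collapse = "x")))
  geom <- capsGeometry(cfg)
  idx1 <- makeIm2colIndex(cfg@inputShape[1], cfg@inputShape[2],
                          cfg@inputShape[3], cfg@conv1Kernel, cfg@conv1Stride)
  idx2 <- makeIm2colIndex(geom$o1H, geom$o1W, cfg@conv1Channels,
                          cfg@primaryKernel, cfg@primaryStride)
  set.seed(cfg@seed)
  params <- initCapsParams(cfg, geom)
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- lapply(params, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; epsA <- 1e-8; step <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(), trainAcc = numeric())
  for (ep in seq_len(cfg@epochs)) {
    ord <- sample.int(n)
    epLoss <- 0; epHit <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / cfg@batchSize))) {
      gAcc <- NULL
      for (i in bs) {
        fw <- capsForward(params, cfg, geom, idx1, idx2, xs[[i]],
                          keepCache = TRUE)
        sc <- pmin(fw$scores, 1)
        epLoss <- epLoss + marginLoss(sc, y[i], cfg@mPlus, cfg@mMinus,
                                      cfg@lambda)
        epHit <- epHit + as.integer(which.max(sc) - 1L == y[i])
        g <- capsBackward(params, cfg, geom, idx2, fw$cache,
                          marginLossGrad(sc, y[i], cfg@mPlus, cfg@mMinus,
                                         cfg@lambda))
        gAcc <- if (is.null(gAcc)) g else mapply(`+`, gAcc, g,
                                                 SIMPLIFY = FALSE)
      }
      gAcc <- lapply(gAcc, function(g) g / length(bs))
      step <- step + 1L
      for (nm in names(params)) {
        mAdam[[nm]] <- b1a * mAdam[[nm]] + (1 - b1a) * gAcc[[nm]]
        vAdam[[nm]] <- b2a * vAdam[[nm]] + (1 - b2a) * gAcc[[nm]]^2
        mh <- mAdam[[nm]] / (1 - b1a^step)
        vh <- vAdam[[nm]] / (1 - b2a^step)
        params[[nm]] <- params[[nm]] - cfg@learningRate * mh / (sqrt(vh) + epsA)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss / n,
                                   trainAcc = epHit / n))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  acc %.3f", ep, epLoss / n,
                      epHit / n))
  }
  new("CapsNetModel", params = params, config = cfg, history = hist,
      featureNames = as.character(featureNames))
}

#' Predict with a trained capsule network
#'
#' Deterministic forward pass. Class scores are the class-capsule lengths
#' in [0, 1); the predicted class is the argmax, ties broken toward the
#' lower class index.
#'
#' @param model a \linkS4class{CapsNetModel}.
#' @param x list of (H, W, C) arrays or an (n, H, W, C) array.
#' @return data.frame with one row per input: score columns
#'   \code{score_0..score_{K-1}} and \code{predicted}.
#' @export
predictCapsNet <- function(model, x) {
  cfg <- model@config
  xs <- asInputList(x)
  for (xi in xs)
    if (!identical(as.integer(dim(xi)), cfg@inputShape))
      stop(sprintf("input shape %s does not match model inputShape %s",
                   paste(dim(xi), collapse = "x"),
                   paste(cfg@inputShape, collapse = "x")))
  geom <- capsGeometry(cfg)
  idx1 <- makeIm2colIndex(cfg@inputShape[1], cfg@inputShape[2],
                          cfg@inputShape[3], cfg@conv1Kernel, cfg@conv1Stride)
  idx2 <- makeIm2colIndex(geom$o1H, geom$o1W, cfg@conv1Channels,
                          cfg@primaryKernel, cfg@primaryStride)
  sc <- t(vapply(xs, function(xi)
    capsForward(model@params, cfg, geom, idx1, idx2, xi)$scores,
    numeric(cfg@nClasses)))
  out <- as.data.frame(sc)
  names(out) <- paste0("score_", seq_len(cfg@nClasses) - 1L)
  out$predicted <- apply(sc, 1, which.max) - 1L
  out
}

#' Serialise / restore a trained model
#'
#' The RDS payload contains the learned tensors, the full configuration
#' (including the seed) and the training history, so a restored model
#' reproduces predictions exactly.
#'
#' @param model a \linkS4class{CapsNetModel}.
#' @param path file path.
#' @return \code{path} invisibly (save); the model (load).
#' @export
saveCapsNetModel <- function(model, path) {
  stopifnot(is(model, "CapsNetModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCapsNetModel
#' @export
loadCapsNetModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "CapsNetModel"))
  m
}
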