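# Independent brute-force oracles. These re-derive every statistic from its
# textbook definition by explicit summation, deliberately avoiding the code
# paths (and the stats:: shortcuts) used by the package implementation.

# two-pass product-moment correlation, explicit sums
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# per-label double loop region means
oracleRegionMeans <- function(volArr, labArr, ids) {
  T <- dim(volArr)[4]
  out <- matrix(0, length(ids), T)
  for (k in seq_along(ids)) {
    vox <- which(labArr == ids[k])
    for (tt in seq_len(T)) {
      sl <- volArr[, , , tt]
      out[k, tt] <- sum(sl[vox]) / length(vox)
    }
  }
  out
}

oracleFcMatrix <- function(series) {
  n <- nrow(series)
  m <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) m[i, j] <- oraclePearson(series[i, ], series[j, ])
  m
}

# all-pairs signed-threshold degree count
oracleDc <- function(volArr, threshold = 0.25) {
  d <- dim(volArr)
  V <- prod(d[1:3])
  X <- matrix(volArr, nrow = V)
  deg <- integer(V)
  for (i in seq_len(V - 1)) for (j in (i + 1):V) {
    r <- oraclePearson(X[i, ], X[j, ])
    if (r > threshold) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
  }
  array(deg, d[1:3])
}

# Kendall's W from rank sums over a K x T matrix of series
oracleKendallW <- function(seriesMat) {
  K <- nrow(seriesMat); T <- ncol(seriesMat)
  R <- apply(seriesMat, 1, rank)            # T x K midranks
  S <- rowSums(R)
  Sbar <- mean(S)
  sum((S - Sbar)^2) / ((1 / 12) * K^2 * (T^3 - T))
}

# per-voxel ReHo by gathering each truncated neighbourhood explicitly
oracleReho <- function(volArr, neighbourhood = 27) {
  d <- dim(volArr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  man <- rowSums(abs(offs))
  offs <- switch(as.character(neighbourhood),
                 "7" = offs[man <= 1, ], "19" = offs[man <= 2, ], "27" = offs)
  out <- array(0, d[1:3])
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    nb <- cbind(x + offs[, 1], y + offs[, 2], z + offs[, 3])
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
               nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
    sm <- t(apply(nb, 1, function(co) volArr[co[1], co[2], co[3], ]))
    out[x, y, z] <- oracleKendallW(sm)
  }
  out
}

# DFT bin enumeration by direct complex summation (no fft call)
oracleSpectrum <- function(series, fs) {
  T <- length(series)
  hs <- 0:(T %/% 2)
  amp <- vapply(hs, function(h)
    Mod(sum(series * exp(-2i * pi * h * (0:(T - 1)) / T))), numeric(1))
  list(amp = amp, freq = hs * fs / T)
}

oracleAlff <- function(series, fs, lo = 0.01, hi = 0.08, power = FALSE) {
  sp <- oracleSpectrum(series, fs)
  a <- if (power) sp$amp^2 else sp$amp
  sum(a[sp$freq >= lo & sp$freq <= hi])
}

oracleFalff <- function(series, fs, lo = 0.01, hi = 0.08) {
  sp <- oracleSpectrum(series, fs)
  keep <- sp$freq >= lo & sp$freq <= hi & sp$freq > 0
  den <- sum(sp$amp[sp$freq > 0])
  sum(sp$amp[keep]) / den
}

# closed-form OLS line fit
oracleLineFit <- function(y) {
  T <- length(y); tt <- seq_len(T)
  b <- sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
  a <- mean(y) - b * mean(tt)
  a + b * tt
}

# pooled-variance two-sample t, scalar formula
oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# depth-first flood fill on a 3D logical mask (stack-based, voxel at a time)
oracleFloodFill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  man <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[man == 1, ], "18" = offs[man <= 2, ], "26" = offs)
  lab <- array(0L, d); cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] != 0L) next
      lab[v] <- cur
      co <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        nb <- co + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[lin] && lab[lin] == 0L) stack <- c(stack, lin)
      }
    }
  }
  lab
}

# random in-memory volume
makeVol <- function(dims = c(4, 4, 4), T = 32, tr = 2, seed = 1) {
  set.seed(seed)
  new("TimeSeriesVolume", data = array(rnorm(prod(dims) * T), c(dims, T)),
      trSeconds = tr)
}

# a bin-aligned sinusoid volume builder
sinusoidSeries <- function(T, tr, hz, amp = 1, phase = 0) {
  amp * sin(2 * pi * hz * (0:(T - 1)) * tr + phase)
}
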