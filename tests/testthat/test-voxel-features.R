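seriesVol <- function(..., tr = 2) {
  ss <- list(...)
  arr <- array(unlist(ss), c(length(ss), 1, 1, length(ss[[1]])))
  for (i in seq_along(ss)) arr[i, 1, 1, ] <- ss[[i]]
  new("TimeSeriesVolume", data = arr, trSeconds = tr)
}

test_that("degree centrality counts signed suprathreshold correlations", {
  T <- 32
  s <- sinusoidSeries(T, 2, 2 / (T * 2))            # bin-aligned sinusoid
  c2 <- sinusoidSeries(T, 2, 2 / (T * 2), phase = pi / 2)  # orthogonal cosine
  dc <- degreeCentrality(seriesVol(s, s, c2))
  expect_equal(as.vector(featureValues(dc)), c(1, 1, 0))

  # perfect anticorrelation is NOT a connection under the signed rule
  dc2 <- degreeCentrality(seriesVol(s, -s))
  expect_equal(as.vector(featureValues(dc2)), c(0, 0))
  # ... but is under the absolute-value variant
  dc2a <- degreeCentrality(seriesVol(s, -s), absolute = TRUE)
  expect_equal(as.vector(featureValues(dc2a)), c(1, 1))

  # complete graph when every voxel carries one shared series
  set.seed(3)
  sh <- rnorm(16)
  arr <- array(rep(sh, each = 8), c(2, 2, 2, 16))
  dc3 <- degreeCentrality(new("TimeSeriesVolume", data = arr, trSeconds = 2))
  expect_true(all(featureValues(dc3) == 7))

  expect_error(degreeCentrality(seriesVol(s, c2), threshold = 1.5),
               "threshold")
})

test_that("degree centrality matches the all-pairs oracle on random volumes", {
  for (seed in 1:3) {
    vol <- makeVol(c(4, 4, 3), T = 24, seed = seed)
    got <- featureValues(degreeCentrality(vol))
    expect_identical(as.integer(got), as.integer(oracleDc(volData(vol))))
  }
})

test_that("ReHo is 1 for identical monotone neighbours, 0 for opposed pairs", {
  # every voxel of a 3^3 grid carries the same strictly monotone series
  arr <- array(rep(2^(1:16 / 4), each = 27), c(3, 3, 3, 16))
  w <- featureValues(regionalHomogeneity(
    new("TimeSeriesVolume", data = arr, trSeconds = 2)))
  expect_equal(as.vector(w), rep(1, 27), tolerance = 1e-12)

  # two voxels with exactly opposite rankings: W = 0
  v2 <- seriesVol(1:16, 16:1)
  w2 <- featureValues(regionalHomogeneity(v2))
  expect_equal(as.vector(w2), c(0, 0), tolerance = 1e-12)
})

test_that("ReHo equals the brute-force rank-sum oracle everywhere", {
  vol <- makeVol(c(5, 5, 5), T = 20, seed = 17)
  for (nb in c(7, 19, 27)) {
    got <- featureValues(regionalHomogeneity(vol, neighbourhood = nb))
    want <- oracleReho(volData(vol), nb)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("amplitude spectrum: DC-only constants, T/2 sinusoid peak, Parseval", {
  T <- 64
  spc <- amplitudeSpectrum(rep(3, T), fs = 0.5)
  expect_equal(unname(spc[1]), 3 * T)
  expect_lt(max(spc[-1]), 1e-10)

  hStar <- 5
  s <- sin(2 * pi * hStar * (0:(T - 1)) / T)
  sp <- amplitudeSpectrum(s, fs = 0.5)
  expect_equal(unname(sp[hStar + 1]), T / 2, tolerance = 1e-10)
  expect_lt(max(sp[-(hStar + 1)]), 1e-8)

  set.seed(2)
  x <- rnorm(T)
  expect_equal(sum(Mod(fft(x))^2), T * sum(x^2), tolerance = 1e-8)
  expect_error(amplitudeSpectrum(1:4, 0.5), ">= 8")
})

test_that("ALFF sums in-band amplitudes, is linear, ignores out-of-band power", {
  T <- 128; tr <- 2                      # bins at k/256 Hz
  s1 <- sinusoidSeries(T, tr, 13 / 256)  # ~0.0508 Hz, in band
  v1 <- seriesVol(s1, 2 * s1)
  a <- featureValues(alffMap(v1))
  expect_equal(a[1, 1, 1], T / 2, tolerance = 1e-8)
  expect_equal(a[2, 1, 1] / a[1, 1, 1], 2, tolerance = 1e-10)  # linearity

  oob <- seriesVol(sinusoidSeries(T, tr, 52 / 256))            # ~0.203 Hz
  expect_lt(featureValues(alffMap(oob))[1, 1, 1], 1e-8)

  # no bin in a silly narrow band -> configuration error naming the grid
  expect_error(alffMap(v1, 0.0001, 0.0002), "no DFT bin")
})

test_that("ALFF and fALFF match the bin-enumeration oracle on white noise", {
  vol <- makeVol(c(3, 3, 2), T = 64, seed = 23)
  a <- featureValues(alffMap(vol))
  f <- featureValues(falffMap(vol))
  ap <- featureValues(alffMap(vol, powerMode = TRUE))
  X <- matrix(volData(vol), ncol = 64)
  for (i in seq_len(nrow(X))) {
    expect_equal(as.vector(a)[i], oracleAlff(X[i, ], 0.5), tolerance = 1e-10)
    expect_equal(as.vector(f)[i], oracleFalff(X[i, ], 0.5), tolerance = 1e-10)
    expect_equal(as.vector(ap)[i], oracleAlff(X[i, ], 0.5, power = TRUE),
                 tolerance = 1e-8)
  }
  expect_true(all(f >= 0 & f <= 1))
})

test_that("fALFF: band-limited signal gives 1, split spectrum gives 0.5, scale-free", {
  T <- 128; tr <- 2
  inb <- seriesVol(sinusoidSeries(T, tr, 13 / 256))
  expect_equal(featureValues(falffMap(inb))[1, 1, 1], 1, tolerance = 1e-10)

  half <- seriesVol(sinusoidSeries(T, tr, 13 / 256) +
                      sinusoidSeries(T, tr, 52 / 256))
  expect_equal(featureValues(falffMap(half))[1, 1, 1], 0.5, tolerance = 1e-10)

  s <- sinusoidSeries(T, tr, 13 / 256) + 0.3 * sinusoidSeries(T, tr, 30 / 256)
  f1 <- featureValues(falffMap(seriesVol(s)))[1, 1, 1]
  f2 <- featureValues(falffMap(seriesVol(17.3 * s)))[1, 1, 1]
  expect_equal(f1, f2, tolerance = 1e-12)

  # constant voxel: flagged, set to 0, warned about
  expect_warning(fc <- falffMap(seriesVol(rep(4, T), sinusoidSeries(T, tr, 13 / 256))),
                 "undefined")
  expect_equal(featureValues(fc)[1, 1, 1], 0)
})

test_that("feature pipeline wiring: spectral maps unfiltered, correlation maps filtered", {
  vol <- makeVol(c(4, 4, 4), T = 64, seed = 29)
  maps <- extractFeatureMaps(vol, c("ALFF", "fALFF", "DC", "ReHo"))
  det <- detrendLinear(vol)
  bp <- bandpassFilter(det, 0.01, 0.08)
  expect_equal(featureValues(maps$ALFF), featureValues(alffMap(det)))
  expect_equal(featureValues(maps$fALFF), featureValues(falffMap(det)))
  expect_equal(as.vector(featureValues(maps$DC)),
               as.vector(featureValues(degreeCentrality(bp))))
  expect_equal(featureValues(maps$ReHo),
               featureValues(regionalHomogeneity(bp)))
})
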