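randMaps <- function(n, dims = c(5, 5, 5), seed = 1, shift = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(dims)) + shift, dims))
}

test_that("voxelwise t: zero on identical groups, antisymmetric under swap", {
  A <- randMaps(4, seed = 1)
  ttAA <- voxelwiseTTest(A, A)
  expect_true(all(abs(ttAA$t) < 1e-12, na.rm = TRUE))

  B <- randMaps(5, seed = 2, shift = 0.5)
  tAB <- voxelwiseTTest(A, B)
  tBA <- voxelwiseTTest(B, A)
  expect_equal(tAB$t, -tBA$t)
  expect_equal(tAB$df, 4 + 5 - 2)
})

test_that("pooled and Welch t match per-voxel oracles and stats::t.test", {
  A <- randMaps(6, dims = c(3, 3, 3), seed = 3)
  B <- randMaps(8, dims = c(3, 3, 3), seed = 4, shift = 0.3)
  tp <- voxelwiseTTest(A, B)
  tw <- voxelwiseTTest(A, B, welch = TRUE)
  for (v in c(1, 7, 27)) {
    a <- vapply(A, function(m) m[v], numeric(1))
    b <- vapply(B, function(m) m[v], numeric(1))
    expect_equal(tp$t[v], oraclePooledT(a, b), tolerance = 1e-10)
    expect_equal(tp$t[v], unname(t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
    ww <- t.test(a, b)
    expect_equal(tw$t[v], unname(ww$statistic), tolerance = 1e-10)
    expect_equal(tw$df[v], unname(ww$parameter), tolerance = 1e-8)
  }
  # degenerate voxels are flagged NA, not silently 0
  A0 <- lapply(A, function(m) { m[1] <- 5; m })
  B0 <- lapply(B, function(m) { m[1] <- 5; m })
  t0 <- voxelwiseTTest(A0, B0)
  expect_true(is.na(t0$t[1]))
  expect_equal(t0$flagged, 1L)
})

test_that("t-to-Z mapping is monotone, sign-preserving, exact against qnorm", {
  ts <- c(-8, -3.2, -1, 0, 0.5, 2.4, 6, 40)
  z <- tToZ(ts, df = 20)
  expect_equal(z[4], 0)
  expect_identical(sign(z), sign(ts))
  expect_true(all(diff(z) > 0))
  expect_true(all(is.finite(z)))          # log-scale path survives |t| = 40
  for (t1 in c(0.5, 2.4)) {
    p2 <- 2 * pt(t1, 20, lower.tail = FALSE)
    expect_equal(tToZ(t1, 20), qnorm(1 - p2 / 2), tolerance = 1e-10)
  }
})

test_that("cluster extraction recovers constructed components and drops small ones", {
  tm <- array(0, c(10, 10, 10))
  tm[3:5, 3:5, 3:5] <- 4                      # one 27-voxel block
  tm[8, 8, 8] <- 5                            # isolated voxel, below extent
  tab <- extractClusters(tm, df = 30, tThreshold = 3, minExtent = 10)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$voxel_count, 27)
  expect_equal(tab$peak_T, 4)
  expect_equal(tab$sign, "increase")
  expect_equal(tab$peak_Z, tToZ(4, 30))

  # negative blocks split by sign
  tm[7:9, 7:9, 7:9] <- -4
  tab2 <- extractClusters(tm, df = 30, tThreshold = 3, minExtent = 10)
  expect_equal(nrow(tab2), 2)
  expect_setequal(tab2$sign, c("increase", "decrease"))

  expect_equal(nrow(extractClusters(array(0, c(5, 5, 5)), df = 10)), 0)
  expect_error(extractClusters(tm, df = 10, tThreshold = -1), "positive")
})

test_that("corner-touching blocks merge at 26-connectivity, split at 6", {
  tm <- array(0, c(8, 8, 8))
  tm[2:3, 2:3, 2:3] <- 4
  tm[4:5, 4:5, 4:5] <- 4                      # touches the first at one corner
  t26 <- extractClusters(tm, df = 20, tThreshold = 3, minExtent = 1,
                         connectivity = 26)
  t6 <- extractClusters(tm, df = 20, tThreshold = 3, minExtent = 1,
                        connectivity = 6)
  expect_equal(nrow(t26), 1)
  expect_equal(t26$voxel_count, 16)
  expect_equal(nrow(t6), 2)
})

test_that("component labelling equals the flood-fill oracle on random masks", {
  set.seed(15)
  samePartition <- function(l1, l2) {
    g1 <- split(which(l1 > 0), l1[l1 > 0])
    g2 <- split(which(l2 > 0), l2[l2 > 0])
    setequal(lapply(g1, sort), lapply(g2, sort))
  }
  for (i in 1:6) {
    d <- sample(8:20, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.2, d)
    for (conn in c(6, 18, 26)) {
      got <- capsfmri:::labelComponents(mask, conn)
      want <- oracleFloodFill(mask, conn)
      expect_true(samePartition(got, want))
    }
  }
})

test_that("FDR map and cluster CSV output behave", {
  A <- randMaps(6, dims = c(4, 4, 4), seed = 6)
  B <- randMaps(6, dims = c(4, 4, 4), seed = 7, shift = 2)
  tt <- voxelwiseTTest(A, B)
  q <- voxelwiseFdr(tt)
  expect_true(all(q >= 0 & q <= 1, na.rm = TRUE))
  p <- 2 * pt(abs(tt$t), tt$df, lower.tail = FALSE)
  expect_true(all(q >= p - 1e-12, na.rm = TRUE))  # BH never decreases p

  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- clusterTable(A, B, tThreshold = 3, minExtent = 5, voxelSizeMm = 3,
                      csvPath = csv)
  if (nrow(tab) > 0) {
    expect_equal(tab$volume_mm3, tab$voxel_count * 27)
    got <- read.csv(csv)
    expect_equal(got$voxel_count, tab$voxel_count)
  }
})
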