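test_that("block atlas partitions a 4x4x4 grid into the eight octants", {
  atlas <- makeBlockAtlas(c(4, 4, 4), 8)
  lab <- atlasLabels(atlas)
  expect_identical(sort(unique(as.vector(lab))), 1:8)
  expect_true(all(table(lab) == 8))
  # each region is one 2x2x2 octant: constant within its octant corner
  expect_true(all(lab[1:2, 1:2, 1:2] == lab[1, 1, 1]))
  expect_true(all(lab[3:4, 3:4, 3:4] == lab[4, 4, 4]))
  expect_error(makeBlockAtlas(c(2, 2, 2), 9), "exceeds")
  expect_identical(atlasLabels(makeBlockAtlas(c(4, 4, 4), 8)), lab)
})

test_that("block atlas handles non-cubic counts with non-empty regions", {
  for (n in c(2, 3, 5, 6, 12)) {
    a <- makeBlockAtlas(c(6, 5, 4), n)
    expect_equal(nRegions(a), n)
    expect_true(all(table(atlasLabels(a)) >= 1))
  }
})

test_that("subject simulation is deterministic and label-conditional only", {
  cfg <- simulationConfig(gridShape = c(6, 6, 6), nTimepoints = 32,
                          effectAlff = 2, affectedRegions = c(5L, 6L))
  atlas <- makeBlockAtlas(c(6, 6, 6), 8)
  v1 <- simulateSubject(cfg, atlas, 1L, 99L)
  v2 <- simulateSubject(cfg, atlas, 1L, 99L)
  expect_identical(volData(v1), volData(v2))
  v3 <- simulateSubject(cfg, atlas, 0L, 99L)
  expect_false(identical(volData(v1), volData(v3)))
  # with all effects zero, label does not enter the generator at all
  cfg0 <- simulationConfig(gridShape = c(6, 6, 6), nTimepoints = 32)
  expect_identical(volData(simulateSubject(cfg0, atlas, 1L, 7L)),
                   volData(simulateSubject(cfg0, atlas, 0L, 7L)))
})

test_that("effectAlff raises affected-region ALFF for patients in most seed pairs", {
  cfg <- simulationConfig(gridShape = c(6, 6, 6), nTimepoints = 64,
                          effectAlff = 2, affectedRegions = c(5L, 6L))
  atlas <- makeBlockAtlas(c(6, 6, 6), 8)
  affVox <- which(atlasLabels(atlas) %in% c(5L, 6L))
  hits <- 0L; nPairs <- 50L
  for (s in seq_len(nPairs)) {
    p <- simulateSubject(cfg, atlas, 1L, 2000L + s)
    c0 <- simulateSubject(cfg, atlas, 0L, 5000L + s)
    ap <- featureValues(alffMap(detrendLinear(p)))
    ac <- featureValues(alffMap(detrendLinear(c0)))
    if (mean(ap[affVox]) > mean(ac[affVox])) hits <- hits + 1L
  }
  expect_gte(hits / nPairs, 0.95)
})

test_that("effectAlff alone leaves off-diagonal FC group means at chance", {
  cfg <- simulationConfig(gridShape = c(6, 6, 6), nTimepoints = 64,
                          effectAlff = 2, affectedRegions = c(5L, 6L))
  atlas <- makeBlockAtlas(c(6, 6, 6), 8)
  offMean <- function(label, seed) {
    v <- simulateSubject(cfg, atlas, label, seed)
    r <- fcValues(fcMatrix(regionMeans(preprocessFor(v, "FC"), atlas)))
    mean(r[lower.tri(r)])
  }
  pats <- vapply(1:50, function(s) offMean(1L, 100L + s), numeric(1))
  ctls <- vapply(1:50, function(s) offMean(0L, 600L + s), numeric(1))
  expect_gt(t.test(pats, ctls)$p.value, 0.001)
})

test_that("cohort simulation writes manifest, atlas, ground truth reproducibly", {
  cfg <- simulationConfig(gridShape = c(6, 6, 6), nRegions = 8,
                          nTimepoints = 16, nPatients = 3, nControls = 2,
                          seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ch <- simulateCohort(cfg, d1)
  man <- readManifest(file.path(d1, "manifest.csv"))
  expect_length(subjectIds(man), 5)
  expect_equal(sum(cohortLabels(man) == 1L), 3)
  expect_equal(sum(cohortLabels(man) == 0L), 2)
  expect_true(all(file.exists(volumePaths(man))))
  expect_s4_class(readAtlas(file.path(d1, "atlas.nii.gz")), "AtlasParcellation")
  simulateCohort(cfg, d2)
  # regeneration is byte-identical apart from the embedded paths
  norm <- function(d, f) gsub(d, "DIR", readLines(file.path(d, f)), fixed = TRUE)
  expect_identical(norm(d1, "manifest.csv"), norm(d2, "manifest.csv"))
  expect_identical(readLines(file.path(d1, "ground_truth.json")),
                   readLines(file.path(d2, "ground_truth.json")))
  v1 <- readVolume(volumePaths(man)[1])
  v2 <- readVolume(file.path(d2, basename(volumePaths(man)[1])))
  expect_identical(volData(v1), volData(v2))
})

test_that("single-class cohorts are generated but rejected at training", {
  cfg <- simulationConfig(gridShape = c(6, 6, 6), nTimepoints = 16,
                          nPatients = 0, nControls = 3, seed = 1)
  d <- withr::local_tempdir()
  ch <- simulateCohort(cfg, d)
  man <- readManifest(file.path(d, "manifest.csv"))
  expect_true(all(cohortLabels(man) == 0L))
  expect_error(trainFromManifest(man, "ALFF", d), "both classes")
})
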