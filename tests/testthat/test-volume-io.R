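test_that("volume write/read round trip is bit-exact and keeps the TR", {
  vol <- makeVol(c(4, 4, 4), T = 16, tr = 2, seed = 11)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, p)
  back <- readVolume(p)
  expect_identical(volData(back), volData(vol))
  expect_equal(trSeconds(back), 2.0)
  expect_equal(samplingFrequency(back), 0.5)
})

test_that("malformed volumes are rejected with informative errors", {
  p3 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(rnorm(64), c(4, 4, 4))), p3)
  expect_error(readVolume(p3), "expected 4D")
  expect_error(readVolume(file.path(tempdir(), "nope.nii.gz")), "not found")

  bad <- array(rnorm(4^3 * 16), c(4, 4, 4, 16))
  bad[1, 1, 1, 1] <- NaN; bad[2, 2, 2, 2] <- Inf
  pb <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(bad); RNifti::pixdim(img) <- c(1, 1, 1, 2)
  RNifti::writeNifti(img, pb)
  expect_error(readVolume(pb), "2 non-finite")
})

test_that("atlas reading validates grid, labels and region count", {
  vol <- makeVol(c(4, 4, 4), T = 16, seed = 2)
  lab <- array(0L, c(4, 4, 4)); lab[1:2, , ] <- 1L; lab[3, , ] <- 2L
  lab[4, , ] <- 3L
  pa <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int32"), pa)
  atlas <- readAtlas(pa, vol)
  expect_equal(nRegions(atlas), 3)
  expect_identical(regionIds(atlas), 1:3)
  # atlas round trip is bit-exact
  pb <- withr::local_tempfile(fileext = ".nii.gz")
  writeAtlas(atlas, pb)
  expect_identical(atlasLabels(readAtlas(pb, vol)), atlasLabels(atlas))

  small <- makeVol(c(3, 4, 4), T = 16, seed = 3)
  expect_error(readAtlas(pa, small), "does not match")
  one <- array(1L, c(4, 4, 4)); one[1, 1, 1] <- 0L
  po <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(one, datatype = "int32"), po)
  expect_error(readAtlas(po, vol), ">= 2 regions")
})

test_that("atlas region count drives the FC matrix order (116 regions)", {
  set.seed(9)
  series <- matrix(rnorm(116 * 24), nrow = 116)
  fc <- fcMatrix(new("RegionTimeSeries", series = series, regionIds = 1:116))
  expect_equal(dim(fcValues(fc)), c(116, 116))
  expect_length(fcFeatures(fc), 116 * 115 / 2)   # 6670
})

test_that("manifest contract: header, labels, duplicates, line numbers", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,volume_path,label",
               "s1,/a/s1.nii.gz,1", "s2,/a/s2.nii.gz,0",
               "s3,/a/s3.nii.gz,1"), p)
  man <- readManifest(p)
  expect_length(subjectIds(man), 3)
  expect_identical(cohortLabels(man), c(1L, 0L, 1L))

  writeLines(c("subject_id,volume_path,label",
               "s1,/a,1", "s1,/b,0"), p)
  expect_error(readManifest(p), "duplicate subject id 's1'")

  writeLines(c("subject_id,volume_path,label",
               "s1,/a,1", "s2,/b,2"), p)
  expect_error(readManifest(p), "line 3")

  writeLines(c("id,path,label", "s1,/a,1"), p)
  expect_error(readManifest(p), "header")

  # write -> read round trip
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeManifest(man, p2)
  man2 <- readManifest(p2)
  expect_identical(subjectIds(man2), subjectIds(man))
  expect_identical(cohortLabels(man2), cohortLabels(man))
})

test_that("atlas voxel (x,y,z) addresses volume voxel (x,y,z,.) unchanged", {
  vol <- makeVol(c(3, 4, 5), T = 16, seed = 5)
  lab <- array(0L, c(3, 4, 5))
  lab[2, 3, 4] <- 1L            # singleton region at a known coordinate
  lab[1, 1, 1] <- 2L
  atlas <- new("AtlasParcellation", labels = lab, regionIds = c(1L, 2L))
  rts <- regionMeans(vol, atlas)
  expect_equal(regionSeries(rts)[1, ], volData(vol)[2, 3, 4, ])
  expect_equal(regionSeries(rts)[2, ], volData(vol)[1, 1, 1, ])
})
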