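test_that("phantom cases round-trip through the BraTS directory layout", {
  td <- file.path(tempdir(), "io_roundtrip")
  unlink(td, recursive = TRUE)
  generatePhantomCohort(1, td, jitter = 0, seed = 7)
  cd <- list.dirs(td, recursive = FALSE)[1]
  cs <- loadCase(cd)
  ref <- generatePhantomCase(local({
    s <- phantomSpec(); s$seed <- deriveSeed(7, 101L, 1L); s
  }))
  for (m in MODALITIES)
    expect_equal(getChannel(cs$volume, m), getChannel(ref$volume, m),
                 tolerance = 1e-6)
  expect_identical(labelArray(cs$labels), labelArray(ref$labels))
  expect_true(all(MODALITIES %in% names(cs$manifest)))
})

test_that("missing modality and bad label values are fatal with diagnostics", {
  td <- file.path(tempdir(), "io_missing")
  unlink(td, recursive = TRUE)
  generatePhantomCohort(1, td, jitter = 0, seed = 7)
  cd <- list.dirs(td, recursive = FALSE)[1]
  t2 <- list.files(cd, pattern = "_t2\\.nii", full.names = TRUE)
  file.remove(t2)
  expect_error(loadCase(cd), "T2")

  td2 <- file.path(tempdir(), "io_badlabel")
  unlink(td2, recursive = TRUE)
  generatePhantomCohort(1, td2, jitter = 0, seed = 7)
  cd2 <- list.dirs(td2, recursive = FALSE)[1]
  segf <- list.files(cd2, pattern = "_seg", full.names = TRUE)
  seg <- RNifti::readNifti(segf)
  arr <- array(as.integer(seg), dim = dim(seg))
  arr[1, 1, 1] <- 3L
  RNifti::writeNifti(RNifti::asNifti(arr), segf, datatype = "uint8")
  expect_error(loadCase(cd2), "3")
})

test_that("label <-> class-index codec is the defining bijection", {
  expect_identical(labelsToClassIndices(c(0L, 1L, 2L, 4L)), c(0L, 1L, 2L, 3L))
  expect_identical(indicesToLabels(c(0L, 1L, 2L, 3L)), c(0L, 1L, 2L, 4L))
  set.seed(5)
  x <- array(sample(c(0L, 1L, 2L, 4L), 60, TRUE), dim = c(3, 4, 5))
  expect_identical(indicesToLabels(labelsToClassIndices(x)), x)
  idx <- array(sample(0:3, 60, TRUE), dim = c(3, 4, 5))
  expect_identical(labelsToClassIndices(indicesToLabels(idx)), idx)
  z <- array(0L, dim = c(2, 2, 2))
  expect_identical(labelsToClassIndices(z), z)
  expect_error(labelsToClassIndices(c(0L, 3L)), "3")
  expect_error(indicesToLabels(c(0L, 4L)), "4")
})

test_that("evaluation regions follow the nested ET/TC/WT definitions", {
  lab <- array(c(0L, 1L, 2L, 4L), dim = c(4, 1, 1))
  r <- deriveRegions(lab)
  expect_equal(as.vector(r$ET), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(as.vector(r$TC), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(as.vector(r$WT), c(FALSE, TRUE, TRUE, TRUE))
  empty <- deriveRegions(array(0L, dim = c(3, 3, 3)))
  expect_false(any(empty$ET) || any(empty$TC) || any(empty$WT))
  set.seed(11)
  for (i in 1:5) {
    lab <- array(sample(c(0L, 1L, 2L, 4L), 4^3, TRUE), dim = c(4, 4, 4))
    r <- deriveRegions(lab)
    expect_true(all(r$TC[r$ET]))        # ET subset of TC
    expect_true(all(r$WT[r$TC]))        # TC subset of WT
    expect_equal(sum(r$WT), sum(lab != 0))
  }
  # information loss: swapping labels 1 and 2 changes TC but two labelings
  # agreeing on {ET, TC, WT} memberships give identical masks
  a <- array(c(1L, 2L, 0L, 4L), dim = c(4, 1, 1))
  b <- a; b[1] <- 1L  # identical labeling
  expect_identical(deriveRegions(a), deriveRegions(b))
})

test_that("saved predictions reload bit-identically and reject bad input", {
  cs <- generatePhantomCase(phantomSpec(seed = 3))
  out <- tempfile(fileext = ".nii.gz")
  saveLabelVolume(cs$labels, cs$volume, out)
  td <- file.path(tempdir(), "io_pred")
  unlink(td, recursive = TRUE); dir.create(td)
  file.copy(out, file.path(td, "case_seg.nii.gz"))
  reread <- RNifti::readNifti(out)
  expect_identical(array(as.integer(reread), dim = dim(reread)),
                   labelArray(cs$labels))
  # class-index space (value 3) must be rejected
  arr <- labelArray(cs$labels); arr[1] <- 3L
  expect_error(LabelVolume(arr), "3")
  # geometry mismatch
  small <- LabelVolume(array(0L, dim = c(8, 8, 4)))
  expect_error(saveLabelVolume(small, cs$volume, out), "geometry")
  # all-zero prediction is a valid file
  zero <- LabelVolume(array(0L, dim = volumeShape(cs$labels)))
  expect_silent(saveLabelVolume(zero, cs$volume, out))
})
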