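test_that("phantom generation is deterministic and respects the contrast table", {
  s <- phantomSpec(seed = 7)
  a <- generatePhantomCase(s)
  b <- generatePhantomCase(s)
  expect_identical(a$volume@channels, b$volume@channels)
  expect_identical(labelArray(a$labels), labelArray(b$labels))
  # noise-free phantom is piecewise constant at the table values
  s0 <- phantomSpec(noise_std = 0, seed = 1)
  c0 <- generatePhantomCase(s0)
  tbl <- defaultContrastTable()
  for (m in MODALITIES) {
    ch <- getChannel(c0$volume, m)
    for (t in colnames(tbl))
      if (any(c0$tissue == t))
        expect_equal(unique(ch[c0$tissue == t]), tbl[m, t],
                     ignore_attr = TRUE)
  }
  # background exactly zero even with noise
  expect_true(all(getChannel(a$volume, "FLAIR")[a$tissue == "background"] == 0))
})

test_that("planted contrasts carry the expected radiological signs", {
  tbl <- defaultContrastTable()
  expect_gt(tbl["FLAIR", "edema"], tbl["FLAIR", "white_matter"])
  expect_gt(tbl["T2", "edema"], tbl["T2", "white_matter"])
  expect_true(all(tbl["T1Gd", "enhancing"] >
                  tbl["T1Gd", c("edema", "necrotic_core")]))
  expect_lt(tbl["T1Gd", "necrotic_core"], tbl["T1Gd", "enhancing"])
  # edema is identical to white matter on T1 and T1Gd (modality-attribution
  # ground truth: only T2/FLAIR can separate them)
  expect_equal(tbl["T1", "edema"], tbl["T1", "white_matter"])
  expect_equal(tbl["T1Gd", "edema"], tbl["T1Gd", "white_matter"])
})

test_that("region voxel counts match the analytic shell conditions", {
  s <- phantomSpec(noise_std = 0, seed = 2)
  cs <- generatePhantomCase(s)
  r <- deriveRegions(cs$labels)
  # exhaustive scan of the analytic conditions
  d <- s$image_shape
  cnt_et <- 0L; cnt_tc <- 0L; cnt_wt <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    rr <- sqrt(sum((c(i, j, k) - s$tumor_center)^2))
    if (rr <= s$r_wt) cnt_wt <- cnt_wt + 1L
    if (rr <= s$r_tc) cnt_tc <- cnt_tc + 1L
    if (rr <= s$r_tc && rr > s$r_core) cnt_et <- cnt_et + 1L
  }
  expect_identical(sum(r$ET), cnt_et)
  expect_identical(sum(r$TC), cnt_tc)
  expect_identical(sum(r$WT), cnt_wt)
})

test_that("tumor outside the brain ellipsoid is fatal", {
  expect_error(generatePhantomCase(phantomSpec(r_wt = 40, r_tc = 30,
                                               r_core = 20)),
               "brain")
})

test_that("cohorts are reproducible, loadable and jitter-controlled", {
  t1 <- file.path(tempdir(), "coh_a"); unlink(t1, recursive = TRUE)
  t2 <- file.path(tempdir(), "coh_b"); unlink(t2, recursive = TRUE)
  d1 <- generatePhantomCohort(3, t1, jitter = 2, seed = 5)
  d2 <- generatePhantomCohort(3, t2, jitter = 2, seed = 5)
  expect_length(d1, 3)
  for (i in 1:3) {
    a <- loadCase(d1[i]); b <- loadCase(d2[i])
    expect_equal(getChannel(a$volume, "T1"), getChannel(b$volume, "T1"),
                 tolerance = 1e-6)
    expect_identical(labelArray(a$labels), labelArray(b$labels))
  }
  # jitter = 0: identical geometry across cases (only the noise stream differs)
  t3 <- file.path(tempdir(), "coh_c"); unlink(t3, recursive = TRUE)
  d3 <- generatePhantomCohort(2, t3, jitter = 0, seed = 5)
  la <- loadCase(d3[1])$labels; lb <- loadCase(d3[2])$labels
  expect_identical(labelArray(la), labelArray(lb))
})

test_that("low-noise phantoms are separable by a nearest-mean classifier", {
  gap <- minContrastGap()
  s <- phantomSpec(noise_std = 0.05 * gap, seed = 13)
  cs <- generatePhantomCase(s)
  stk <- channelStack(cs$volume)
  tbl <- defaultContrastTable()
  X <- matrix(stk, ncol = 4)
  d2 <- vapply(colnames(tbl),
               function(t) colSums((t(X) - tbl[, t])^2), numeric(nrow(X)))
  cls <- colnames(tbl)[max.col(-d2)]
  pred_wt <- array(cls %in% c("edema", "necrotic_core", "enhancing"),
                   dim = dim(labelArray(cs$labels)))
  expect_gte(diceCoefficient(pred_wt, labelArray(cs$labels) != 0), 0.98)
})
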