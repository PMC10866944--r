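.mkVol <- function(arrs) {
  names(arrs) <- MODALITIES
  MultimodalVolume(arrs)
}

test_that("z-score uses brain voxels only, population std, exact values", {
  a <- array(0, dim = c(4, 4, 2))
  a[1:3, 1, 1] <- c(1, 2, 3)
  vol <- .mkVol(list(a, a, a, a))
  mask <- a != 0
  zs <- zscoreNormalize(vol, mask)
  v <- getChannel(zs$volume, "T1")[1:3, 1, 1]
  expect_equal(v, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-7)
  expect_equal(sum(getChannel(zs$volume, "T1")[!mask]), 0)
  # brain mean ~0, population std ~1
  bv <- getChannel(zs$volume, "T2")[mask]
  expect_lt(abs(mean(bv)), 1e-6)
  expect_lt(abs(sqrt(mean((bv - mean(bv))^2)) - 1), 1e-6)
  # constant channel: fallback flag, zeros inside brain
  cc <- array(0, dim = c(4, 4, 2)); cc[mask] <- 5
  vol2 <- .mkVol(list(cc, a, a, a))
  zs2 <- zscoreNormalize(vol2, mask)
  expect_true(zs2$norm$T1$fallback)
  expect_equal(sum(abs(getChannel(zs2$volume, "T1"))), 0)
  # statistics unaffected by background voxels (they are excluded)
  big <- array(0, dim = c(8, 8, 2)); big[1:3, 1, 1] <- c(1, 2, 3)
  zs3 <- zscoreNormalize(.mkVol(list(big, big, big, big)), big != 0)
  expect_equal(getChannel(zs3$volume, "T1")[1:3, 1, 1], v)
})

test_that("z-score is invariant to affine intensity rescaling", {
  set.seed(2)
  a <- array(0, dim = c(6, 6, 3))
  mask <- array(FALSE, dim = dim(a)); mask[2:5, 2:5, ] <- TRUE
  a[mask] <- rnorm(sum(mask), 10, 3)
  b <- a; b[mask] <- 2.5 * a[mask] + 7
  za <- zscoreNormalize(.mkVol(list(a, a, a, a)), mask)
  zb <- zscoreNormalize(.mkVol(list(b, b, b, b)), mask)
  expect_equal(getChannel(za$volume, "T1"), getChannel(zb$volume, "T1"),
               tolerance = 1e-10)
})

test_that("non-brain zeroing is idempotent and removes isolated speckles", {
  set.seed(4)
  a <- array(0, dim = c(24, 24, 8))
  a[8:16, 8:16, 3:6] <- 1 + runif(9 * 9 * 4)   # main component
  spk <- rbind(c(1, 1, 1), c(22, 3, 8), c(2, 20, 1), c(23, 23, 7),
               c(1, 12, 8))
  for (i in seq_len(nrow(spk))) a[spk[i, 1], spk[i, 2], spk[i, 3]] <- 9
  vol <- .mkVol(list(a, a, a, a))
  zb <- zeroNonbrain(vol)
  # independent oracle: exhaustive flood fill from a voxel of the big block
  nz <- a != 0
  comp <- array(FALSE, dim = dim(a))
  queue <- matrix(c(10, 10, 4), ncol = 3)
  comp[10, 10, 4] <- TRUE
  while (nrow(queue) > 0) {
    v <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      u <- v + d
      if (all(u >= 1) && all(u <= dim(a)) &&
          nz[u[1], u[2], u[3]] && !comp[u[1], u[2], u[3]]) {
        comp[u[1], u[2], u[3]] <- TRUE
        queue <- rbind(queue, u)
      }
    }
  }
  expect_identical(zb$mask, comp)
  for (i in seq_len(nrow(spk)))
    expect_equal(getChannel(zb$volume, "T1")[spk[i, 1], spk[i, 2], spk[i, 3]], 0)
  # interior unchanged, idempotent
  expect_equal(getChannel(zb$volume, "T2")[10, 10, 4], a[10, 10, 4])
  zb2 <- zeroNonbrain(zb$volume)
  expect_identical(zb2$volume@channels, zb$volume@channels)
  # entirely empty volume is fatal
  z <- array(0, dim = c(4, 4, 2))
  expect_error(zeroNonbrain(.mkVol(list(z, z, z, z))), "zero")
})

test_that("center crop records offsets and inverts exactly", {
  x <- array(seq_len(240 * 240 * 3), dim = c(240, 240, 3))
  cr <- centerCrop(x, c(192L, 192L))
  expect_equal(dim(cr$x), c(192, 192, 3))
  expect_equal(cr$record$crop_offsets, c(24L, 24L))
  expect_equal(cr$x[1, 1, 1], x[25, 25, 1])
  inv <- invertCrop(cr$x, cr$record)
  expect_equal(inv[25:216, 25:216, ], x[25:216, 25:216, ])
  expect_true(all(inv[1:24, , ] == 0))

  id <- centerCrop(array(1, dim = c(192, 192, 2)), c(192L, 192L))
  expect_equal(id$record$crop_offsets, c(0L, 0L))

  small <- array(seq_len(160 * 160 * 2), dim = c(160, 160, 2))
  pd <- centerCrop(small, c(192L, 192L))
  expect_equal(pd$record$crop_offsets, c(-16L, -16L))
  expect_equal(dim(pd$x), c(192, 192, 2))
  expect_true(all(pd$x[1:16, , ] == 0))
  expect_equal(pd$x[17, 17, 1], small[1, 1, 1])
  expect_identical(invertCrop(pd$x, pd$record), small)
})

test_that("axial slice extraction and prediction reassembly are inverse", {
  cs <- generatePhantomCase(phantomSpec(seed = 9))
  pp <- preprocessCase(cs$volume, labels = cs$labels,
                       crop_size = c(96L, 96L))
  sl <- extractAxialSlices(pp)
  expect_length(sl, 32)
  expect_equal(dim(sl[[1]]$image), c(96, 96, 4))
  # channel order is the canonical modality order regardless of input order
  perm <- cs$volume@channels[c("FLAIR", "T2", "T1Gd", "T1")]
  vol2 <- MultimodalVolume(perm)
  pp2 <- preprocessCase(vol2, labels = cs$labels, crop_size = c(96L, 96L))
  expect_equal(pp2$x, pp$x)
  # reassembling the true label slices reproduces the original volume
  lv <- reassemblePrediction(lapply(sl, `[[`, "label"),
                             vapply(sl, `[[`, 0L, "index"), pp$record)
  expect_identical(labelArray(lv), labelArray(cs$labels))
  # training filter drops near-empty slices
  sl_tr <- extractAxialSlices(pp, training_only = TRUE)
  expect_lt(length(sl_tr), length(sl))
})
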