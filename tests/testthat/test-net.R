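test_that("encoder/decoder shapes follow the config arithmetic", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 1)
  x <- array(rnorm(96 * 96 * 4 * 2), dim = c(96, 96, 4, 2))
  fw <- netForward(m, x)
  expect_equal(dim(fw$acts$EB4), c(12, 12, 64, 2))   # 96 / 8, 8 * 2^3
  expect_equal(dim(fw$probs), c(96, 96, 4, 2))
  expect_equal(sort(m$tags),
               sort(c(paste0("EB", 1:4), "BOT", paste0("DB", 1:4), "OUT")))
  expect_error(modelConfig(input_size = c(100L, 100L)), "divisible")
  expect_error(netForward(m, array(0, dim = c(96, 96, 3, 1))), "channels")
})

test_that("parameter count is a pure function of the config", {
  expect_identical(parameterCount(buildModel(tinyModelConfig(), seed = 1)),
                   246748L)
  expect_identical(parameterCount(buildModel(tinyModelConfig(), seed = 99)),
                   246748L)
})

test_that("patch embedding produces the expected token counts and inverts", {
  feat <- array(rnorm(24 * 24 * 6), dim = c(24, 24, 6))
  W1 <- diag(6); b <- numeric(6)
  z1 <- patchEmbed(feat, W1, b, pos = NULL, P = 1L)
  expect_equal(dim(z1), c(576, 6))
  # identity projection: unembedding restores the spatial arrangement
  back <- gliomaseg:::.patch2im(z1, 24, 24, 1L, 6)
  expect_equal(back, feat)
  W2 <- diag(4 * 6)
  z2 <- patchEmbed(feat, W2, numeric(24), pos = NULL, P = 2L)
  expect_equal(dim(z2), c(144, 24))
  back2 <- gliomaseg:::.patch2im(z2, 12, 12, 2L, 6)
  expect_equal(back2, feat)
})

test_that("transformer blocks: zero output projections give the identity", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 2)
  m$params[["TB1.Wo"]][] <- 0; m$params[["TB1.bo"]][] <- 0
  m$params[["TB1.W2"]][] <- 0; m$params[["TB1.b2"]][] <- 0
  set.seed(3)
  z <- matrix(rnorm(144 * 64), 144, 64)
  out <- transformerBlockForward(z, m$params, "TB1", cfg$num_heads)$out
  expect_lt(max(abs(out - z)), 1e-6)
})

test_that("self-attention is permutation-equivariant (4-token brute force)", {
  D <- 8; Tn <- 4; heads <- 2
  set.seed(5)
  p <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    p[[paste0("TB1.", nm)]] <- matrix(rnorm(D * D, 0, 0.3), D, D)
  for (nm in c("bq", "bk", "bv", "bo")) p[[paste0("TB1.", nm)]] <- rnorm(D)
  p[["TB1.ln1.gamma"]] <- rep(1, D); p[["TB1.ln1.beta"]] <- numeric(D)
  p[["TB1.ln2.gamma"]] <- rep(1, D); p[["TB1.ln2.beta"]] <- numeric(D)
  p[["TB1.W1"]] <- matrix(rnorm(D * 16, 0, 0.3), D, 16)
  p[["TB1.b1"]] <- rnorm(16)
  p[["TB1.W2"]] <- matrix(rnorm(16 * D, 0, 0.3), 16, D)
  p[["TB1.b2"]] <- rnorm(D)
  z <- matrix(rnorm(Tn * D), Tn, D)
  perm <- c(3, 1, 4, 2)
  out <- transformerBlockForward(z, p, "TB1", heads)$out
  out_p <- transformerBlockForward(z[perm, ], p, "TB1", heads)$out
  expect_equal(out_p[order(perm), ], out, tolerance = 1e-10)
  # brute-force single-head attention oracle on the LN-ed input
  ln <- gliomaseg:::lnForward(z, p[["TB1.ln1.gamma"]], p[["TB1.ln1.beta"]])$out
  Q <- sweep(ln %*% p[["TB1.Wq"]], 2, p[["TB1.bq"]], `+`)
  K <- sweep(ln %*% p[["TB1.Wk"]], 2, p[["TB1.bk"]], `+`)
  V <- sweep(ln %*% p[["TB1.Wv"]], 2, p[["TB1.bv"]], `+`)
  dh <- D / heads
  O <- matrix(0, Tn, D)
  for (h in 1:heads) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, cols] %*% t(K[, cols]) / sqrt(dh)
    A <- matrix(0, Tn, Tn)
    for (i in 1:Tn) A[i, ] <- exp(S[i, ] - max(S[i, ])) /
        sum(exp(S[i, ] - max(S[i, ])))
    O[, cols] <- A %*% V[, cols]
  }
  msa <- sweep(O %*% p[["TB1.Wo"]], 2, p[["TB1.bo"]], `+`)
  got <- gliomaseg:::msaForward(ln, p, "TB1", heads)$out
  expect_equal(got, msa, tolerance = 1e-12)
})

test_that("forward pass is deterministic, softmax-normalized and NaN-free", {
  m <- buildModel(tinyModelConfig(), seed = 4)
  x1 <- array(rnorm(96 * 96 * 4), dim = c(96, 96, 4, 1))
  x <- array(0, dim = c(96, 96, 4, 2))
  x[, , , 1] <- x1; x[, , , 2] <- x1
  fw <- netForward(m, x)
  expect_equal(fw$probs[, , , 1], fw$probs[, , , 2], tolerance = 1e-12)
  expect_lt(max(abs(apply(fw$probs, c(1, 2, 4), sum) - 1)), 1e-5)
  z <- netForward(m, array(0, dim = c(96, 96, 4, 1)))
  expect_false(any(!is.finite(z$probs)))
  # argmax decodes to the BraTS alphabet
  cls <- apply(fw$probs[, , , 1], c(1, 2), which.max) - 1L
  expect_true(all(indicesToLabels(cls) %in% c(0L, 1L, 2L, 4L)))
})

test_that("gradients exist, are finite, and skips are live", {
  m <- buildModel(tinyModelConfig(), seed = 6)
  set.seed(7)
  x <- array(rnorm(96 * 96 * 4 * 2), dim = c(96, 96, 4, 2))
  y <- array(sample(0:3, 96 * 96 * 2, TRUE), dim = c(96, 96, 2))
  bl <- gliomaseg:::.batchLoss(m, x, y, training = TRUE)
  bw <- netBackward(m, bl$fw, bl$dlogits)
  expect_setequal(names(bw$grads), names(m$params))
  expect_true(all(vapply(bw$grads, function(g) all(is.finite(g)), TRUE)))
  # substituting a zero activation for an encoder skip changes the output
  fw0 <- netForward(m, x)
  fw1 <- netForward(m, x,
                    substitute = list(EB1 = array(0, dim = dim(fw0$acts$EB1))))
  expect_gt(max(abs(fw0$probs - fw1$probs)), 1e-6)
})

test_that("checkpoints round-trip to bit-identical logits", {
  m <- buildModel(tinyModelConfig(), seed = 8)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  x <- array(rnorm(96 * 96 * 4), dim = c(96, 96, 4, 1))
  expect_identical(netForward(m, x)$logits, netForward(m2, x)$logits)
})
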