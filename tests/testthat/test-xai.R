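test_that("Grad-CAM weights match a finite-difference gradient oracle", {
  m <- .toyModel()
  set.seed(12)
  img <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  spec <- classScoreSpec(2, pixels = "all", source = "logit")
  cam <- gradCAM(m, img, "EB1", spec)
  x <- array(img, dim = c(8, 8, 4, 1))
  base <- netForward(m, x)
  A <- base$acts$EB1
  Npix <- 8 * 8
  yc <- function(acts) sum(acts$OUT[, , spec$target_class + 1, 1])
  eps <- 1e-4
  for (k in seq_len(dim(A)[3])) {
    Ap <- A; Ap[, , k, ] <- Ap[, , k, ] + eps
    Am <- A; Am[, , k, ] <- Am[, , k, ] - eps
    yp <- yc(netForward(m, x, substitute = list(EB1 = Ap))$acts)
    ym <- yc(netForward(m, x, substitute = list(EB1 = Am))$acts)
    fd_alpha <- (yp - ym) / (2 * eps) / Npix
    expect_equal(cam$alpha[k], fd_alpha, tolerance = 1e-4)
  }
})

test_that("Grad-CAM at the last decoder block matches the symbolic derivation", {
  m <- .toyModel()
  set.seed(13)
  img <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  spec <- classScoreSpec(1, pixels = "all", source = "logit")
  cam <- gradCAM(m, img, "DB2", spec)
  # y^c = sum_pix logits_c and logits = 1x1 conv of A: the gradient w.r.t.
  # channel k is exactly OUT.W[k, c] at every pixel, so alpha_k = OUT.W[k, c]
  Wout <- m$params[["OUT.W"]]
  expect_equal(cam$alpha, as.vector(Wout[1, 1, , spec$target_class + 1]),
               tolerance = 1e-8)
  A <- netForward(m, array(img, dim = c(8, 8, 4, 1)))$acts$DB2
  manual <- array(0, dim = c(8, 8))
  for (k in seq_len(dim(A)[3]))
    manual <- manual + cam$alpha[k] * A[, , k, 1]
  expect_equal(cam$raw, pmax(manual, 0), tolerance = 1e-8)
})

test_that("ReLU gating: nonnegativity, annihilation, linearity, idempotence", {
  m <- .toyModel()
  set.seed(14)
  img <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  spec <- classScoreSpec(0, pixels = "all")
  # force all-negative weights into the output conv for class 0
  m$params[["OUT.W"]][1, 1, , 1] <- -abs(m$params[["OUT.W"]][1, 1, , 1]) - 0.1
  cam <- gradCAM(m, img, "DB2", spec)
  expect_true(cam$all_zero)
  expect_true(all(cam$heatmap == 0))
  # all-positive weights: ReLU inactive, map = sum alpha A exactly
  m$params[["OUT.W"]][1, 1, , 1] <- abs(m$params[["OUT.W"]][1, 1, , 1]) + 0.1
  cam2 <- gradCAM(m, img, "DB2", spec)
  expect_true(all(cam2$raw >= 0))
  A <- netForward(m, array(img, dim = c(8, 8, 4, 1)))$acts$DB2
  lin <- array(0, dim = c(8, 8))
  for (k in seq_len(dim(A)[3])) lin <- lin + cam2$alpha[k] * A[, , k, 1]
  expect_equal(cam2$raw, lin, tolerance = 1e-10)
  # frozen alpha: the pre-ReLU map is linear in A
  expect_equal(2 * lin, {
    l2 <- array(0, dim = c(8, 8))
    for (k in seq_len(dim(A)[3])) l2 <- l2 + cam2$alpha[k] * (2 * A[, , k, 1])
    l2
  }, tolerance = 1e-12)
  # min-max normalization is idempotent
  h <- cam2$heatmap
  expect_equal((h - min(h)) / (max(h) - min(h)), h, tolerance = 1e-12)
  expect_gte(min(h), 0); expect_equal(max(h), 1)
})

test_that("explanations are post hoc: weights untouched; errors are informative", {
  m <- .toyModel()
  img <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  before <- m$params
  invisible(gradCAM(m, img, "EB2", classScoreSpec(1)))
  expect_identical(m$params, before)
  expect_error(gradCAM(m, img, "NOPE", classScoreSpec(1)), "EB1")
  # an all-false ROI yields zero gradient and a flagged all-zero map
  cam <- gradCAM(m, img, "DB1",
                 classScoreSpec(1, pixels = "roi",
                                roi = matrix(FALSE, 8, 8)))
  expect_true(cam$all_zero)
})

test_that("layer sweep covers all tags with correctly ordered resolutions", {
  m <- buildModel(tinyModelConfig(), seed = 15)
  set.seed(16)
  img <- array(rnorm(96 * 96 * 4), dim = c(96, 96, 4))
  sw <- layerSweep(m, img, spec = classScoreSpec(2, pixels = "all"))
  expect_length(sw, 10)
  expect_named(sw, c(paste0("EB", 1:4), "BOT", paste0("DB", 1:4), "OUT"))
  for (s in sw) {
    expect_equal(dim(s$heatmap), c(96, 96))
    expect_true(all(s$heatmap >= 0 & s$heatmap <= 1))
  }
  enc_res <- vapply(sw[paste0("EB", 1:4)], function(s) nrow(s$raw), 0)
  dec_res <- vapply(sw[paste0("DB", 1:4)], function(s) nrow(s$raw), 0)
  expect_true(all(diff(enc_res) < 0))   # encoder grids get coarser
  expect_true(all(diff(dec_res) >= 0))  # decoder grids recover resolution
  expect_error(layerSweep(m, img, layers = c("EB1", "XX"),
                          spec = classScoreSpec(1)), "XX")
})

test_that("ablating an identically-zero channel changes nothing", {
  pc <- phantomCases()
  pp <- pc$cases[[1]]
  pp$x[, , , 1] <- 0   # kill T1 in the input itself
  m <- buildModel(tinyModelConfig(), seed = 17)
  full <- predictVolume(m, pp)
  noT1 <- predictVolume(m, pp, channel_mask = c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(labelArray(full$labels), labelArray(noT1$labels))
  expect_equal(full$probs, noT1$probs, tolerance = 1e-12)
})
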