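# Independent brute-force oracles for the losses, written as literal
# per-voxel loops over the defining sums.

.bruteGD <- function(s, y, eps = 1e-5) {
  C <- ncol(s)
  W <- numeric(C); num <- 0; den <- 0
  for (c in seq_len(C)) {
    ysum <- 0
    for (n in seq_len(nrow(s))) ysum <- ysum + y[n, c]
    W[c] <- if (ysum > 0) 1 / ysum^2 else 0
  }
  for (c in seq_len(C)) {
    inter <- 0; ys <- 0; ss <- 0
    for (n in seq_len(nrow(s))) {
      inter <- inter + y[n, c] * s[n, c]
      ys <- ys + y[n, c]; ss <- ss + s[n, c]
    }
    num <- num + W[c] * inter
    den <- den + W[c] * (ys + ss)
  }
  1 - (2 * num + eps) / (den + eps)
}

.bruteCE <- function(s, y, floor = 1e-7) {
  tot <- 0
  for (n in seq_len(nrow(s))) for (c in seq_len(ncol(s)))
    tot <- tot + y[n, c] * log(max(s[n, c], floor))
  -tot / nrow(s)
}

.randProbs <- function(n, C, seed) {
  set.seed(seed)
  s <- matrix(rexp(n * C), n, C)
  s / rowSums(s)
}

test_that("generalized dice matches the brute-force voxel loop", {
  # 2-class, 4-pixel toy: y = [A,A,B,B], s = hard [A,B,B,B]
  y <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  s <- rbind(c(1, 0), c(0, 1), c(0, 1), c(0, 1))
  got <- generalizedDiceLoss(s, y)
  expect_equal(got$loss, .bruteGD(s, y), tolerance = 1e-12)
  # uniform prediction on balanced 2-class targets: closed form
  su <- matrix(0.5, 4, 2)
  # W = 1/4 both; num = 2*(1/4*1 + 1/4*1); den = 1/4*(2+2)*2
  closed <- 1 - (2 * (0.25 + 0.25) + 1e-5) / (0.25 * 4 * 2 + 1e-5)
  expect_equal(generalizedDiceLoss(su, y)$loss, closed, tolerance = 1e-12)
  # perfect prediction: loss vanishes up to epsilon
  expect_lt(generalizedDiceLoss(y, y)$loss, 1e-6)
  # random toys
  for (seed in 1:5) {
    s <- .randProbs(32, 4, seed)
    yc <- max.col(.randProbs(32, 4, seed + 100))
    y <- matrix(0, 32, 4); y[cbind(1:32, yc)] <- 1
    expect_equal(generalizedDiceLoss(s, y)$loss, .bruteGD(s, y),
                 tolerance = 1e-7)
  }
})

test_that("cross-entropy matches closed forms and the per-pixel loop", {
  y <- matrix(0, 8, 4); y[cbind(1:8, sample(1:4, 8, TRUE))] <- 1
  su <- matrix(0.25, 8, 4)
  expect_equal(categoricalCrossEntropy(su, y)$loss, log(4),
               tolerance = 1e-12)
  expect_lt(categoricalCrossEntropy(y, y)$loss, 1e-5)
  for (seed in 6:10) {
    s <- .randProbs(64, 4, seed)
    yc <- max.col(.randProbs(64, 4, seed + 100))
    y <- matrix(0, 64, 4); y[cbind(1:64, yc)] <- 1
    expect_equal(categoricalCrossEntropy(s, y)$loss, .bruteCE(s, y),
                 tolerance = 1e-7)
  }
})

test_that("overall loss is the exact sum and its gradient is finite", {
  s <- .randProbs(40, 4, 3)
  yc <- max.col(.randProbs(40, 4, 303))
  y <- matrix(0, 40, 4); y[cbind(1:40, yc)] <- 1
  lo <- overallLoss(s, y, grad = TRUE)
  expect_identical(lo$L_Overall, lo$L_GD + lo$L_CE)
  expect_true(all(is.finite(lo$ds)))
  expect_true(all(is.finite(lo$dlogits)))
  expect_lt(overallLoss(y, y)$L_Overall, 1e-5)
})

test_that("losses are invariant to voxel permutation and monotone toward truth", {
  s <- .randProbs(30, 4, 4)
  yc <- max.col(.randProbs(30, 4, 404))
  y <- matrix(0, 30, 4); y[cbind(1:30, yc)] <- 1
  perm <- sample(30)
  expect_equal(generalizedDiceLoss(s, y)$loss,
               generalizedDiceLoss(s[perm, ], y[perm, ])$loss,
               tolerance = 1e-12)
  expect_equal(categoricalCrossEntropy(s, y)$loss,
               categoricalCrossEntropy(s[perm, ], y[perm, ])$loss,
               tolerance = 1e-12)
  # moving linearly from uniform toward the one-hot target decreases L_GD
  su <- matrix(0.25, 30, 4)
  ts <- seq(0, 1, by = 0.2)
  vals <- vapply(ts, function(t)
    generalizedDiceLoss((1 - t) * su + t * y, y)$loss, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("dice coefficient handles the defining cases and is symmetric", {
  a <- array(0, dim = c(4, 4, 1)); b <- a
  a[1:2, 1, 1] <- 1
  expect_equal(diceCoefficient(a, a), 1)
  b[3:4, 4, 1] <- 1
  expect_equal(diceCoefficient(a, b), 0)
  expect_equal(diceCoefficient(array(0, dim = c(2, 2, 1)),
                               array(0, dim = c(2, 2, 1))), 1)
  p <- array(0, dim = c(10, 1, 1)); t <- p
  p[1:4, 1, 1] <- 1; t[2:7, 1, 1] <- 1   # |P|=4 |T|=6 |inter|=3
  expect_equal(diceCoefficient(p, t), 0.6)
  expect_equal(diceCoefficient(t, p), 0.6)
})

test_that("HD95 matches the exhaustive oracle and honors sentinels", {
  a <- array(0, dim = c(8, 8, 8)); a[4, 4, 4] <- 1
  b <- array(0, dim = c(8, 8, 8)); b[4, 7, 4] <- 1
  expect_equal(hausdorff95(a, b), 3.0)
  expect_equal(hausdorff95(a, a), 0)
  expect_equal(hausdorff95(a, b), hausdorff95(b, a))
  set.seed(21)
  for (i in 1:4) {
    a <- array(runif(16^3) < 0.1, dim = c(16, 16, 16))
    b <- array(runif(16^3) < 0.1, dim = c(16, 16, 16))
    sp <- c(1, 1.5, 2)
    expect_equal(hausdorff95(a, b, sp), .bruteHD95(a, b, sp),
                 tolerance = 1e-9)
  }
  empty <- array(FALSE, dim = c(16, 16, 16))
  expect_equal(hausdorff95(empty, empty), 0)
  expect_equal(hausdorff95(a, empty, sp), sqrt(sum((c(16, 16, 16) * sp)^2)))
  expect_equal(hausdorff95(a, empty, empty_sentinel = 99), 99)
})

test_that("region reports carry DSC and HD95 for ET, TC and WT", {
  cs <- generatePhantomCase(phantomSpec(seed = 17))
  ev <- evaluateRegions(cs$labels, cs$labels)
  expect_equal(ev$dsc, rep(1, 3))
  expect_equal(ev$hd95, rep(0, 3))
  expect_equal(ev$region, c("ET", "TC", "WT"))
})
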