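# Independent oracles shared across test files.

# classic binary STAPLE EM transcribed directly from the defining
# equations (same init and epsilon placement as the implementation)
.oracleEM <- function(D, prior, iters, p0 = 0.99999, q0 = 0.99999) {
  K <- ncol(D)
  p <- rep(p0, K); q <- rep(q0, K)
  eps <- 1e-12
  Wv <- NULL
  for (it in seq_len(iters)) {
    a <- rep(prior + eps, nrow(D))
    b <- rep(1 - prior + eps, nrow(D))
    for (i in seq_len(nrow(D))) for (k in seq_len(K)) {
      if (D[i, k] == 1) {
        a[i] <- a[i] * (p[k] + eps)
        b[i] <- b[i] * (1 - q[k] + eps)
      } else {
        a[i] <- a[i] * (1 - p[k] + eps)
        b[i] <- b[i] * (q[k] + eps)
      }
    }
    Wv <- a / (a + b)
    for (k in seq_len(K)) {
      p[k] <- sum(Wv * D[, k]) / sum(Wv)
      q[k] <- sum((1 - Wv) * (1 - D[, k])) / sum(1 - Wv)
    }
  }
  list(W = Wv, p = p, q = q)
}

# exhaustive all-pairs surface-distance HD95
.bruteHD95 <- function(a, b, spacing) {
  sa <- surfaceVoxels(a); sb <- surfaceVoxels(b)
  am <- sweep(sa, 2, spacing, `*`); bm <- sweep(sb, 2, spacing, `*`)
  dab <- apply(am, 1, function(v) min(sqrt(colSums((t(bm) - v)^2))))
  dba <- apply(bm, 1, function(v) min(sqrt(colSums((t(am) - v)^2))))
  as.numeric(quantile(c(dab, dba), 0.95))
}

# small fixed-weight conv net for explanation-generator oracles
.toyModel <- function(seed = 11) {
  cfg <- modelConfig(in_channels = 4L, num_classes = 4L, base_filters = 2L,
                     encoder_levels = 2L, input_size = c(8L, 8L),
                     num_blocks = 0L)
  buildModel(cfg, seed = seed)
}
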