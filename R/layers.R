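# Low-level differentiable layer primitives. Feature tensors are numeric
# arrays [H, W, C, N]; every *Forward returns the caches its *Backward
# needs. The heavy lifting (convolutions, pooling, batch norm, softmax)
# happens in the compiled kernels.

reluForward <- function(x) {
  out <- cpp_relu(x)
  list(out = out)
}

reluBackward <- function(dout, out) {
  cpp_relu_bw(dout, out)
}

# --- batch normalization (per channel over H, W, N) -----------------------

bnForward <- function(x, gamma, beta, state, training, momentum = 0.1,
                      eps = 1e-5) {
  if (training) {
    st <- cpp_channel_stats(x, dim(x))
    mu <- st$mean
    v <- st$var
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  out <- cpp_bn_apply(x, dim(x), mu, invstd, gamma, beta)
  list(out = out, state = state,
       cache = list(x = x, mean = mu, invstd = invstd,
                    training = training))
}

bnBackward <- function(dout, gamma, cache) {
  r <- cpp_bn_bw(cache$x, dim(cache$x), cache$mean, cache$invstd, gamma,
                 dout, cache$training)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# --- conv block: [conv3x3 -> BN -> ReLU] x2 -------------------------------

convBlockForward <- function(params, bn, prefix, x, training,
                             momentum = 0.1, eps = 1e-5) {
  p <- function(nm) params[[paste0(prefix, ".", nm)]]
  z1 <- cpp_conv2d_fw(x, dim(x), p("c1.W"), dim(p("c1.W")), p("c1.b"))
  b1 <- bnForward(z1, p("bn1.gamma"), p("bn1.beta"),
                  bn[[paste0(prefix, ".bn1")]], training, momentum, eps)
  r1 <- reluForward(b1$out)
  z2 <- cpp_conv2d_fw(r1$out, dim(r1$out), p("c2.W"), dim(p("c2.W")),
                      p("c2.b"))
  b2 <- bnForward(z2, p("bn2.gamma"), p("bn2.beta"),
                  bn[[paste0(prefix, ".bn2")]], training, momentum, eps)
  r2 <- reluForward(b2$out)
  bn[[paste0(prefix, ".bn1")]] <- b1$state
  bn[[paste0(prefix, ".bn2")]] <- b2$state
  list(out = r2$out, bn = bn,
       cache = list(x = x, a1 = r1$out, a2 = r2$out, bn1 = b1$cache,
                    bn2 = b2$cache))
}

convBlockBackward <- function(params, prefix, dout, cache, grads) {
  p <- function(nm) params[[paste0(prefix, ".", nm)]]
  g <- function(nm, v) {
    key <- paste0(prefix, ".", nm)
    grads[[key]] <<- if (is.null(grads[[key]])) v else grads[[key]] + v
  }
  d2 <- reluBackward(dout, cache$a2)
  bb2 <- bnBackward(d2, p("bn2.gamma"), cache$bn2)
  g("bn2.gamma", bb2$dgamma); g("bn2.beta", bb2$dbeta)
  cb2 <- cpp_conv2d_bw(cache$a1, dim(cache$a1), p("c2.W"), dim(p("c2.W")),
                       bb2$dx)
  g("c2.W", cb2$dW); g("c2.b", cb2$db)
  d1 <- reluBackward(cb2$dx, cache$a1)
  bb1 <- bnBackward(d1, p("bn1.gamma"), cache$bn1)
  g("bn1.gamma", bb1$dgamma); g("bn1.beta", bb1$dbeta)
  cb1 <- cpp_conv2d_bw(cache$x, dim(cache$x), p("c1.W"), dim(p("c1.W")),
                       bb1$dx)
  g("c1.W", cb1$dW); g("c1.b", cb1$db)
  list(dx = cb1$dx, grads = grads)
}

# --- channel concat / split ----------------------------------------------

channelConcat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

channelSplit <- function(d, c1) {
  list(a = d[, , seq_len(c1), , drop = FALSE],
       b = d[, , -seq_len(c1), , drop = FALSE])
}
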