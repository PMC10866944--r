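# Vision-transformer bottleneck: pre-norm residual blocks
#   z' = MSA(LN(z)) + z ;  z_l = MLP(LN(z')) + z'
# operating on token matrices [T, D] (one per batch sample).

lnForward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, invstd = invstd))
}

lnBackward <- function(dout, gamma, cache) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, `*`)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

geluForward <- function(x) {
  ph <- pnorm(x)
  list(out = x * ph, cache = list(x = x, ph = ph))
}

geluBackward <- function(dout, cache) {
  dout * (cache$ph + cache$x * dnorm(cache$x))
}

.rowSoftmax <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

msaForward <- function(z, p, prefix, num_heads) {
  pn <- function(nm) p[[paste0(prefix, ".", nm)]]
  D <- ncol(z)
  dh <- D / num_heads
  Q <- sweep(z %*% pn("Wq"), 2, pn("bq"), `+`)
  K <- sweep(z %*% pn("Wk"), 2, pn("bk"), `+`)
  V <- sweep(z %*% pn("Wv"), 2, pn("bv"), `+`)
  O <- matrix(0, nrow(z), D)
  heads <- vector("list", num_heads)
  for (h in seq_len(num_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    A <- .rowSoftmax(S)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[h]] <- A
  }
  out <- sweep(O %*% pn("Wo"), 2, pn("bo"), `+`)
  list(out = out, cache = list(z = z, Q = Q, K = K, V = V, O = O,
                               heads = heads, dh = dh))
}

msaBackward <- function(dout, p, prefix, cache, grads, num_heads) {
  pn <- function(nm) p[[paste0(prefix, ".", nm)]]
  acc <- function(nm, v) {
    key <- paste0(prefix, ".", nm)
    grads[[key]] <<- if (is.null(grads[[key]])) v else grads[[key]] + v
  }
  dh <- cache$dh
  acc("Wo", t(cache$O) %*% dout)
  acc("bo", colSums(dout))
  dO <- dout %*% t(pn("Wo"))
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ; dV <- dQ
  for (h in seq_len(num_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$heads[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / sqrt(dh)
    dK[, cols] <- (t(dS) %*% cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  acc("Wq", t(cache$z) %*% dQ); acc("bq", colSums(dQ))
  acc("Wk", t(cache$z) %*% dK); acc("bk", colSums(dK))
  acc("Wv", t(cache$z) %*% dV); acc("bv", colSums(dV))
  dz <- dQ %*% t(pn("Wq")) + dK %*% t(pn("Wk")) + dV %*% t(pn("Wv"))
  list(dz = dz, grads = grads)
}

#' One pre-norm transformer block applied to a token matrix
#'
#' @param z token matrix [T, D]
#' @param params flat parameter list of the model
#' @param prefix parameter prefix, e.g. "TB1"
#' @param num_heads number of attention heads (D must be divisible)
#' @return list with \code{out} [T, D] and backward \code{cache}
#' @export
transformerBlockForward <- function(z, params, prefix, num_heads) {
  l1 <- lnForward(z, params[[paste0(prefix, ".ln1.gamma")]],
                  params[[paste0(prefix, ".ln1.beta")]])
  at <- msaForward(l1$out, params, prefix, num_heads)
  zp <- at$out + z
  l2 <- lnForward(zp, params[[paste0(prefix, ".ln2.gamma")]],
                  params[[paste0(prefix, ".ln2.beta")]])
  h1 <- sweep(l2$out %*% params[[paste0(prefix, ".W1")]], 2,
              params[[paste0(prefix, ".b1")]], `+`)
  gl <- geluForward(h1)
  mout <- sweep(gl$out %*% params[[paste0(prefix, ".W2")]], 2,
                params[[paste0(prefix, ".b2")]], `+`)
  out <- mout + zp
  list(out = out,
       cache = list(ln1 = l1$cache, msa = at$cache, ln2 = l2$cache,
                    gelu = gl$cache, gout = gl$out, l2out = l2$out,
                    zp = zp))
}

#' Backward pass of \code{\link{transformerBlockForward}}
#'
#' @param dout upstream gradient [T, D]
#' @param params flat parameter list
#' @param prefix parameter prefix
#' @param cache forward cache
#' @param grads accumulator list of gradients
#' @param num_heads number of heads
#' @return list with \code{dz} and updated \code{grads}
#' @export
transformerBlockBackward <- function(dout, params, prefix, cache, grads,
                                     num_heads) {
  acc <- function(nm, v) {
    key <- paste0(prefix, ".", nm)
    grads[[key]] <<- if (is.null(grads[[key]])) v else grads[[key]] + v
  }
  # z_l = zp + MLP(LN2(zp))
  dmout <- dout
  acc("W2", t(cache$gout) %*% dmout)
  acc("b2", colSums(dmout))
  dG <- dmout %*% t(params[[paste0(prefix, ".W2")]])
  dh1 <- geluBackward(dG, cache$gelu)
  acc("W1", t(cache$l2out) %*% dh1)
  acc("b1", colSums(dh1))
  dl2 <- dh1 %*% t(params[[paste0(prefix, ".W1")]])
  lb2 <- lnBackward(dl2, params[[paste0(prefix, ".ln2.gamma")]], cache$ln2)
  acc("ln2.gamma", lb2$dgamma); acc("ln2.beta", lb2$dbeta)
  dzp <- dout + lb2$dx
  # zp = z + MSA(LN1(z))
  mb <- msaBackward(dzp, params, prefix, cache$msa, grads, num_heads)
  grads <- mb$grads
  lb1 <- lnBackward(mb$dz, params[[paste0(prefix, ".ln1.gamma")]],
                    cache$ln1)
  acc("ln1.gamma", lb1$dgamma); acc("ln1.beta", lb1$dbeta)
  dz <- dzp + lb1$dx
  list(dz = dz, grads = grads)
}
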