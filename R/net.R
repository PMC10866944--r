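#' Model configuration for the hybrid CNN-Transformer segmentation network
#'
#' The network is a U-shaped conv encoder-decoder with a vision-transformer
#' bottleneck: \code{encoder_levels} double-conv blocks (channel widths
#' \code{base_filters * 2^level}) separated by 2x2 max-pooling, a token
#' embedding of the bottleneck features (patch size P, learned positional
#' embeddings), \code{num_blocks} pre-norm transformer blocks, a feature
#' restoration (reshape + 1x1 conv), and a symmetric decoder of 2x2
#' transposed convolutions with encoder skip concatenation, ending in a
#' 1x1 conv to \code{num_classes} with per-pixel softmax.
#'
#' @param in_channels input channels (4 modalities)
#' @param num_classes output classes (background + 3 tumor tissues)
#' @param base_filters width K of the first encoder level (default 32)
#' @param encoder_levels number of encoder blocks (default 4, i.e. 3
#'   poolings and an H/8 bottleneck)
#' @param input_size in-plane H x W (must be divisible by
#'   \code{2^(encoder_levels-1) * patch_size})
#' @param num_blocks transformer depth L
#' @param num_heads attention heads
#' @param embed_dim token dimension
#' @param mlp_dim hidden width of the transformer MLP
#' @param patch_size P; each P x P patch of bottleneck features is a token
#' @param bn_momentum running-statistics update rate
#' @param bn_eps,ln_eps normalization epsilons
#' @return a \code{modelConfig} list
#' @export
modelConfig <- function(in_channels = 4L, num_classes = 4L,
                        base_filters = 32L, encoder_levels = 4L,
                        input_size = c(192L, 192L),
                        num_blocks = 4L, num_heads = 8L,
                        embed_dim = 256L, mlp_dim = 1024L,
                        patch_size = 1L,
                        bn_momentum = 0.1, bn_eps = 1e-5, ln_eps = 1e-5) {
  stopifnot(base_filters >= 1, encoder_levels >= 1, num_blocks >= 0,
            embed_dim %% num_heads == 0)
  div <- 2^(encoder_levels - 1) * patch_size
  if (any(input_size %% div != 0))
    stop(sprintf("input_size must be divisible by %d", div))
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_filters = as.integer(base_filters),
                 encoder_levels = as.integer(encoder_levels),
                 input_size = as.integer(input_size),
                 num_blocks = as.integer(num_blocks),
                 num_heads = as.integer(num_heads),
                 embed_dim = as.integer(embed_dim),
                 mlp_dim = as.integer(mlp_dim),
                 patch_size = as.integer(patch_size),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 ln_eps = ln_eps),
            class = "modelConfig")
}

.heConv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

.truncNormal <- function(n, sd = 0.02) pmin(pmax(rnorm(n, 0, sd), -2 * sd), 2 * sd)

.levelWidth <- function(cfg, level) cfg$base_filters * 2^(level - 1)

#' Build and initialize the segmentation network
#'
#' Weight initialization: He-normal for convolutions, truncated normal
#' (sd 0.02) for transformer projections and positional embeddings, unit
#' gamma / zero beta for the normalization layers.
#'
#' @param cfg a \code{\link{modelConfig}}
#' @param seed integer seed for the initialization
#' @return a model list with \code{params}, \code{bn} (running stats),
#'   \code{cfg} and \code{tags}
#' @export
buildModel <- function(cfg, seed = 1L) {
  withSeed(seed, {
    p <- list()
    bn <- list()
    L <- cfg$encoder_levels
    addBlock <- function(prefix, cin, cout) {
      p[[paste0(prefix, ".c1.W")]] <<- .heConv(3, cin, cout)
      p[[paste0(prefix, ".c1.b")]] <<- numeric(cout)
      p[[paste0(prefix, ".bn1.gamma")]] <<- rep(1, cout)
      p[[paste0(prefix, ".bn1.beta")]] <<- numeric(cout)
      p[[paste0(prefix, ".c2.W")]] <<- .heConv(3, cout, cout)
      p[[paste0(prefix, ".c2.b")]] <<- numeric(cout)
      p[[paste0(prefix, ".bn2.gamma")]] <<- rep(1, cout)
      p[[paste0(prefix, ".bn2.beta")]] <<- numeric(cout)
      bn[[paste0(prefix, ".bn1")]] <<- list(mean = numeric(cout),
                                            var = rep(1, cout))
      bn[[paste0(prefix, ".bn2")]] <<- list(mean = numeric(cout),
                                            var = rep(1, cout))
    }
    cin <- cfg$in_channels
    for (l in seq_len(L)) {
      addBlock(sprintf("EB%d", l), cin, .levelWidth(cfg, l))
      cin <- .levelWidth(cfg, l)
    }
    cbot <- .levelWidth(cfg, L)
    hb <- cfg$input_size[1] / 2^(L - 1)
    wb <- cfg$input_size[2] / 2^(L - 1)
    if (cfg$num_blocks > 0) {
      P <- cfg$patch_size
      D <- cfg$embed_dim
      Tn <- (hb / P) * (wb / P)
      p[["PE.W"]] <- matrix(.truncNormal(P * P * cbot * D), P * P * cbot, D)
      p[["PE.b"]] <- numeric(D)
      p[["PE.pos"]] <- matrix(.truncNormal(Tn * D), Tn, D)
      for (l in seq_len(cfg$num_blocks)) {
        pre <- sprintf("TB%d", l)
        p[[paste0(pre, ".ln1.gamma")]] <- rep(1, D)
        p[[paste0(pre, ".ln1.beta")]] <- numeric(D)
        for (nm in c("Wq", "Wk", "Wv", "Wo"))
          p[[paste0(pre, ".", nm)]] <- matrix(.truncNormal(D * D), D, D)
        for (nm in c("bq", "bk", "bv", "bo"))
          p[[paste0(pre, ".", nm)]] <- numeric(D)
        p[[paste0(pre, ".ln2.gamma")]] <- rep(1, D)
        p[[paste0(pre, ".ln2.beta")]] <- numeric(D)
        p[[paste0(pre, ".W1")]] <- matrix(.truncNormal(D * cfg$mlp_dim),
                                          D, cfg$mlp_dim)
        p[[paste0(pre, ".b1")]] <- numeric(cfg$mlp_dim)
        p[[paste0(pre, ".W2")]] <- matrix(.truncNormal(cfg$mlp_dim * D),
                                          cfg$mlp_dim, D)
        p[[paste0(pre, ".b2")]] <- numeric(D)
      }
      p[["RST.W"]] <- .heConv(1, D, cbot)
      p[["RST.b"]] <- numeric(cbot)
    }
    # decoder: DB1 at bottleneck resolution, then one up stage per level
    addBlock("DB1", cbot, cbot)
    if (L > 1) {
      for (j in 2:L) {
        lev <- L - j + 1                      # encoder level whose skip is used
        cup_in <- .levelWidth(cfg, lev + 1)
        cup_out <- .levelWidth(cfg, lev)
        p[[sprintf("UP%d.W", j)]] <- array(
          rnorm(4 * cup_in * cup_out, 0, sqrt(2 / (4 * cup_in))),
          dim = c(2, 2, cup_in, cup_out))
        p[[sprintf("UP%d.b", j)]] <- numeric(cup_out)
        addBlock(sprintf("DB%d", j), 2 * cup_out, cup_out)
      }
    }
    # small-scale head init: logits start near zero, so the initial
    # prediction is near-uniform and the loss starts near its
    # random-prediction value
    p[["OUT.W"]] <- array(.truncNormal(cfg$base_filters * cfg$num_classes,
                                       0.01),
                          dim = c(1, 1, cfg$base_filters, cfg$num_classes))
    p[["OUT.b"]] <- numeric(cfg$num_classes)
    tags <- c(sprintf("EB%d", seq_len(L)),
              if (cfg$num_blocks > 0) "BOT",
              sprintf("DB%d", seq_len(L)), "OUT")
    list(params = p, bn = bn, cfg = cfg, tags = tags)
  })
}

#' Number of trainable parameters
#' @param model a model from \code{\link{buildModel}}
#' @return integer count
#' @export
parameterCount <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' Embed bottleneck features as a token sequence
#'
#' Splits an [h, w, C] feature map into P x P patches (row index fastest),
#' projects each flattened patch with a learned linear map and adds the
#' learned positional embedding.
#'
#' @param feat array [h, w, C]
#' @param W projection matrix [P^2 C, D]
#' @param b bias length D
#' @param pos positional embeddings [T, D] (or NULL to omit)
#' @param P patch size
#' @return token matrix [T, D] with T = (h/P)(w/P)
#' @export
patchEmbed <- function(feat, W, b, pos = NULL, P = 1L) {
  d <- dim(feat)
  stopifnot(d[1] %% P == 0, d[2] %% P == 0)
  X <- .im2patch(feat, P)
  z <- sweep(X %*% W, 2, b, `+`)
  if (!is.null(pos)) z <- z + pos
  z
}

.im2patch <- function(feat, P) {
  d <- dim(feat)
  hp <- d[1] / P; wp <- d[2] / P
  if (P == 1L) {
    X <- feat
    dim(X) <- c(d[1] * d[2], d[3])
    return(X)
  }
  X <- matrix(0, hp * wp, P * P * d[3])
  for (j in seq_len(wp)) for (i in seq_len(hp)) {
    patch <- feat[((i - 1) * P + 1):(i * P), ((j - 1) * P + 1):(j * P), ,
                  drop = FALSE]
    X[i + (j - 1) * hp, ] <- as.vector(patch)
  }
  X
}

.patch2im <- function(X, hp, wp, P, C) {
  if (P == 1L) {
    out <- X
    dim(out) <- c(hp, wp, C)
    return(out)
  }
  out <- array(0, dim = c(hp * P, wp * P, C))
  for (j in seq_len(wp)) for (i in seq_len(hp)) {
    out[((i - 1) * P + 1):(i * P), ((j - 1) * P + 1):(j * P), ] <-
      array(X[i + (j - 1) * hp, ], dim = c(P, P, C))
  }
  out
}

.softmax4 <- function(logits) {
  cpp_softmax(logits, dim(logits))
}

#' Forward pass of the segmentation network
#'
#' @param model model list from \code{\link{buildModel}}
#' @param x input batch [H, W, C_in, N]
#' @param training use batch statistics in BN and update running stats
#' @param keep_cache retain every intermediate needed for a backward pass
#' @param substitute optional named list \code{tag = activation}: the
#'   activation produced at that tag is replaced before the graph
#'   continues (used by explanation oracles)
#' @return list with \code{logits} [H, W, num_classes, N], \code{probs}
#'   (softmax), \code{acts} (activations at every tag), \code{bn}
#'   (possibly updated running stats) and \code{cache}
#' @export
netForward <- function(model, x, training = FALSE, keep_cache = FALSE,
                       substitute = NULL) {
  cfg <- model$cfg
  p <- model$params
  bn <- model$bn
  if (dim(x)[3] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels,
                 dim(x)[3]))
  L <- cfg$encoder_levels
  acts <- list()
  cache <- list()
  sub <- function(tag, a) {
    if (!is.null(substitute) && tag %in% names(substitute))
      substitute[[tag]] else a
  }
  h <- x
  skips <- list()
  for (l in seq_len(L)) {
    blk <- convBlockForward(p, bn, sprintf("EB%d", l), h, training,
                            cfg$bn_momentum, cfg$bn_eps)
    bn <- blk$bn
    a <- sub(sprintf("EB%d", l), blk$out)
    acts[[sprintf("EB%d", l)]] <- a
    if (keep_cache) cache[[sprintf("EB%d", l)]] <- blk$cache
    skips[[l]] <- a
    if (l < L) {
      mp <- cpp_maxpool_fw(a, dim(a))
      if (keep_cache) cache[[sprintf("pool%d", l)]] <- list(idx = mp$idx,
                                                            xdim = dim(a))
      h <- mp$out
    } else h <- a
  }
  # transformer bottleneck
  if (cfg$num_blocks > 0) {
    P <- cfg$patch_size
    D <- cfg$embed_dim
    dbot <- dim(h)
    hp <- dbot[1] / P; wp <- dbot[2] / P
    N <- dbot[4]
    rst <- array(0, dim = c(dbot[1], dbot[2], .levelWidth(cfg, L), N))
    tcache <- vector("list", N)
    for (n in seq_len(N)) {
      feat <- h[, , , n, drop = TRUE]
      dim(feat) <- dbot[1:3]
      Xp <- .im2patch(feat, P)
      z <- sweep(Xp %*% p[["PE.W"]], 2, p[["PE.b"]], `+`) + p[["PE.pos"]]
      bcaches <- vector("list", cfg$num_blocks)
      for (l in seq_len(cfg$num_blocks)) {
        tb <- transformerBlockForward(z, p, sprintf("TB%d", l),
                                      cfg$num_heads)
        bcaches[[l]] <- tb$cache
        z <- tb$out
      }
      grid <- .patch2im(z, hp, wp, 1L, D)      # [hp, wp, D]
      if (P > 1L) {
        # nearest upsampling back to the bottleneck grid
        grid <- grid[rep(seq_len(hp), each = P), rep(seq_len(wp), each = P),
                     , drop = FALSE]
      }
      dim(grid) <- c(dbot[1], dbot[2], D, 1L)
      r <- cpp_conv2d_fw(grid, dim(grid), p[["RST.W"]], dim(p[["RST.W"]]),
                         p[["RST.b"]])
      rst[, , , n] <- r
      if (keep_cache) tcache[[n]] <- list(Xp = Xp, blocks = bcaches,
                                          grid = grid)
    }
    if (keep_cache) cache$transformer <- list(per_sample = tcache,
                                              dbot = dbot, hp = hp, wp = wp)
    h <- sub("BOT", rst)
    acts[["BOT"]] <- h
  }
  # decoder
  blk <- convBlockForward(p, bn, "DB1", h, training, cfg$bn_momentum,
                          cfg$bn_eps)
  bn <- blk$bn
  h <- sub("DB1", blk$out)
  acts[["DB1"]] <- h
  if (keep_cache) cache[["DB1"]] <- blk$cache
  if (L > 1) {
    for (j in 2:L) {
      lev <- L - j + 1
      up <- cpp_convt2_fw(h, dim(h), p[[sprintf("UP%d.W", j)]],
                          p[[sprintf("UP%d.b", j)]])
      if (keep_cache) cache[[sprintf("upin%d", j)]] <- h
      skip <- skips[[lev]]
      if (!identical(dim(up)[1:2], dim(skip)[1:2]))
        stop("decoder/skip resolution mismatch")
      cat_in <- channelConcat(up, skip)
      if (keep_cache) cache[[sprintf("cat%d", j)]] <- dim(up)[3]
      blk <- convBlockForward(p, bn, sprintf("DB%d", j), cat_in, training,
                              cfg$bn_momentum, cfg$bn_eps)
      bn <- blk$bn
      h <- sub(sprintf("DB%d", j), blk$out)
      acts[[sprintf("DB%d", j)]] <- h
      if (keep_cache) {
        cache[[sprintf("DB%d", j)]] <- blk$cache
        cache[[sprintf("DB%din", j)]] <- cat_in
      }
    }
  }
  logits <- cpp_conv2d_fw(h, dim(h), p[["OUT.W"]], dim(p[["OUT.W"]]),
                          p[["OUT.b"]])
  logits <- sub("OUT", logits)
  acts[["OUT"]] <- logits
  if (keep_cache) cache$out_in <- h
  probs <- .softmax4(logits)
  list(logits = logits, probs = probs, acts = acts, bn = bn,
       cache = if (keep_cache) cache else NULL)
}

#' Backward pass of the segmentation network
#'
#' Backpropagates a gradient with respect to the logits through the whole
#' graph, accumulating parameter gradients and, when requested, the
#' gradients of the tagged intermediate activations (as needed by
#' Grad-CAM).
#'
#' @param model model list
#' @param fw result of \code{netForward(..., keep_cache = TRUE)}
#' @param dlogits gradient w.r.t. logits [H, W, num_classes, N]
#' @param want_tags character vector of tags whose activation gradients to
#'   record
#' @return list with \code{grads} (named like \code{model$params}),
#'   \code{dx} (gradient w.r.t. the input) and \code{tag_grads}
#' @export
netBackward <- function(model, fw, dlogits, want_tags = character(0)) {
  cfg <- model$cfg
  p <- model$params
  cache <- fw$cache
  stopifnot(!is.null(cache))
  L <- cfg$encoder_levels
  grads <- list()
  tag_grads <- list()
  keepTag <- function(tag, g) {
    if (tag %in% want_tags) tag_grads[[tag]] <<- g
  }
  keepTag("OUT", dlogits)
  cb <- cpp_conv2d_bw(cache$out_in, dim(cache$out_in), p[["OUT.W"]],
                      dim(p[["OUT.W"]]), dlogits)
  grads[["OUT.W"]] <- cb$dW; grads[["OUT.b"]] <- cb$db
  dh <- cb$dx
  dskips <- vector("list", L)
  if (L > 1) {
    for (j in L:2) {
      lev <- L - j + 1
      keepTag(sprintf("DB%d", j), dh)
      bb <- convBlockBackward(p, sprintf("DB%d", j), dh,
                              cache[[sprintf("DB%d", j)]], grads)
      grads <- bb$grads
      sp <- channelSplit(bb$dx, cache[[sprintf("cat%d", j)]])
      dskips[[lev]] <- sp$b
      upin <- cache[[sprintf("upin%d", j)]]
      ub <- cpp_convt2_bw(upin, dim(upin), p[[sprintf("UP%d.W", j)]],
                          sp$a)
      grads[[sprintf("UP%d.W", j)]] <- ub$dW
      grads[[sprintf("UP%d.b", j)]] <- ub$db
      dh <- ub$dx
    }
  }
  keepTag("DB1", dh)
  bb <- convBlockBackward(p, "DB1", dh, cache[["DB1"]], grads)
  grads <- bb$grads
  dh <- bb$dx
  if (cfg$num_blocks > 0) {
    keepTag("BOT", dh)
    tc <- cache$transformer
    dbot <- tc$dbot
    D <- cfg$embed_dim
    P <- cfg$patch_size
    N <- dbot[4]
    dfeat <- array(0, dim = dbot)
    for (n in seq_len(N)) {
      per <- tc$per_sample[[n]]
      dr <- dh[, , , n, drop = FALSE]
      rb <- cpp_conv2d_bw(per$grid, dim(per$grid), p[["RST.W"]],
                          dim(p[["RST.W"]]), dr)
      grads[["RST.W"]] <- if (is.null(grads[["RST.W"]])) rb$dW else
        grads[["RST.W"]] + rb$dW
      grads[["RST.b"]] <- if (is.null(grads[["RST.b"]])) rb$db else
        grads[["RST.b"]] + rb$db
      dgrid <- rb$dx
      dim(dgrid) <- c(dbot[1], dbot[2], D)
      if (P > 1L) {
        # sum-pool the nearest-upsample gradient back to the token grid
        dg <- array(0, dim = c(tc$hp, tc$wp, D))
        for (di in seq_len(P)) for (dj in seq_len(P)) {
          dg <- dg + dgrid[seq(di, by = P, length.out = tc$hp),
                           seq(dj, by = P, length.out = tc$wp), ,
                           drop = FALSE]
        }
        dgrid <- dg
      }
      dz <- dgrid
      dim(dz) <- c(tc$hp * tc$wp, D)
      for (l in rev(seq_len(cfg$num_blocks))) {
        tb <- transformerBlockBackward(dz, p, sprintf("TB%d", l),
                                       per$blocks[[l]], grads,
                                       cfg$num_heads)
        grads <- tb$grads
        dz <- tb$dz
      }
      accg <- function(nm, v) {
        grads[[nm]] <<- if (is.null(grads[[nm]])) v else grads[[nm]] + v
      }
      accg("PE.pos", dz)
      accg("PE.W", t(per$Xp) %*% dz)
      accg("PE.b", colSums(dz))
      dXp <- dz %*% t(p[["PE.W"]])
      df <- .patch2im(dXp, dbot[1] / P, dbot[2] / P, P, dbot[3])
      dfeat[, , , n] <- df
    }
    dh <- dfeat
  }
  # encoder (reverse)
  for (l in L:1) {
    if (l < L) {
      pl <- cache[[sprintf("pool%d", l)]]
      dh <- cpp_maxpool_bw(pl$idx, dh, pl$xdim)
    }
    if (!is.null(dskips[[l]])) dh <- dh + dskips[[l]]
    keepTag(sprintf("EB%d", l), dh)
    bb <- convBlockBackward(p, sprintf("EB%d", l), dh,
                            cache[[sprintf("EB%d", l)]], grads)
    grads <- bb$grads
    dh <- bb$dx
  }
  list(grads = grads, dx = dh, tag_grads = tag_grads)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds parameters, BN running statistics and the model
#' configuration; save-load-predict round-trips give bit-identical logits
#' in eval mode.
#'
#' @param model model list
#' @param path file path (.rds)
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model$params, bn = model$bn, cfg = model$cfg,
               tags = model$tags), path)
  jsonlite::write_json(
    list(config = model$cfg[setdiff(names(model$cfg), NULL)],
         n_params = parameterCount(model),
         package_version = as.character(utils::packageVersion("gliomaseg"))),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  m <- readRDS(path)
  class(m$cfg) <- "modelConfig"
  m
}
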