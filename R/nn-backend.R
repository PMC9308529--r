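# A compact convolutional-network engine in base R, sufficient to train the
# width-reduced U-Net demo: stride-1 same-padded convolutions (im2col),
# 2x2 max-pooling, 2x2 stride-2 learned transposed convolutions, channel
# concatenation, inverted dropout, sigmoid output, soft-Dice loss and Adam.
# Tensors are (rows, cols, channels) arrays; forward passes return caches
# consumed by the matching backward passes. Correctness is established by
# finite-difference gradient checks in the test suite.

as3d <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- stride-1 convolution, square kernel, zero padding 'pad' ----

im2col <- function(x, k, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- H + 2 * pad - k + 1; Wo <- W + 2 * pad - k + 1
  if (pad > 0) {
    xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  cols <- matrix(0, Ho * Wo, k * k * C)
  idx <- 0L
  for (ci in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    cols[, idx] <- xp[di:(di + Ho - 1), dj:(dj + Wo - 1), ci]
  }
  cols
}

col2im <- function(dcols, dimx, k, pad) {
  H <- dimx[1]; W <- dimx[2]; C <- dimx[3]
  Ho <- H + 2 * pad - k + 1; Wo <- W + 2 * pad - k + 1
  dxp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  idx <- 0L
  for (ci in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- idx + 1L
    dxp[di:(di + Ho - 1), dj:(dj + Wo - 1), ci] <-
      dxp[di:(di + Ho - 1), dj:(dj + Wo - 1), ci] +
      matrix(dcols[, idx], Ho, Wo)
  }
  if (pad > 0) dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  else dxp
}

# W: (k, k, Cin, Cout) array; b: length-Cout; same padding for odd k
convForward <- function(x, W, b) {
  x <- as3d(x)
  k <- dim(W)[1]; pad <- (k - 1) %/% 2
  cols <- im2col(x, k, pad)
  Wmat <- matrix(W, ncol = dim(W)[4])
  y <- cols %*% Wmat
  y <- sweep(y, 2, b, `+`)
  out <- array(y, c(dim(x)[1], dim(x)[2], dim(W)[4]))
  list(out = out, cache = list(cols = cols, dimx = dim(x), W = W,
                               k = k, pad = pad))
}

convBackward <- function(dout, cache) {
  co <- dim(dout)[3]
  dY <- matrix(dout, ncol = co)
  Wmat <- matrix(cache$W, ncol = co)
  dW <- array(crossprod(cache$cols, dY), dim(cache$W))
  db <- colSums(dY)
  dx <- col2im(dY %*% t(Wmat), cache$dimx, cache$k, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(dout, cache) dout * cache

# 2x2 max pooling, stride 2; even input dims required
poolForward <- function(x) {
  d <- dim(x)
  o <- seq(1, d[1], 2); e <- o + 1
  p <- seq(1, d[2], 2); q <- p + 1
  a <- x[o, p, , drop = FALSE]; b <- x[o, q, , drop = FALSE]
  cc <- x[e, p, , drop = FALSE]; dd <- x[e, q, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  m1 <- a == y; m2 <- b == y & !m1
  m3 <- cc == y & !m1 & !m2; m4 <- dd == y & !m1 & !m2 & !m3
  list(out = y, cache = list(m = list(m1, m2, m3, m4), dimx = d))
}

poolBackward <- function(dout, cache) {
  d <- cache$dimx
  o <- seq(1, d[1], 2); e <- o + 1
  p <- seq(1, d[2], 2); q <- p + 1
  dx <- array(0, d)
  m <- cache$m
  dx[o, p, ] <- dout * m[[1]]; dx[o, q, ] <- dout * m[[2]]
  dx[e, p, ] <- dout * m[[3]]; dx[e, q, ] <- dout * m[[4]]
  dx
}

# 2x2 transposed convolution with stride 2 (non-overlapping tiles);
# W: (2, 2, Cin, Cout), b: length Cout
upconvForward <- function(x, W, b) {
  x <- as3d(x)
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[4]
  xm <- matrix(x, H * Wd, Cin)
  y <- array(0, c(2 * H, 2 * Wd, Cout))
  for (di in 1:2) for (dj in 1:2) {
    ym <- xm %*% matrix(W[di, dj, , ], Cin, Cout)
    ym <- sweep(ym, 2, b, `+`)
    y[seq(di, 2 * H, 2), seq(dj, 2 * Wd, 2), ] <- array(ym, c(H, Wd, Cout))
  }
  list(out = y, cache = list(xm = xm, dimx = d, W = W))
}

upconvBackward <- function(dout, cache) {
  W <- cache$W
  d <- cache$dimx; H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[4]
  dW <- array(0, dim(W)); db <- numeric(Cout)
  dxm <- matrix(0, H * Wd, Cin)
  for (di in 1:2) for (dj in 1:2) {
    dYm <- matrix(dout[seq(di, 2 * H, 2), seq(dj, 2 * Wd, 2), , drop = FALSE],
                  H * Wd, Cout)
    dW[di, dj, , ] <- crossprod(cache$xm, dYm)
    db <- db + colSums(dYm)
    dxm <- dxm + dYm %*% t(matrix(W[di, dj, , ], Cin, Cout))
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

concatChannels <- function(a, b) {
  a <- as3d(a); b <- as3d(b)
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  list(out = y, cache = c(da[3], db[3]))
}

splitChannels <- function(dout, cache) {
  list(da = dout[, , seq_len(cache[1]), drop = FALSE],
       db = dout[, , cache[1] + seq_len(cache[2]), drop = FALSE])
}

dropoutForward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- array((runif(length(x)) >= p) / (1 - p), dim(x))
  list(out = x * mask, cache = mask)
}

dropoutBackward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

sigmoidForward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = y)
}
sigmoidBackward <- function(dout, cache) dout * cache * (1 - cache)

# soft Dice loss and its gradient w.r.t. the prediction
diceLossGrad <- function(pred, truth, eps = 1) {
  num <- 2 * sum(pred * truth) + eps
  den <- sum(pred) + sum(truth) + eps
  list(loss = 1 - num / den,
       grad = array(-(2 * truth * den - num) / den^2, dim(as3d(pred))))
}

# ---- width-reduced U-Net: parameter init, forward, backward ----

# channels: the 5 encoder widths (e.g. c(4, 8, 16, 32, 64))
unetParamShapes <- function(channels) {
  ch <- channels
  shp <- list()
  cin <- 1
  for (b in 1:5) {
    shp[[paste0("c", b, "a")]] <- c(3, 3, cin, ch[b])
    shp[[paste0("c", b, "b")]] <- c(3, 3, ch[b], ch[b])
    cin <- ch[b]
  }
  for (s in 1:4) {
    b <- 5 - s
    shp[[paste0("u", 5 + s)]] <- c(2, 2, cin, ch[b])
    shp[[paste0("c", 5 + s, "a")]] <- c(3, 3, 2 * ch[b], ch[b])
    shp[[paste0("c", 5 + s, "b")]] <- c(3, 3, ch[b], ch[b])
    cin <- ch[b]
  }
  shp[["c10"]] <- c(1, 1, cin, 1)
  shp
}

initUnetParams <- function(channels, seed = 1, weight_init_sd = 0.01,
                           bias_init = 0) {
  shp <- unetParamShapes(channels)
  withSeed(seed, lapply(shp, function(s)
    list(W = array(rnorm(prod(s), 0, weight_init_sd), s),
         b = rep(bias_init, s[4]))))
}

convRelu <- function(x, p) {
  cv <- convForward(x, p$W, p$b)
  rl <- reluForward(cv$out)
  list(out = rl$out, conv = cv$cache, relu = rl$cache)
}

convReluBack <- function(dout, cache) {
  cb <- convBackward(reluBackward(dout, cache$relu), cache$conv)
  cb
}

# forward pass; training=TRUE engages dropout (uses the current RNG stream)
unetForward <- function(x, params, training = FALSE, dropout_p = 0.5) {
  cc <- list()
  h <- as3d(x)
  enc <- list()
  for (b in 1:5) {
    a <- convRelu(h, params[[paste0("c", b, "a")]])
    bb <- convRelu(a$out, params[[paste0("c", b, "b")]])
    cc[[paste0("c", b, "a")]] <- a; cc[[paste0("c", b, "b")]] <- bb
    h <- bb$out
    if (b %in% c(4, 5)) {
      dr <- dropoutForward(h, dropout_p, training)
      cc[[paste0("drop", b)]] <- dr$cache
      h <- dr$out
    }
    enc[[b]] <- h                     # post-dropout at levels 4 and 5
    if (b < 5) {
      pl <- poolForward(h)
      cc[[paste0("pool", b)]] <- pl$cache
      h <- pl$out
    }
  }
  for (s in 1:4) {
    b <- 5 - s
    up <- upconvForward(h, params[[paste0("u", 5 + s)]]$W,
                        params[[paste0("u", 5 + s)]]$b)
    ur <- reluForward(up$out)
    cn <- concatChannels(enc[[b]], ur$out)
    a <- convRelu(cn$out, params[[paste0("c", 5 + s, "a")]])
    bb <- convRelu(a$out, params[[paste0("c", 5 + s, "b")]])
    cc[[paste0("u", 5 + s)]] <- list(up = up$cache, relu = ur$cache,
                                     concat = cn$cache)
    cc[[paste0("c", 5 + s, "a")]] <- a; cc[[paste0("c", 5 + s, "b")]] <- bb
    h <- bb$out
  }
  out <- convForward(h, params$c10$W, params$c10$b)
  sg <- sigmoidForward(out$out)
  cc$c10 <- out$cache; cc$sig <- sg$cache
  list(pred = sg$out[, , 1], cache = cc)
}

# backward pass from dPred (gradient of the loss w.r.t. the sigmoid output)
unetBackward <- function(dPred, cache, params) {
  g <- list()
  d <- sigmoidBackward(as3d(dPred), cache$sig)
  cb <- convBackward(d, cache$c10)
  g$c10 <- list(W = cb$dW, b = cb$db)
  d <- cb$dx
  dskip <- vector("list", 5)          # gradients flowing into encoder outputs
  for (s in 4:1) {
    b <- 5 - s
    bb <- convReluBack(d, cache[[paste0("c", 5 + s, "b")]])
    g[[paste0("c", 5 + s, "b")]] <- list(W = bb$dW, b = bb$db)
    aa <- convReluBack(bb$dx, cache[[paste0("c", 5 + s, "a")]])
    g[[paste0("c", 5 + s, "a")]] <- list(W = aa$dW, b = aa$db)
    uc <- cache[[paste0("u", 5 + s)]]
    sp <- splitChannels(aa$dx, uc$concat)
    dskip[[b]] <- sp$da
    ub <- upconvBackward(reluBackward(sp$db, uc$relu), uc$up)
    g[[paste0("u", 5 + s)]] <- list(W = ub$dW, b = ub$db)
    d <- ub$dx
  }
  for (b in 5:1) {
    if (b < 5) {
      d <- poolBackward(d, cache[[paste0("pool", b)]])
      if (!is.null(dskip[[b]])) d <- d + dskip[[b]]
    } else if (!is.null(dskip[[b]])) d <- d + dskip[[b]]
    if (b %in% c(4, 5))
      d <- dropoutBackward(d, cache[[paste0("drop", b)]])
    bb <- convReluBack(d, cache[[paste0("c", b, "b")]])
    g[[paste0("c", b, "b")]] <- list(W = bb$dW, b = bb$db)
    aa <- convReluBack(bb$dx, cache[[paste0("c", b, "a")]])
    g[[paste0("c", b, "a")]] <- list(W = aa$dW, b = aa$db)
    d <- aa$dx
  }
  g
}

# in-place-style Adam update; state holds first/second moments and step count
adamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) list(W = array(0, dim(p$W)),
                                           b = numeric(length(p$b)))),
       v = lapply(params, function(p) list(W = array(0, dim(p$W)),
                                           b = numeric(length(p$b)))))
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (fld in c("W", "b")) {
      gg <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * gg
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] +
        (1 - beta2) * gg^2
      mh <- state$m[[nm]][[fld]] / bc1
      vh <- state$v[[nm]][[fld]] / bc2
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}

# forward + loss + full gradient for one image (used by training and by the
# finite-difference gradient checks)
unetLossGrad <- function(x, truth, params, training = FALSE,
                         dropout_p = 0.5, eps = 1) {
  fw <- unetForward(x, params, training = training, dropout_p = dropout_p)
  dl <- diceLossGrad(fw$pred, truth, eps = eps)
  grads <- unetBackward(dl$grad, fw$cache, params)
  list(loss = dl$loss, grads = grads, pred = fw$pred)
}
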