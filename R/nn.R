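# Minimal convolutional network engine used by the LCACNN classifier.
# Feature blocks are 4-D arrays in (h, w, n, c) layout: with channels
# last, the (h*w*n) x c matrix view of a block is a plain dim<- change
# (no copy), so convolutions reduce to k^2 shifted BLAS products.
# The public API of the classifier still speaks (h, w, c, n); the
# conversion happens once per forward call.

nn_view <- function(a) {          # (h,w,n,c) array -> (h*w*n) x c view
  d <- dim(a)
  dim(a) <- c(d[1] * d[2] * d[3], d[4])
  a
}

nn_unview <- function(m, h, w, n, c) {
  dim(m) <- c(h, w, n, c)
  m
}

nn_pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# ---- standard convolution (stride 1, same padding, odd kernel) --------

conv_forward <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  xp <- nn_pad_hw(x, p)
  Y <- matrix(0, h * w * n, cout)
  slices <- vector("list", k * k)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      xs <- xp[di - 1L + seq_len(h), dj - 1L + seq_len(w), , ,
               drop = FALSE]
      Xs <- nn_view(xs)
      slices[[(di - 1L) * k + dj]] <- Xs
      Y <- Y + Xs %*% matrix(W[di, dj, , ], cin, cout)
    }
  }
  Y <- Y + rep(b, each = h * w * n)
  list(out = nn_unview(Y, h, w, n, cout),
       cache = list(slices = slices, dims = d))
}

conv_backward <- function(dout, cache, W) {
  d <- cache$dims; h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  D <- nn_view(dout)
  dW <- array(0, dim(W))
  dxp <- array(0, c(h + 2L * p, w + 2L * p, n, cin))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      Xs <- cache$slices[[(di - 1L) * k + dj]]
      dW[di, dj, , ] <- crossprod(Xs, D)
      dXs <- tcrossprod(D, matrix(W[di, dj, , ], cin, cout))
      ih <- di - 1L + seq_len(h); iw <- dj - 1L + seq_len(w)
      dxp[ih, iw, , ] <- dxp[ih, iw, , , drop = FALSE] +
        nn_unview(dXs, h, w, n, cin)
    }
  }
  dx <- dxp[p + seq_len(h), p + seq_len(w), , , drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(D))
}

# ---- depthwise + pointwise (separable) convolution --------------------

dwconv_forward <- function(x, Wd, Wp, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  k <- dim(Wd)[1]
  p <- (k - 1L) %/% 2L
  xp <- nn_pad_hw(x, p)
  Ydw <- array(0, d)
  slices <- vector("list", k * k)
  hwn <- h * w * n
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      xs <- xp[di - 1L + seq_len(h), dj - 1L + seq_len(w), , ,
               drop = FALSE]
      slices[[(di - 1L) * k + dj]] <- xs
      Ydw <- Ydw + xs * rep(Wd[di, dj, ], each = hwn)
    }
  }
  Ym <- nn_view(Ydw) %*% Wp
  cout <- ncol(Wp)
  Ym <- Ym + rep(b, each = hwn)
  list(out = nn_unview(Ym, h, w, n, cout),
       cache = list(slices = slices, Ydw = Ydw, dims = d))
}

dwconv_backward <- function(dout, cache, Wd, Wp) {
  d <- cache$dims; h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  k <- dim(Wd)[1]
  p <- (k - 1L) %/% 2L
  hwn <- h * w * n
  D <- nn_view(dout)
  dWp <- crossprod(nn_view(cache$Ydw), D)
  db <- colSums(D)
  dYdw <- nn_unview(tcrossprod(D, Wp), h, w, n, cin)
  dWd <- array(0, dim(Wd))
  dxp <- array(0, c(h + 2L * p, w + 2L * p, n, cin))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      ih <- di - 1L + seq_len(h); iw <- dj - 1L + seq_len(w)
      xs <- cache$slices[[(di - 1L) * k + dj]]
      dWd[di, dj, ] <- colSums(nn_view(xs) * nn_view(dYdw))
      dxp[ih, iw, , ] <- dxp[ih, iw, , , drop = FALSE] +
        dYdw * rep(Wd[di, dj, ], each = hwn)
    }
  }
  dx <- dxp[p + seq_len(h), p + seq_len(w), , , drop = FALSE]
  list(dx = dx, dWd = dWd, dWp = dWp, db = db)
}

# ---- batch normalization (per channel over batch and space) -----------

bn_forward <- function(x_mat, gamma, beta, running, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(x_mat)
    xc <- sweep(x_mat, 2L, mu, `-`)
    v <- colMeans(xc^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(x_mat, 2L, mu, `-`)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = y, cache = list(xhat = xhat, invstd = invstd),
       running = running)
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, gamma, `*`)
  t1 <- colMeans(dxhat)
  t2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2L, t1, `-`) - sweep(xhat, 2L, t2, `*`)
  dx <- sweep(dx, 2L, cache$invstd, `*`)
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

# ---- mixed (max/average blend) pooling, 2x2 stride 2 ------------------

# pad odd spatial dims by replicating the last row/column
pool_pad <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L == 1L) {
    xe <- array(0, c(d[1] + 1L, d[2], d[3], d[4]))
    xe[seq_len(d[1]), , , ] <- x
    xe[d[1] + 1L, , , ] <- x[d[1], , , ]
    x <- xe
    d <- dim(x)
  }
  if (d[2] %% 2L == 1L) {
    xe <- array(0, c(d[1], d[2] + 1L, d[3], d[4]))
    xe[, seq_len(d[2]), , ] <- x
    xe[, d[2] + 1L, , ] <- x[, d[2], , ]
    x <- xe
  }
  x
}

mixed_pool_forward <- function(x, lambda) {
  x <- pool_pad(x)
  d <- dim(x); h <- d[1]; w <- d[2]
  oi <- seq(1L, h, by = 2L); oj <- seq(1L, w, by = 2L)
  a <- x[oi, oj, , , drop = FALSE]
  b <- x[oi + 1L, oj, , , drop = FALSE]
  cc <- x[oi, oj + 1L, , , drop = FALSE]
  dd <- x[oi + 1L, oj + 1L, , , drop = FALSE]
  mx <- pmax(a, b, cc, dd)
  mn <- (a + b + cc + dd) / 4
  y <- lambda * mx + (1 - lambda) * mn
  list(out = y,
       cache = list(a = a, b = b, cc = cc, dd = dd, mx = mx,
                    lambda = lambda, in_dim = d))
}

mixed_pool_backward <- function(dy, cache, orig_dim) {
  a <- cache$a; b <- cache$b; cc <- cache$cc; dd <- cache$dd
  mx <- cache$mx; lam <- cache$lambda
  # route the max gradient to the first maximal entry (a,b,c,d order)
  m1 <- a == mx
  m2 <- b == mx & !m1
  m3 <- cc == mx & !m1 & !m2
  m4 <- dd == mx & !m1 & !m2 & !m3
  avg <- (1 - lam) * dy / 4
  da <- lam * m1 * dy + avg
  db <- lam * m2 * dy + avg
  dc <- lam * m3 * dy + avg
  dd_ <- lam * m4 * dy + avg
  d <- cache$in_dim
  dx <- array(0, d)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  dx[oi, oj, , ] <- da
  dx[oi + 1L, oj, , ] <- db
  dx[oi, oj + 1L, , ] <- dc
  dx[oi + 1L, oj + 1L, , ] <- dd_
  # fold replicated padding back onto the true last row/column
  if (d[1] > orig_dim[1]) {
    dx[orig_dim[1], , , ] <- dx[orig_dim[1], , , ] + dx[d[1], , , ]
    dx <- dx[seq_len(orig_dim[1]), , , , drop = FALSE]
  }
  if (d[2] > orig_dim[2]) {
    dx[, orig_dim[2], , ] <- dx[, orig_dim[2], , ] + dx[, d[2], , ]
    dx <- dx[, seq_len(orig_dim[2]), , , drop = FALSE]
  }
  dx
}

# ---- coordinate attention ---------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# params: W1 (c x cr), b1 (cr), bn gamma/beta (cr), Wh, Ww (cr x c),
# bh, bw (c). x is (h, w, n, c).
ca_forward <- function(x, pars, running, training, bn_momentum = 0.9) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; c <- d[4]
  # axis-wise GAP: Mh (h, n, c) means over w; Mw (w, n, c) means over h
  xm <- aperm(x, c(2L, 1L, 3L, 4L))       # (w, h, n, c)
  dim(xm) <- c(w, h * n * c)
  Mh <- array(colMeans(xm), c(h, n, c))
  xm2 <- x
  dim(xm2) <- c(h, w * n * c)
  Mw <- array(colMeans(xm2), c(w, n, c))
  # concatenate along the spatial axis -> ((h+w)*n) x c
  zh <- Mh; dim(zh) <- c(h * n, c)
  zw <- Mw; dim(zw) <- c(w * n, c)
  Z <- rbind(zh, zw)
  Z1 <- sweep(Z %*% pars$W1, 2L, pars$b1, `+`)
  bn <- bn_forward(Z1, pars$bn_gamma, pars$bn_beta, running, training,
                   momentum = bn_momentum)
  Zr <- pmax(bn$out, 0)
  ih <- seq_len(h * n); iw <- h * n + seq_len(w * n)
  Ah <- sweep(Zr[ih, , drop = FALSE] %*% pars$Wh, 2L, pars$bh, `+`)
  Aw <- sweep(Zr[iw, , drop = FALSE] %*% pars$Ww, 2L, pars$bw, `+`)
  gh <- sigmoid(Ah)                        # (h*n) x c, h fastest
  gw <- sigmoid(Aw)                        # (w*n) x c
  # broadcast gates over the missing spatial axis
  Gh <- aperm(array(gh, c(h, n, c, w)), c(1L, 4L, 2L, 3L))
  Gw <- aperm(array(gw, c(w, n, c, h)), c(4L, 1L, 2L, 3L))
  y <- x * Gh * Gw
  list(out = y,
       cache = list(x = x, Gh = Gh, Gw = Gw, gh = gh, gw = gw, Zr = Zr,
                    bn_cache = bn$cache, relu_in = bn$out, Z = Z,
                    dims = d),
       running = bn$running,
       Mh = Mh, Mw = Mw)
}

ca_backward <- function(dy, cache, pars) {
  d <- cache$dims; h <- d[1]; w <- d[2]; n <- d[3]; c <- d[4]
  x <- cache$x; Gh <- cache$Gh; Gw <- cache$Gw
  dx_direct <- dy * Gh * Gw
  dGh <- dy * x * Gw
  dGw <- dy * x * Gh
  # collapse the broadcast axes
  dgh_a <- aperm(dGh, c(1L, 3L, 4L, 2L))   # (h, n, c, w)
  dim(dgh_a) <- c(h * n * c, w)
  dgh <- matrix(rowSums(dgh_a), h * n, c)
  dgw_a <- aperm(dGw, c(2L, 3L, 4L, 1L))   # (w, n, c, h)
  dim(dgw_a) <- c(w * n * c, h)
  dgw <- matrix(rowSums(dgw_a), w * n, c)
  dAh <- dgh * cache$gh * (1 - cache$gh)
  dAw <- dgw * cache$gw * (1 - cache$gw)
  ih <- seq_len(h * n); iw <- h * n + seq_len(w * n)
  Zr <- cache$Zr
  dWh <- crossprod(Zr[ih, , drop = FALSE], dAh)
  dWw <- crossprod(Zr[iw, , drop = FALSE], dAw)
  dbh <- colSums(dAh)
  dbw <- colSums(dAw)
  dZr <- matrix(0, nrow(Zr), ncol(Zr))
  dZr[ih, ] <- tcrossprod(dAh, pars$Wh)
  dZr[iw, ] <- tcrossprod(dAw, pars$Ww)
  dZ1 <- dZr * (cache$relu_in > 0)
  bnb <- bn_backward(dZ1, cache$bn_cache, pars$bn_gamma)
  dW1 <- crossprod(cache$Z, bnb$dx)
  db1 <- colSums(bnb$dx)
  dZ <- tcrossprod(bnb$dx, pars$W1)
  # undo the GAP: spread means back over the pooled axis
  dMh <- dZ[ih, , drop = FALSE]            # (h*n) x c
  dMw <- dZ[iw, , drop = FALSE]
  dx_h <- aperm(array(dMh / w, c(h, n, c, w)), c(1L, 4L, 2L, 3L))
  dx_w <- aperm(array(dMw / h, c(w, n, c, h)), c(4L, 1L, 2L, 3L))
  dx <- dx_direct + dx_h + dx_w
  list(dx = dx, dW1 = dW1, db1 = db1,
       dgamma = bnb$dgamma, dbeta = bnb$dbeta,
       dWh = dWh, dbh = dbh, dWw = dWw, dbw = dbw)
}
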