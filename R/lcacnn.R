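#' Configuration of the lightweight coordinate-attention CNN
#'
#' The classifier stacks `n_groups` blocks of convolution -> batch
#' normalization -> ReLU -> mixed pooling (2x2, stride 2) -> coordinate
#' attention, followed by global average pooling and a sigmoid unit.
#' The first two groups use standard convolutions; later groups use
#' depthwise-separable convolutions to cut the parameter count.
#'
#' @param n_groups Number of conv/pool/attention groups (1-5).
#' @param channels Output channels per group; recycled/truncated to
#'   `n_groups`.
#' @param kernel Odd convolution kernel size.
#' @param ca_reduction Channel-reduction ratio of the attention
#'   bottleneck; must divide every group's channel count.
#' @param input_shape Spatial size `c(h, w)` feature maps are resized to.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param standard_groups Number of leading groups using standard
#'   convolution (the rest are depthwise-separable).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   pooling-blend draws.
#' @export
lcacnn_config <- function(n_groups = 4L,
                          channels = c(32L, 64L, 128L, 256L, 256L),
                          kernel = 3L, ca_reduction = 8L,
                          input_shape = c(32L, 32L),
                          learning_rate = 0.001, batch_size = 64L,
                          epochs = 100L, standard_groups = 2L,
                          seed = 1L) {
  if (n_groups < 1L || n_groups > 5L) stop("n_groups must be in 1..5")
  if (kernel %% 2L != 1L) stop("kernel size must be odd")
  channels <- rep_len(as.integer(channels), n_groups)
  if (any(channels %% ca_reduction != 0L)) {
    stop("ca_reduction must divide every group's channel count")
  }
  structure(
    list(n_groups = as.integer(n_groups), channels = channels,
         kernel = as.integer(kernel), ca_reduction = as.integer(ca_reduction),
         input_shape = as.integer(input_shape),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         standard_groups = as.integer(standard_groups),
         seed = as.integer(seed)),
    class = "lcacnn_config"
  )
}

init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build an untrained LCACNN model
#'
#' Weights are He-initialized from the config seed. Fails if the spatial
#' size entering any group has already collapsed below 2 pixels.
#'
#' @param config An [lcacnn_config()].
#' @return An `lcacnn_model` (list of layer parameter sets).
#' @export
build_model <- function(config) {
  set.seed(config$seed)
  h <- config$input_shape[1]; w <- config$input_shape[2]
  k <- config$kernel
  cin <- 1L
  groups <- vector("list", config$n_groups)
  for (g in seq_len(config$n_groups)) {
    if (h < 2L || w < 2L) {
      stop("feature map collapses before group ", g,
           ": spatial size ", h, "x", w)
    }
    cout <- config$channels[g]
    cr <- cout %/% config$ca_reduction
    conv <- if (g <= config$standard_groups) {
      list(type = "conv",
           W = array(stats::rnorm(k * k * cin * cout, 0,
                                  sqrt(2 / (k * k * cin))),
                     c(k, k, cin, cout)),
           b = numeric(cout))
    } else {
      list(type = "dwconv",
           Wd = array(stats::rnorm(k * k * cin, 0, sqrt(2 / (k * k))),
                      c(k, k, cin)),
           Wp = init_mat(cin, cout, cin),
           b = numeric(cout))
    }
    groups[[g]] <- list(
      conv = conv,
      bn = list(gamma = rep(1, cout), beta = numeric(cout),
                running = list(mean = numeric(cout), var = rep(1, cout))),
      ca = list(W1 = init_mat(cout, cr, cout), b1 = numeric(cr),
                bn_gamma = rep(1, cr), bn_beta = numeric(cr),
                running = list(mean = numeric(cr), var = rep(1, cr)),
                Wh = init_mat(cr, cout, cr), bh = numeric(cout),
                Ww = init_mat(cr, cout, cr), bw = numeric(cout))
    )
    cin <- cout
    h <- as.integer(ceiling(h / 2)); w <- as.integer(ceiling(w / 2))
  }
  head <- list(W = init_mat(cin, 1L, cin), b = 0)
  structure(list(config = config, groups = groups, head = head),
            class = "lcacnn_model")
}

#' Number of trainable parameters of a model
#' @param model An `lcacnn_model`.
#' @export
count_parameters <- function(model) {
  n <- 0L
  for (grp in model$groups) {
    cv <- grp$conv
    n <- n + if (cv$type == "conv") length(cv$W) + length(cv$b) else
      length(cv$Wd) + length(cv$Wp) + length(cv$b)
    n <- n + length(grp$bn$gamma) + length(grp$bn$beta)
    ca <- grp$ca
    n <- n + length(ca$W1) + length(ca$b1) + length(ca$bn_gamma) +
      length(ca$bn_beta) + length(ca$Wh) + length(ca$bh) +
      length(ca$Ww) + length(ca$bw)
  }
  n + length(model$head$W) + 1L
}

# forward pass over a batch; x is (h, w, 1, n). lambdas: one pooling
# blend per group. Returns probabilities and (if requested) caches.
lcacnn_forward <- function(model, x, lambdas = NULL, training = FALSE,
                           keep_cache = FALSE, bn_momentum = 0.9) {
  ng <- model$config$n_groups
  if (is.null(lambdas)) lambdas <- rep(0.5, ng)
  x <- aperm(x, c(1L, 2L, 4L, 3L))  # public (h,w,c,n) -> internal (h,w,n,c)
  caches <- if (keep_cache) vector("list", ng) else NULL
  for (g in seq_len(ng)) {
    grp <- model$groups[[g]]
    cv <- grp$conv
    cf <- if (cv$type == "conv") conv_forward(x, cv$W, cv$b) else
      dwconv_forward(x, cv$Wd, cv$Wp, cv$b)
    d <- dim(cf$out)
    xm <- nn_view(cf$out)
    bnf <- bn_forward(xm, grp$bn$gamma, grp$bn$beta, grp$bn$running,
                      training, momentum = bn_momentum)
    if (training) model$groups[[g]]$bn$running <- bnf$running
    relu_in <- bnf$out
    xr <- nn_unview(pmax(relu_in, 0), d[1], d[2], d[3], d[4])
    orig_dim <- dim(xr)
    mpf <- mixed_pool_forward(xr, lambdas[g])
    caf <- ca_forward(mpf$out, grp$ca, grp$ca$running, training,
                      bn_momentum = bn_momentum)
    if (training) model$groups[[g]]$ca$running <- caf$running
    if (keep_cache) {
      caches[[g]] <- list(conv = cf$cache, conv_dim = d, bn = bnf$cache,
                          relu_in = relu_in, pool = mpf$cache,
                          pool_orig_dim = orig_dim, ca = caf$cache)
    }
    x <- caf$out
  }
  d <- dim(x)                               # (h, w, n, c)
  feat <- nn_view(x)                        # (h*w*n) x c
  hw <- d[1] * d[2]
  # global average pooling to (n x c)
  idx <- rep(seq_len(d[3]), each = hw)
  gap <- rowsum(feat, idx) / hw
  logit <- as.numeric(gap %*% model$head$W + model$head$b)
  p <- sigmoid(logit)
  list(p = p, model = model, caches = caches, gap = gap,
       final_dim = d)
}

# backward pass; dlogit is the gradient at the pre-sigmoid output
lcacnn_backward <- function(model, fw, dlogit) {
  grads <- list(groups = vector("list", model$config$n_groups))
  d <- fw$final_dim
  hw <- d[1] * d[2]
  grads$head <- list(W = crossprod(fw$gap, dlogit), b = sum(dlogit))
  dgap <- matrix(dlogit, ncol = 1L) %*% t(model$head$W)  # n x c
  # spread GAP gradient uniformly over spatial positions
  idx <- rep(seq_len(d[3]), each = hw)
  dfeat <- dgap[idx, , drop = FALSE] / hw
  dx <- nn_unview(dfeat, d[1], d[2], d[3], d[4])
  for (g in rev(seq_len(model$config$n_groups))) {
    cache <- fw$caches[[g]]
    grp <- model$groups[[g]]
    cab <- ca_backward(dx, cache$ca, grp$ca)
    dpool <- mixed_pool_backward(cab$dx, cache$pool, cache$pool_orig_dim)
    drelu <- nn_view(dpool) * (cache$relu_in > 0)
    bnb <- bn_backward(drelu, cache$bn, grp$bn$gamma)
    cd <- cache$conv_dim
    dconv_out <- nn_unview(bnb$dx, cd[1], cd[2], cd[3], cd[4])
    cv <- grp$conv
    cvb <- if (cv$type == "conv") {
      conv_backward(dconv_out, cache$conv, cv$W)
    } else {
      dwconv_backward(dconv_out, cache$conv, cv$Wd, cv$Wp)
    }
    grads$groups[[g]] <- list(
      conv = cvb[setdiff(names(cvb), "dx")],
      bn = list(dgamma = bnb$dgamma, dbeta = bnb$dbeta),
      ca = cab[setdiff(names(cab), "dx")]
    )
    dx <- cvb$dx
  }
  grads
}

#' Binary cross-entropy loss
#'
#' \eqn{L(y, p) = -[y \log p + (1-y)\log(1-p)]}, averaged over the
#' batch; predictions are clipped to `[eps, 1-eps]` first.
#'
#' @param y Labels in `{0, 1}`.
#' @param p Predicted probabilities in `(0, 1)`.
#' @param eps Clipping bound.
#' @export
bce_loss <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(model) {
  walk <- function(p) lapply(p, function(v) {
    if (is.list(v)) walk(v) else array(0, dim(v) %||% length(v))
  })
  params <- model_parameters(model)
  list(m = walk(params), v = walk(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat named access to trainable parameters (excludes running stats)
model_parameters <- function(model) {
  out <- list()
  for (g in seq_along(model$groups)) {
    grp <- model$groups[[g]]
    cv <- grp$conv
    conv_p <- if (cv$type == "conv") list(W = cv$W, b = cv$b) else
      list(Wd = cv$Wd, Wp = cv$Wp, b = cv$b)
    out[[paste0("g", g)]] <- list(
      conv = conv_p,
      bn = list(gamma = grp$bn$gamma, beta = grp$bn$beta),
      ca = list(W1 = grp$ca$W1, b1 = grp$ca$b1,
                bn_gamma = grp$ca$bn_gamma, bn_beta = grp$ca$bn_beta,
                Wh = grp$ca$Wh, bh = grp$ca$bh,
                Ww = grp$ca$Ww, bw = grp$ca$bw)
    )
  }
  out$head <- list(W = model$head$W, b = model$head$b)
  out
}

# map gradients list (as produced by lcacnn_backward) onto the same
# structure as model_parameters
grads_as_parameters <- function(grads, model) {
  out <- list()
  for (g in seq_along(model$groups)) {
    gg <- grads$groups[[g]]
    cv <- model$groups[[g]]$conv
    conv_g <- if (cv$type == "conv") {
      list(W = gg$conv$dW, b = gg$conv$db)
    } else {
      list(Wd = gg$conv$dWd, Wp = gg$conv$dWp, b = gg$conv$db)
    }
    out[[paste0("g", g)]] <- list(
      conv = conv_g,
      bn = list(gamma = gg$bn$dgamma, beta = gg$bn$dbeta),
      ca = list(W1 = gg$ca$dW1, b1 = gg$ca$db1,
                bn_gamma = gg$ca$dgamma, bn_beta = gg$ca$dbeta,
                Wh = gg$ca$dWh, bh = gg$ca$dbh,
                Ww = gg$ca$dWw, bw = gg$ca$dbw)
    )
  }
  out$head <- list(W = grads$head$W, b = grads$head$b)
  out
}

set_model_parameters <- function(model, params) {
  for (g in seq_along(model$groups)) {
    p <- params[[paste0("g", g)]]
    cv <- model$groups[[g]]$conv
    if (cv$type == "conv") {
      model$groups[[g]]$conv$W <- p$conv$W
      model$groups[[g]]$conv$b <- as.numeric(p$conv$b)
    } else {
      model$groups[[g]]$conv$Wd <- p$conv$Wd
      model$groups[[g]]$conv$Wp <- p$conv$Wp
      model$groups[[g]]$conv$b <- as.numeric(p$conv$b)
    }
    model$groups[[g]]$bn$gamma <- as.numeric(p$bn$gamma)
    model$groups[[g]]$bn$beta <- as.numeric(p$bn$beta)
    for (nm in names(p$ca)) model$groups[[g]]$ca[[nm]] <- p$ca[[nm]]
  }
  model$head$W <- params$head$W
  model$head$b <- as.numeric(params$head$b)
  model
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    g <- array(as.numeric(g), dim(p) %||% length(p))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

#' Train the LCACNN classifier
#'
#' Minimizes binary cross-entropy with Adam. The blend coefficient of
#' every mixed-pooling layer is redrawn Bernoulli(0.5) for each training
#' batch; at inference the blend is fixed at 0.5 so predictions are
#' deterministic. All randomness (initialization, shuffling, blend
#' draws) derives from `config$seed`.
#'
#' @param x Array `(h, w, 1, n)` of input feature maps (see
#'   [prepare_model_input()]).
#' @param y Numeric labels in `{0, 1}` (1 = CHD).
#' @param config An [lcacnn_config()].
#' @param model Optional pre-built model (for warm starts).
#' @param verbose Print per-epoch loss.
#' @return The trained `lcacnn_model`, with a `history` data.frame
#'   (epoch, loss, accuracy) attached.
#' @export
train_lcacnn <- function(x, y, config = lcacnn_config(), model = NULL,
                         verbose = FALSE) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  n <- dim(x)[4]
  if (length(y) != n) stop("label count must match batch dimension")
  if (is.null(model)) model <- build_model(config)
  set.seed(config$seed + 1L)
  state <- adam_init(model)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      lambdas <- stats::rbinom(config$n_groups, 1L, 0.5)
      fw <- lcacnn_forward(model, xb, lambdas = lambdas, training = TRUE,
                           keep_cache = TRUE)
      model <- fw$model  # running BN stats updated
      losses <- c(losses, bce_loss(yb, fw$p))
      correct <- correct + sum((fw$p >= 0.5) == (yb == 1))
      dlogit <- matrix((fw$p - yb) / length(yb), ncol = 1L)
      grads <- lcacnn_backward(model, fw, dlogit)
      st <- adam_step(model_parameters(model),
                      grads_as_parameters(grads, model),
                      state, config$learning_rate)
      model <- set_model_parameters(model, st$params)
      state <- st$state
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = mean(losses), accuracy = correct / n))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch,
                      mean(losses), correct / n))
    }
  }
  # exact BN running statistics: equal-weight average of batch stats
  # over one ordered pass (protects runs with few gradient updates)
  k <- 0L
  for (start in seq(1L, n, by = config$batch_size)) {
    idx <- start:min(start + config$batch_size - 1L, n)
    k <- k + 1L
    fw <- lcacnn_forward(model, x[, , , idx, drop = FALSE],
                         training = TRUE, bn_momentum = (k - 1) / k)
    model <- fw$model
  }
  attr(model, "history") <- history
  model
}

#' Predict class probabilities with a trained model
#'
#' Deterministic: mixed pooling uses the fixed 0.5 blend and batch
#' normalization its running statistics.
#'
#' @param object An `lcacnn_model`.
#' @param x Input array `(h, w, 1, n)`.
#' @param ... Unused.
#' @return Numeric vector of CHD probabilities.
#' @export
predict.lcacnn_model <- function(object, x, ...) {
  lcacnn_forward(object, x, training = FALSE)$p
}

# --- exported op-level wrappers ----------------------------------------

#' Mixed (max/average) pooling of a feature block
#'
#' Per pooling region: `lambda * max + (1 - lambda) * mean`. `lambda = 1`
#' is max pooling, `lambda = 0` average pooling; during training the
#' network redraws `lambda` from Bernoulli(0.5) per batch.
#'
#' @param x Matrix `(h, w)` or array `(h, w, c, n)`.
#' @param lambda Blend coefficient in `[0, 1]`.
#' @param pool Pooling region size (square, stride = size); only 2 is
#'   used by the network.
#' @return Pooled matrix/array.
#' @export
mixed_pool <- function(x, lambda, pool = 2L) {
  if (pool != 2L) stop("only 2x2 pooling regions are supported")
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1L, 1L)) else
    x <- aperm(x, c(1L, 2L, 4L, 3L))
  out <- mixed_pool_forward(x, lambda)$out
  out <- if (was_mat) out[, , 1L, 1L] else aperm(out, c(1L, 2L, 4L, 3L))
  out
}

#' Coordinate attention over a feature block
#'
#' Pools the block along each spatial axis separately (keeping
#' positional information), squeezes the pooled activations through a
#' shared bottleneck (1x1 convolution + batch normalization + ReLU),
#' expands per axis, and gates the input with the two sigmoid maps.
#'
#' @param x Array `(h, w, c, n)` (or `(h, w, c)` for a single block).
#' @param reduction Bottleneck reduction ratio; must divide `c`.
#' @param pars Optional parameter list (as in an `lcacnn_model` group's
#'   `ca` entry); random weights from `seed` otherwise.
#' @param seed Seed for random weights when `pars` is missing.
#' @return Gated block, same shape as the input, with attributes `Mh`
#'   and `Mw` (the axis-pooled activations).
#' @export
coordinate_attention <- function(x, reduction = 8L, pars = NULL, seed = 1L) {
  squeeze <- FALSE
  if (length(dim(x)) == 3L) {
    x <- array(x, c(dim(x), 1L))
    squeeze <- TRUE
  }
  c_ch <- dim(x)[3]
  if (c_ch %% reduction != 0L || reduction > c_ch) {
    stop("reduction must divide the channel count and not exceed it")
  }
  if (is.null(pars)) {
    set.seed(seed)
    cr <- c_ch %/% reduction
    pars <- list(W1 = init_mat(c_ch, cr, c_ch), b1 = numeric(cr),
                 bn_gamma = rep(1, cr), bn_beta = numeric(cr),
                 running = list(mean = numeric(cr), var = rep(1, cr)),
                 Wh = init_mat(cr, c_ch, cr), bh = numeric(c_ch),
                 Ww = init_mat(cr, c_ch, cr), bw = numeric(c_ch))
  }
  fw <- ca_forward(aperm(x, c(1L, 2L, 4L, 3L)), pars, pars$running,
                   training = TRUE)
  out <- aperm(fw$out, c(1L, 2L, 4L, 3L))
  if (squeeze) out <- out[, , , 1L]
  attr(out, "Mh") <- aperm(fw$Mh, c(1L, 3L, 2L))  # (h, c, n)
  attr(out, "Mw") <- aperm(fw$Mw, c(1L, 3L, 2L))  # (w, c, n)
  out
}

#' Depthwise-separable convolution
#'
#' A per-channel `k x k` depthwise convolution followed by a `1 x 1`
#' pointwise convolution (stride 1, same padding). Parameter count is
#' `c k^2 + c c_out` versus `c c_out k^2` for a standard convolution.
#'
#' @param x Array `(h, w, c, n)`.
#' @param Wd Depthwise kernel `(k, k, c)`.
#' @param Wp Pointwise weights `(c, c_out)`.
#' @param b Bias, length `c_out` (default 0).
#' @return Array `(h, w, c_out, n)`.
#' @export
depthwise_separable_conv <- function(x, Wd, Wp, b = numeric(ncol(Wp))) {
  if (dim(Wd)[1] %% 2L != 1L) stop("kernel size must be odd")
  out <- dwconv_forward(aperm(x, c(1L, 2L, 4L, 3L)), Wd, Wp, b)$out
  aperm(out, c(1L, 2L, 4L, 3L))
}

#' Resize and standardize a feature map for the classifier
#'
#' Bilinear resizing to the configured input shape, then per-map
#' z-scoring (zero mean, unit variance) so maps from recordings of
#' different loudness are comparable.
#'
#' @param W Feature matrix (frames x channels).
#' @param shape Target `c(h, w)`.
#' @return `shape[1] x shape[2]` matrix.
#' @export
prepare_model_input <- function(W, shape = c(32L, 32L)) {
  W <- unclass(W)
  attributes(W) <- list(dim = dim(W))
  out <- resize_bilinear(W, shape[1], shape[2])
  s <- stats::sd(out)
  if (!is.finite(s) || s < 1e-12) s <- 1
  (out - mean(out)) / s
}

resize_bilinear <- function(M, nr, nc) {
  r_src <- if (nrow(M) == 1L) rep(1, nr) else
    seq(1, nrow(M), length.out = nr)
  c_src <- if (ncol(M) == 1L) rep(1, nc) else
    seq(1, ncol(M), length.out = nc)
  r0 <- floor(r_src); r1 <- pmin(r0 + 1, nrow(M)); rf <- r_src - r0
  c0 <- floor(c_src); c1 <- pmin(c0 + 1, ncol(M)); cf <- c_src - c0
  A <- M[r0, c0, drop = FALSE] * outer(1 - rf, 1 - cf) +
    M[r1, c0, drop = FALSE] * outer(rf, 1 - cf) +
    M[r0, c1, drop = FALSE] * outer(1 - rf, cf) +
    M[r1, c1, drop = FALSE] * outer(rf, cf)
  A
}

#' Stack per-record feature maps into a model input array
#'
#' @param maps List of frames x channels matrices.
#' @param shape Target spatial shape.
#' @return Array `(shape[1], shape[2], 1, length(maps))`.
#' @export
stack_model_inputs <- function(maps, shape = c(32L, 32L)) {
  arr <- array(0, c(shape[1], shape[2], 1L, length(maps)))
  for (i in seq_along(maps)) {
    arr[, , 1L, i] <- prepare_model_input(maps[[i]], shape)
  }
  arr
}
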