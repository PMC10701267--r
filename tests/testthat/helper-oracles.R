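# Independent brute-force reference implementations used to validate
# the package's vectorized/dynamic-programming code paths. These are
# deliberately written as plain double loops over the defining formulas.

oracle_autocorr <- function(x) {
  N <- length(x)
  r <- numeric(N)
  for (l in 0:(N - 1)) {
    s <- 0
    for (n in 0:(N - l - 1)) s <- s + x[n + l + 1] * x[n + 1]
    r[l + 1] <- s / N
  }
  r
}

oracle_dft_power <- function(frame, fft_size) {
  x <- c(frame, numeric(fft_size - length(frame)))
  K <- fft_size %/% 2 + 1
  out <- numeric(K)
  for (k in 0:(K - 1)) {
    re <- 0; im <- 0
    for (n in 0:(fft_size - 1)) {
      ang <- -2 * pi * k * n / fft_size
      re <- re + x[n + 1] * cos(ang)
      im <- im + x[n + 1] * sin(ang)
    }
    out[k + 1] <- re^2 + im^2
  }
  out
}

oracle_mfsc_frame <- function(pow_row, H, floor_energy = 1e-10) {
  out <- numeric(nrow(H))
  for (nf in seq_len(nrow(H))) {
    s <- 0
    for (k in seq_along(pow_row)) s <- s + pow_row[k] * H[nf, k]
    out[nf] <- log(max(s, floor_energy))
  }
  out
}

oracle_mixed_pool <- function(m, lambda) {
  h <- nrow(m); w <- ncol(m)
  ho <- ceiling(h / 2); wo <- ceiling(w / 2)
  # replicate-edge padding for odd sizes, as the layer defines it
  if (h %% 2 == 1) m <- rbind(m, m[h, , drop = FALSE])
  if (w %% 2 == 1) m <- cbind(m, m[, ncol(m), drop = FALSE])
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      blk <- m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      out[i, j] <- lambda * max(blk) + (1 - lambda) * mean(blk)
    }
  }
  out
}

oracle_overlay <- function(M, G, mask) {
  W <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      W[i, j] <- if (mask[i]) M[i, j] + G[i, j] else (M[i, j] + G[i, j]) / 2
    }
  }
  W
}

# naive depthwise-separable convolution on one (h, w, c) block
oracle_dwsep <- function(x, Wd, Wp, b = numeric(ncol(Wp))) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(Wd)[1]; p <- (k - 1) %/% 2
  cout <- ncol(Wp)
  dw <- array(0, c(h, w, cin))
  for (ch in seq_len(cin)) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        s <- 0
        for (di in seq_len(k)) {
          for (dj in seq_len(k)) {
            ii <- i + di - 1 - p; jj <- j + dj - 1 - p
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
              s <- s + x[ii, jj, ch] * Wd[di, dj, ch]
            }
          }
        }
        dw[i, j, ch] <- s
      }
    }
  }
  out <- array(0, c(h, w, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        out[i, j, co] <- sum(dw[i, j, ] * Wp[, co]) + b[co]
      }
    }
  }
  out
}

# Exhaustive decode of the duration-constrained HMM on short sequences,
# under the same path semantics as the package decoder: cyclic state
# order, first and last segments duration-censored (survival P(D >= d)),
# interior segments scored with the exact duration pmf.
oracle_hsmm_decode <- function(features, model) {
  obs <- (features - mean(features)) / max(stats::sd(features), 1e-12)
  T_len <- length(obs)
  lv <- pcg_states()
  ll <- sapply(1:4, function(j) {
    e <- model$emission[[lv[j]]]
    stats::dnorm(obs, e$mean, e$sd, log = TRUE)
  })
  seg_ll <- function(j, a, b) sum(ll[a:b, j])
  surv <- function(j, d) {
    pm <- model$duration_pmf[[lv[j]]]
    if (d <= min(pm$d)) 1 else sum(pm$p[pm$d >= d])
  }
  pmf <- function(j, d) {
    pm <- model$duration_pmf[[lv[j]]]
    i <- match(d, pm$d)
    if (is.na(i)) 0 else pm$p[i]
  }
  best <- list(score = -Inf, states = NULL)
  extend <- function(states, score, t_used, j_prev) {
    j <- j_prev %% 4L + 1L
    rem <- T_len - t_used
    # close with a censored final segment
    sf <- surv(j, rem)
    if (sf > 0) {
      sc <- score + log(sf) + seg_ll(j, t_used + 1, T_len)
      if (sc > best$score) {
        best <<- list(score = sc, states = c(states, rep(j, rem)))
      }
    }
    # or insert an interior segment with exact duration
    pm <- model$duration_pmf[[lv[j]]]
    for (d in pm$d) {
      if (d >= rem) next
      p <- pmf(j, d)
      if (p <= 0) next
      extend(c(states, rep(j, d)), score + log(p) +
               seg_ll(j, t_used + 1, t_used + d), t_used + d, j)
    }
  }
  for (j in 1:4) {
    for (d1 in seq_len(T_len)) {
      s1 <- surv(j, d1)
      if (s1 <= 0) next
      sc <- log(model$pi[j]) + log(s1) + seg_ll(j, 1, d1)
      if (d1 == T_len) {
        if (sc > best$score) {
          best <- list(score = sc, states = rep(j, T_len))
        }
      } else {
        extend(rep(j, d1), sc, d1, j)
      }
    }
  }
  best
}

# a small duration_hmm with given duration support (uniform pmf) and
# random Gaussian emissions, for decoder tests
random_toy_dhmm <- function(support = 3:5, seed = 1) {
  set.seed(seed)
  lv <- pcg_states()
  pmf <- lapply(lv, function(st) {
    list(d = as.integer(support), p = rep(1 / length(support),
                                          length(support)))
  })
  names(pmf) <- lv
  em <- lapply(seq_along(lv), function(i) {
    list(mean = stats::rnorm(1, 0, 1.5), sd = stats::runif(1, 0.4, 1.2))
  })
  names(em) <- lv
  structure(
    list(A = dhmm_transition_matrix(), pi = rep(0.25, 4),
         duration_mean = stats::setNames(rep(mean(support), 4), lv),
         duration_var = stats::setNames(rep(stats::var(support), 4), lv),
         duration_pmf = pmf, emission = em, hop = 20L),
    class = "duration_hmm"
  )
}
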