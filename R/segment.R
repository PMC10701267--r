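#' Biased autocorrelation of a signal
#'
#' Computes \eqn{\tilde r_x(l) = \frac{1}{N}\sum_{n=0}^{N-l-1} x(n+l)x(n)}
#' for lags \eqn{l = 0, \dots, N-1}. The 1/N normalization is shared by
#' all lags, so the sequence decays with lag even for periodic inputs.
#'
#' @param x Numeric vector, length >= 1.
#' @return Numeric vector of length `length(x)`; element `l+1` is the
#'   coefficient at lag `l`.
#' @export
pcg_autocorr <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 1L) stop("autocorrelation needs a non-empty input")
  # FFT-based linear correlation: exact up to floating point
  m <- 2^ceiling(log2(2 * N))
  X <- stats::fft(c(x, numeric(m - N)))
  r <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / m
  r[seq_len(N)] / N
}

#' Hilbert (analytic-signal) envelope
#'
#' Magnitude of the analytic signal computed by the FFT method.
#'
#' @param x Numeric vector, length >= 2.
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("hilbert_envelope needs length >= 2")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Estimate the cardiac cycle length of a recording
#'
#' Takes the autocorrelation of the Hilbert envelope and returns the lag
#' of its most prominent peak within a physiologic search band
#' (30-160 bpm, i.e. cycle lengths of 0.375-2 s, by default).
#'
#' @param record A [pcg_record()] of at least 2 s.
#' @param band Search band in seconds, `c(min_cycle, max_cycle)`.
#' @param min_prominence Minimum peak height relative to the zero-lag
#'   coefficient; below this the periodicity is considered absent.
#' @return Cycle length in samples.
#' @export
estimate_cycle_length <- function(record, band = c(0.375, 2.0),
                                  min_prominence = 0.15) {
  if (pcg_duration(record) < 2) stop("recording must be at least 2 s long")
  env <- hilbert_envelope(record$samples)
  env <- env - mean(env)
  r <- pcg_autocorr(env)
  fs <- record$sampling_rate
  lo <- max(2L, as.integer(floor(band[1] * fs)))
  hi <- min(length(r) - 1L, as.integer(ceiling(band[2] * fs)))
  if (lo >= hi) stop("cycle not found: search band empty at this rate")
  lag <- lo:hi
  rr <- r[lag + 1L]
  # local maxima within the band
  is_peak <- c(FALSE, rr[2:(length(rr) - 1)] > rr[1:(length(rr) - 2)] &
                 rr[2:(length(rr) - 1)] >= rr[3:length(rr)], FALSE)
  if (!any(is_peak)) stop("cycle not found: no autocorrelation peak in band")
  peaks <- lag[is_peak]
  heights <- rr[is_peak]
  best <- which.max(heights)
  if (heights[best] < min_prominence * r[1]) {
    stop("cycle not found: peak below prominence threshold")
  }
  peaks[best]
}

#' Per-phase timing rule for ECG-guided labeling
#'
#' Mean durations (seconds) of S1 and S2 used when projecting ECG
#' fiducials onto the heart-sound signal, with their standard deviations
#' kept as quality-control tolerances. Defaults reflect S1/S2 phases of
#' about 0.2 s each.
#'
#' @param s1_mean,s2_mean Mean S1 / S2 duration, s (> 0).
#' @param s1_sd,s2_sd Standard deviations, s (>= 0); not used for
#'   boundary placement.
#' @export
ecg_label_rule <- function(s1_mean = 0.2, s1_sd = 0.02,
                           s2_mean = 0.2, s2_sd = 0.02) {
  if (s1_mean <= 0 || s2_mean <= 0) stop("rule means must be > 0")
  if (s1_sd < 0 || s2_sd < 0) stop("rule sds must be >= 0")
  structure(list(s1_mean = s1_mean, s1_sd = s1_sd,
                 s2_mean = s2_mean, s2_sd = s2_sd),
            class = "ecg_label_rule")
}

#' Construct a segment map
#'
#' Per-frame phase labels plus the run-length boundary table. Checks that
#' consecutive distinct states follow the cyclic order S1 -> systole ->
#' S2 -> diastole -> S1 and that boundaries tile the frame axis.
#'
#' @param states Integer (1-4) or factor/character vector of per-frame
#'   states.
#' @param hop,sampling_rate Optional frame hop (samples) and rate for
#'   converting boundaries back to time.
#' @return A `segment_map`: list with `states` (factor), `boundaries`
#'   (data.frame state,start_frame,end_frame; 0-based, half-open), `hop`,
#'   `sampling_rate`.
#' @export
segment_map <- function(states, hop = NA_integer_,
                        sampling_rate = NA_real_) {
  lv <- pcg_states()
  if (is.numeric(states)) states <- lv[states]
  states <- factor(as.character(states), levels = lv)
  if (anyNA(states)) stop("unknown state labels in segment map")
  code <- as.integer(states)
  if (length(code) > 1L) {
    d <- code[-1L][code[-1L] != code[-length(code)]]
    prev <- code[-length(code)][code[-1L] != code[-length(code)]]
    if (any((prev %% 4L + 1L) != d)) {
      stop("states violate the cyclic order S1 -> systole -> S2 -> diastole")
    }
  }
  r <- rle(as.integer(code))
  ends <- cumsum(r$lengths)
  boundaries <- data.frame(
    state = lv[r$values],
    start_frame = c(0L, ends[-length(ends)]),
    end_frame = ends
  )
  structure(list(states = states, boundaries = boundaries,
                 hop = hop, sampling_rate = sampling_rate),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d frames, %d segments, %d complete cycles\n",
              length(x$states), nrow(x$boundaries),
              length(cycle_starts(x))))
  invisible(x)
}

#' Start frames of complete cardiac cycles in a segment map
#'
#' A complete cycle is an S1 run followed (within the map) by systole,
#' S2, diastole and the next S1 onset.
#'
#' @param segmap A [segment_map()].
#' @return Integer vector of 0-based start frames; attribute `"ends"`
#'   holds the matching 0-based half-open end frames.
#' @export
cycle_starts <- function(segmap) {
  b <- segmap$boundaries
  s1 <- which(b$state == "S1")
  s1 <- s1[s1 + 4L <= nrow(b) + 1L]
  # next S1 run must exist to close the cycle
  s1 <- s1[vapply(s1, function(i) {
    i + 4L <= nrow(b) && all(b$state[i:(i + 4L)] ==
      c("S1", "systole", "S2", "diastole", "S1"))
  }, logical(1))]
  structure(b$start_frame[s1], ends = b$start_frame[s1 + 4L][seq_along(s1)])
}

#' Label heart-sound phases from synchronized ECG fiducials
#'
#' S1 starts at each R peak and lasts `rule$s1_mean`. S2 is centered on
#' the largest Hilbert-envelope peak following the T-wave end of the same
#' cycle, with half-width `rule$s2_mean / 2`. Systole fills the S1-end to
#' S2-start gap and diastole the S2-end to next-S1 gap. Output is at
#' frame resolution (`hop` samples); a frame takes the phase of its
#' center sample.
#'
#' @param record A [pcg_record()] carrying `r_peaks` and `t_ends`.
#' @param rule An [ecg_label_rule()].
#' @param hop Frame hop in samples used for the output grid.
#' @return A [segment_map()] at frame resolution. Frames before the first
#'   R peak and after the last complete cycle are labeled by extrapolating
#'   the cyclic pattern (diastole before the first S1).
#' @export
label_from_ecg <- function(record, rule = ecg_label_rule(),
                           hop = round(0.010 * record$sampling_rate),
                           frame_length = round(0.025 * record$sampling_rate)) {
  if (is.null(record$r_peaks) || is.null(record$t_ends)) {
    stop("record has no ECG fiducials (r_peaks / t_ends)")
  }
  if (length(record$r_peaks) < 2L) {
    stop("need at least one complete R-R interval (two R peaks)")
  }
  fs <- record$sampling_rate
  n <- length(record$samples)
  env <- hilbert_envelope(record$samples)
  s1_len <- round(rule$s1_mean * fs)
  s2_half <- round(rule$s2_mean * fs / 2)
  min_gap <- max(1L, as.integer(hop))  # >= one frame of systole / diastole
  rp <- record$r_peaks
  K <- length(rp)

  # per-cycle S2 onset from the envelope peak after the T-wave end
  s2_on <- rep(NA_integer_, K)
  for (k in seq_len(K - 1L)) {
    a <- rp[k]; b_next <- rp[k + 1L]
    s1_hi <- min(a + s1_len, b_next - 2L * min_gap)
    te <- record$t_ends[record$t_ends > a & record$t_ends < b_next]
    if (length(te) == 0L) {
      warning("cycle at R peak ", a, " has no T-wave end; timing extrapolated")
      next
    }
    search <- seq.int(te[1L] + 1L, b_next - 1L)
    search <- search[search > s1_hi & search <= n - 1L]
    if (length(search) == 0L) {
      warning("empty S2 search window in cycle at R peak ", a,
              "; timing extrapolated")
      next
    }
    s2_center <- search[which.max(env[search + 1L])]
    s2_on[k] <- s2_center - s2_half
  }
  sys_durs <- s2_on[seq_len(K - 1L)] - (rp[seq_len(K - 1L)] + s1_len)
  mean_sys <- if (any(!is.na(sys_durs))) {
    max(round(mean(sys_durs, na.rm = TRUE)), min_gap)
  } else {
    max(round(0.3 * (mean(diff(rp)) - s1_len - 2 * s2_half)), min_gap)
  }

  states <- rep(4L, n)  # diastole before the first S1 and as fill
  for (k in seq_len(K)) {
    a <- rp[k]
    fill <- function(lo, hi, code) {
      lo <- max(lo, 0L); hi <- min(hi, n)
      if (lo < hi) states[(lo + 1L):hi] <<- code
    }
    if (k < K) {
      b_next <- rp[k + 1L]
      if (b_next - a < 4L * min_gap) {
        stop("R-R interval at sample ", a, " too short to hold four phases")
      }
      s1_hi <- max(a + min_gap, min(a + s1_len, b_next - 3L * min_gap))
      on_k <- if (!is.na(s2_on[k])) s2_on[k] else s1_hi + mean_sys
      s2_lo <- min(max(on_k, s1_hi + min_gap), b_next - 2L * min_gap)
      s2_hi <- min(max(s2_lo + min_gap, s2_lo + 2L * s2_half),
                   b_next - min_gap)
      fill(a, s1_hi, 1L)
      fill(s1_hi, s2_lo, 2L)
      fill(s2_lo, s2_hi, 3L)
      fill(s2_hi, b_next, 4L)
    } else {
      # final (possibly truncated) cycle: phases laid out in order and
      # clipped at the record end
      s1_hi <- a + s1_len
      s2_lo <- max(if (!is.na(s2_on[k])) s2_on[k] else s1_hi + mean_sys,
                   s1_hi + min_gap)
      s2_hi <- s2_lo + 2L * s2_half
      fill(a, s1_hi, 1L)
      fill(s1_hi, s2_lo, 2L)
      fill(s2_lo, s2_hi, 3L)
      fill(s2_hi, n, 4L)
    }
  }

  centers <- frame_center_samples(n, hop, frame_length)
  segment_map(states[centers + 1L], hop = hop, sampling_rate = fs)
}

# 0-based center samples of 10ms-hop frames covering n samples
frame_center_samples <- function(n, hop, frame_length = hop) {
  n_fr <- max(1L, (n - as.integer(frame_length)) %/% as.integer(hop) + 1L)
  starts <- (seq_len(n_fr) - 1L) * hop
  pmin(starts + as.integer(frame_length) %/% 2L, n - 1L)
}

#' Fit a duration-constrained HMM from labeled recordings
#'
#' The transition matrix is fixed to the cyclic permutation over
#' S1 -> systole -> S2 -> diastole and the initial distribution to 1/4
#' per state (an auscultation probe may land in any phase); neither is
#' re-estimated. Dwell-time mean and variance per state are estimated
#' from the labeled run lengths (runs touching the record edges are
#' dropped as censored) and turned into a discretized Gaussian duration
#' pmf truncated to `[max(1, mu - 3 sd), mu + 3 sd]`. Emissions are
#' per-state Gaussians over the per-frame observation feature.
#'
#' @param labeled List of `list(features = numeric per-frame vector,
#'   segmap = segment_map)` pairs; at least one, jointly containing every
#'   state.
#' @return A `duration_hmm`: list with `A` (4x4), `pi` (length 4),
#'   `duration_mean`, `duration_var` (frames), `duration_pmf` (list of
#'   `d`/`p` per state), `emission` (mean/sd per state), `hop`.
#' @export
fit_dhmm <- function(labeled) {
  if (length(labeled) < 1L) stop("need at least one labeled recording")
  lv <- pcg_states()
  dwells <- stats::setNames(vector("list", 4L), lv)
  obs <- stats::setNames(vector("list", 4L), lv)
  hop <- NA_integer_
  for (item in labeled) {
    seg <- item$segmap
    feats <- standardize(item$features)
    if (length(feats) != length(seg$states)) {
      stop("feature vector and segment map lengths differ")
    }
    hop <- seg$hop
    b <- seg$boundaries
    interior <- seq_len(nrow(b))
    interior <- interior[interior > 1L & interior < nrow(b)]
    for (i in interior) {
      st <- b$state[i]
      dwells[[st]] <- c(dwells[[st]], b$end_frame[i] - b$start_frame[i])
    }
    for (st in lv) {
      obs[[st]] <- c(obs[[st]], feats[seg$states == st])
    }
  }
  for (st in lv) {
    if (length(dwells[[st]]) == 0L || length(obs[[st]]) == 0L) {
      stop("state '", st, "' absent from the labeled recordings")
    }
  }
  duration_mean <- vapply(dwells, function(d) mean(d), numeric(1))
  duration_var <- vapply(dwells, function(d) {
    if (length(d) > 1L) stats::var(d) else 0
  }, numeric(1))
  duration_pmf <- lapply(lv, function(st) {
    duration_pmf_gaussian(duration_mean[[st]], duration_var[[st]])
  })
  names(duration_pmf) <- lv
  emission <- lapply(lv, function(st) {
    list(mean = mean(obs[[st]]),
         sd = max(stats::sd(obs[[st]]), 1e-3))
  })
  names(emission) <- lv
  structure(
    list(A = dhmm_transition_matrix(), pi = rep(1 / 4, 4L),
         duration_mean = duration_mean, duration_var = duration_var,
         duration_pmf = duration_pmf, emission = emission, hop = hop),
    class = "duration_hmm"
  )
}

#' The cyclic phase-transition matrix
#'
#' Each phase passes deterministically to the next in the order
#' S1 -> systole -> S2 -> diastole -> S1.
#' @return A 4x4 matrix with a single 1 per row.
#' @export
dhmm_transition_matrix <- function() {
  A <- matrix(0, 4, 4, dimnames = list(pcg_states(), pcg_states()))
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- 1
  A
}

# discretized Gaussian dwell pmf on [max(1, mu-3sd), mu+3sd]
duration_pmf_gaussian <- function(mu, sigma2) {
  sd <- sqrt(sigma2)
  if (sd < 1e-9) {
    d <- max(1L, as.integer(round(mu)))
    return(list(d = d, p = 1))
  }
  lo <- max(1L, as.integer(floor(mu - 3 * sd)))
  hi <- max(lo, as.integer(ceiling(mu + 3 * sd)))
  d <- lo:hi
  p <- stats::dnorm(d, mu, sd)
  list(d = d, p = p / sum(p))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) s <- 1
  (x - mean(x)) / s
}

#' Duration-explicit Viterbi decoding of heart-sound phases
#'
#' Finds the maximum-probability segmentation under the
#' duration-constrained model: a path is a sequence of segments whose
#' states follow the cyclic transition matrix; its log score is the sum
#' over segments of the duration log-probability plus the per-frame
#' emission log-likelihoods, plus `log pi` for the first segment. The
#' first and last segments are duration-censored (the recording may start
#' and end mid-phase), scored with the duration survival function
#' `P(D >= d)`. Scores tie-break toward the earliest boundary (shortest
#' duration considered first, strict improvement required to switch).
#'
#' @param features Per-frame observation vector (the homomorphic envelope
#'   averaged per frame; z-scored internally, making the segmentation
#'   invariant to overall amplitude scaling).
#' @param model A `duration_hmm` from [fit_dhmm()].
#' @return A [segment_map()].
#' @export
viterbi_segment <- function(features, model) {
  obs <- standardize(as.numeric(features))
  T_len <- length(obs)
  if (T_len < 1L) stop("need at least one frame")
  lv <- pcg_states()
  # per-state per-frame emission log-likelihood, cumulative
  ll <- vapply(lv, function(st) {
    e <- model$emission[[st]]
    stats::dnorm(obs, e$mean, e$sd, log = TRUE)
  }, numeric(T_len))
  if (T_len == 1L) ll <- matrix(ll, nrow = 1L)
  cum <- rbind(0, apply(ll, 2, cumsum))  # cum[t+1, j] = sum of ll[1..t, j]
  seg_ll <- function(j, a, b) cum[b + 1L, j] - cum[a, j]  # frames a..b

  logp <- lapply(lv, function(st) {
    pm <- model$duration_pmf[[st]]
    log(pm$p)
  })
  logS <- lapply(lv, function(st) {  # log P(D >= d) for d = 1..T
    pm <- model$duration_pmf[[st]]
    out <- vapply(seq_len(T_len), function(d) {
      if (d <= min(pm$d)) 1 else sum(pm$p[pm$d >= d])
    }, numeric(1))
    log(out)
  })
  names(logp) <- names(logS) <- lv
  dur_support <- lapply(lv, function(st) model$duration_pmf[[st]]$d)
  names(dur_support) <- lv
  prev_state <- c(4L, 1L, 2L, 3L)  # predecessor under the cyclic A

  NEG <- -Inf
  alpha <- matrix(NEG, T_len, 4L)      # best score, segment of j ends at t
  back_d <- matrix(0L, T_len, 4L)      # chosen duration
  log_pi <- log(model$pi)

  for (t in seq_len(T_len)) {
    for (j in 1:4) {
      best <- NEG; bd <- 0L
      # first (start-censored) segment covering frames 1..t
      sc <- log_pi[j] + logS[[j]][t] + seg_ll(j, 1L, t)
      if (sc > best) { best <- sc; bd <- t }
      # interior segment of exact duration d
      pv <- prev_state[j]
      for (di in seq_along(dur_support[[j]])) {
        d <- dur_support[[j]][di]
        if (d >= t) next
        prev <- alpha[t - d, pv]
        if (prev == NEG) next
        sc <- prev + logp[[j]][di] + seg_ll(j, t - d + 1L, t)
        if (sc > best) { best <- sc; bd <- d }
      }
      alpha[t, j] <- best
      back_d[t, j] <- bd
    }
  }

  # final segment: end-censored
  best_sc <- NEG; best_j <- 0L; best_d <- 0L
  for (j in 1:4) {
    # whole record as one doubly censored segment
    sc <- log_pi[j] + logS[[j]][T_len] + seg_ll(j, 1L, T_len)
    if (sc > best_sc) {
      best_sc <- sc; best_j <- j; best_d <- T_len
    }
    pv <- prev_state[j]
    for (d in seq_len(T_len - 1L)) {
      prev <- alpha[T_len - d, pv]
      if (prev == NEG) next
      sc <- prev + logS[[j]][d] + seg_ll(j, T_len - d + 1L, T_len)
      if (sc > best_sc) {
        best_sc <- sc; best_j <- j; best_d <- d
      }
    }
  }
  if (!is.finite(best_sc)) stop("no admissible path")

  # backtrack
  states <- integer(T_len)
  t <- T_len; j <- best_j; d <- best_d
  states[(t - d + 1L):t] <- j
  t <- t - d
  while (t > 0L) {
    j <- prev_state[j]
    d <- back_d[t, j]
    states[(t - d + 1L):t] <- j
    t <- t - d
  }
  sm <- segment_map(states, hop = model$hop)
  attr(sm, "log_score") <- best_sc
  sm
}

#' Per-frame observation feature for the segmentation HMM
#'
#' Homomorphic envelope averaged over each analysis frame.
#'
#' @param record A [pcg_record()].
#' @param frame_length,hop Frame parameters in samples.
#' @return Numeric per-frame vector.
#' @export
segmentation_features <- function(record,
                                  frame_length = round(0.025 * record$sampling_rate),
                                  hop = round(0.010 * record$sampling_rate)) {
  env <- homomorphic_envelope(record$samples, record$sampling_rate)
  fs <- frame_signal(env, frame_length, hop, window = "rectangular")
  colMeans(fs$frames)
}

#' Segment a recording with a fitted duration-constrained HMM
#'
#' @param record A [pcg_record()].
#' @param model A `duration_hmm`.
#' @param frame_length,hop Frame parameters in samples.
#' @return A [segment_map()] at frame resolution.
#' @export
dhmm_segment <- function(record, model,
                         frame_length = round(0.025 * record$sampling_rate),
                         hop = round(0.010 * record$sampling_rate)) {
  feats <- segmentation_features(record, frame_length, hop)
  sm <- viterbi_segment(feats, model)
  sm$hop <- hop
  sm$sampling_rate <- record$sampling_rate
  sm
}

#' Write / read a segment map as CSV
#'
#' Columns `state,start_frame,end_frame`, 0-based half-open.
#' @param segmap A [segment_map()].
#' @param path CSV path.
#' @export
write_segment_map <- function(segmap, path) {
  utils::write.csv(segmap$boundaries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_map
#' @export
read_segment_map <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  states <- rep(b$state, b$end_frame - b$start_frame)
  segment_map(states)
}
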