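#' One-sided power spectrum of analysis frames
#'
#' FFT of each (already windowed) frame, zero-padded to `fft_size`,
#' returning the magnitude-squared of the first `fft_size/2 + 1` bins.
#'
#' @param frames A `frame_set` from [frame_signal()], or a
#'   frame_length x n_frames matrix.
#' @param fft_size FFT length, >= frame length; a non-power-of-two size
#'   is accepted with a warning.
#' @return n_frames x K matrix of `|X(k)|^2`, `K = fft_size/2 + 1`.
#' @export
power_spectrum <- function(frames, fft_size = 512L) {
  f <- if (inherits(frames, "frame_set")) frames$frames else as.matrix(frames)
  fft_size <- as.integer(fft_size)
  if (fft_size < nrow(f)) stop("fft_size must be >= frame length")
  if (bitwAnd(fft_size, fft_size - 1L) != 0L) {
    warning("fft_size ", fft_size, " is not a power of two; zero-padding anyway")
  }
  padded <- rbind(f, matrix(0, fft_size - nrow(f), ncol(f)))
  X <- stats::mvfft(padded)
  K <- fft_size %/% 2L + 1L
  t(Mod(X[seq_len(K), , drop = FALSE])^2)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Build a triangular Mel filter bank
#'
#' `n_filters` filters with center frequencies equally spaced on the Mel
#' scale between `f_lo` and `f_hi`, mapped to FFT bin indices. Each row
#' is the classic triangle: zero below the previous center, rising
#' linearly to 1 at its own center bin, falling to zero at the next
#' center. Between consecutive centers the falling and rising edges of
#' adjacent filters sum to exactly 1.
#'
#' @param n_filters Number of filters (>= 2).
#' @param fft_size FFT length the bank will be applied to.
#' @param sample_rate Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi <= sample_rate/2`.
#' @return A `mel_filter_bank`: list with `H` (n_filters x K weight
#'   matrix), `centers_bin`, `centers_hz`, `n_filters`, `fft_size`,
#'   `sample_rate`.
#' @export
build_mel_bank <- function(n_filters = 64L, fft_size = 512L,
                           sample_rate = 2000, f_lo = 25, f_hi = 1000) {
  if (n_filters < 2L) stop("need at least 2 filters")
  if (!(f_lo < f_hi && f_hi <= sample_rate / 2)) {
    stop("need f_lo < f_hi <= sample_rate / 2")
  }
  K <- fft_size %/% 2L + 1L
  mel_pts <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_pts <- as.integer(floor(hz_pts / sample_rate * fft_size + 0.5))
  bin_pts <- pmin(bin_pts, K - 1L)
  if (any(diff(bin_pts) < 1L)) {
    stop("duplicate filter centers: too many filters for this FFT resolution")
  }
  H <- matrix(0, n_filters, K)
  k <- 0:(K - 1L)
  for (nf in seq_len(n_filters)) {
    fl <- bin_pts[nf]; fc <- bin_pts[nf + 1L]; fr <- bin_pts[nf + 2L]
    rise <- k >= fl & k <= fc
    fall <- k > fc & k <= fr
    H[nf, rise] <- (k[rise] - fl) / (fc - fl)
    H[nf, fall] <- (fr - k[fall]) / (fr - fc)
  }
  structure(
    list(H = H, centers_bin = bin_pts[2:(n_filters + 1L)],
         centers_hz = hz_pts[2:(n_filters + 1L)],
         n_filters = n_filters, fft_size = fft_size,
         sample_rate = sample_rate),
    class = "mel_filter_bank"
  )
}

#' Mel-frequency spectral coefficients (log filter-bank energies)
#'
#' Applies the Mel filter bank to the per-frame power spectrum and takes
#' the natural log of each filter's energy:
#' \eqn{s_n = \ln \sum_k |X(k)|^2 H_n(k)}. Energies are floored at
#' `floor_energy` before the log so silent frames stay finite.
#'
#' @param frames A `frame_set` (or windowed frame matrix).
#' @param bank A [build_mel_bank()] filter bank.
#' @param floor_energy Energy floor applied before the log.
#' @return An `mfsc_matrix`: n_frames x n_filters matrix with attributes
#'   `hop`, `sampling_rate`, `centers_hz`.
#' @export
mfsc <- function(frames, bank, floor_energy = 1e-10) {
  P <- power_spectrum(frames, bank$fft_size)
  M <- log(pmax(P %*% t(bank$H), floor_energy))
  attr(M, "hop") <- if (inherits(frames, "frame_set")) frames$hop else NA_integer_
  attr(M, "sampling_rate") <-
    if (inherits(frames, "frame_set")) frames$sampling_rate else NA_real_
  attr(M, "centers_hz") <- bank$centers_hz
  class(M) <- c("mfsc_matrix", "matrix")
  M
}

#' Homomorphic amplitude envelope of a heart-sound signal
#'
#' Band-pass Butterworth filtering, analytic-signal magnitude, then the
#' homomorphic chain: log amplitude, zero-phase (forward-backward)
#' low-pass filtering, and exponentiation. The output is strictly
#' positive and tracks slow amplitude modulation while discarding the
#' carrier.
#'
#' @param x Numeric sample vector.
#' @param sample_rate Sampling rate, Hz; must exceed twice the band-pass
#'   upper edge.
#' @param band Band-pass edges in Hz (order-2 Butterworth).
#' @param lp_cutoff Envelope low-pass cutoff in Hz (order-1 Butterworth,
#'   applied forward-backward for zero phase).
#' @return Envelope vector, same length as `x`, strictly positive.
#' @export
homomorphic_envelope <- function(x, sample_rate, band = c(25, 400),
                                 lp_cutoff = 8) {
  x <- as.numeric(x)
  if (sample_rate / 2 <= band[2]) {
    stop("sample_rate must exceed twice the band-pass upper edge (",
         band[2], " Hz)")
  }
  if (length(x) < 12L) stop("input too short for filtering")
  # reflect the signal at both ends so filter transients stay in the
  # padding; this also keeps the chain exactly amplitude-equivariant
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(0.5 * sample_rate)))
  xe <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  bp <- signal::butter(2, band / (sample_rate / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, xe))
  a <- hilbert_envelope(xf)
  la <- log(pmax(a, 1e-12))
  lp <- signal::butter(1, lp_cutoff / (sample_rate / 2), type = "low")
  sm <- as.numeric(signal::filtfilt(lp, la))
  exp(sm[pad + seq_len(n)])
}

#' Non-overlapping max pooling of a vector
#'
#' @param x Numeric vector.
#' @param region Window size in samples (>= 1); output length is
#'   `ceiling(length(x) / region)`.
#' @export
maxpool_vector <- function(x, region) {
  region <- as.integer(region)
  if (region < 1L) stop("pool region must be >= 1")
  n_out <- ceiling(length(x) / region)
  grp <- rep(seq_len(n_out), each = region)[seq_along(x)]
  as.numeric(tapply(x, grp, max))
}

#' Build the normalized envelope matrix of a recording
#'
#' Each complete cardiac cycle's homomorphic envelope is max-pooled over
#' non-overlapping windows of `pool_region` samples, log-transformed to a
#' reference-envelope row, linearly resampled to `n_columns` so rows
#' align, and stacked into a matrix `Q`. The result is centralized and
#' amplitude-normalized: `G = (Q - mean(Q)) / max|Q - mean(Q)|`, so
#' `mean(G) = 0` and `max|G| = 1`.
#'
#' @param record A [pcg_record()].
#' @param segmap A [segment_map()] with at least one complete cycle
#'   (frame resolution; its `hop` converts frames to samples).
#' @param pool_region Max-pooling window in samples (>= 3).
#' @param n_columns Common row length; default the median pooled cycle
#'   length.
#' @return An `envelope_matrix`: list with `G` (cycles x n_columns), `Q`,
#'   `He` (full-record envelope), `pool_region`, `cycle_bounds_frames`.
#' @export
build_envelope_matrix <- function(record, segmap, pool_region = 3L,
                                  n_columns = NULL) {
  if (pool_region < 3L) stop("pool_region must be >= 3")
  hop <- segmap$hop
  if (is.na(hop)) stop("segment map lacks frame hop information")
  cs <- cycle_starts(segmap)
  if (length(cs) == 0L) stop("no cycle: segment map has no complete cycle")
  ce <- attr(cs, "ends")
  He <- homomorphic_envelope(record$samples, record$sampling_rate)
  n <- length(He)
  rows <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    lo <- cs[i] * hop + 1L
    hi <- min(ce[i] * hop, n)
    pooled <- maxpool_vector(He[lo:hi], pool_region)
    rows[[i]] <- log(pmax(pooled, 1e-12))
  }
  if (is.null(n_columns)) {
    n_columns <- as.integer(round(stats::median(lengths(rows))))
  }
  Q <- t(vapply(rows, function(r) resample_row(r, n_columns),
                numeric(n_columns)))
  if (length(rows) == 1L) Q <- matrix(Q, nrow = 1L)
  Qc <- Q - mean(Q)
  denom <- max(abs(Qc))
  G <- if (denom > 0) Qc / denom else Qc
  structure(
    list(G = G, Q = Q, He = He, pool_region = as.integer(pool_region),
         cycle_bounds_frames = cbind(start = as.integer(cs),
                                     end = as.integer(ce))),
    class = "envelope_matrix"
  )
}

# linear interpolation of a row to a fixed number of columns
resample_row <- function(r, n_out) {
  if (length(r) == 1L) return(rep(r, n_out))
  stats::approx(seq_along(r), r, n = n_out)$y
}
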