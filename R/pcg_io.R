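#' Construct a PCG recording object
#'
#' The in-memory container for one phonocardiogram: a numeric sample
#' vector, its sampling rate, and optionally a class label and synchronized
#' ECG fiducials (R-peak and T-wave-end sample indices). All sample indices
#' are 0-based.
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param record_id Identifier string.
#' @param label Optional class label, `"normal"` or `"chd"`.
#' @param r_peaks,t_ends Optional integer vectors of 0-based sample indices
#'   of ECG R peaks / T-wave ends, strictly increasing and within range.
#' @return An object of class `pcg_record`.
#' @export
pcg_record <- function(samples, sampling_rate, record_id = "pcg",
                       label = NULL, r_peaks = NULL, t_ends = NULL) {
  if (is.null(sampling_rate) || !is.numeric(sampling_rate) ||
      length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (!is.null(label)) {
    label <- match.arg(tolower(label), c("normal", "chd"))
  }
  check_fiducials <- function(idx, what) {
    if (is.null(idx)) return(NULL)
    idx <- as.integer(idx)
    if (any(idx < 0L) || any(idx >= length(samples))) {
      stop(what, " indices out of range [0, n_samples)")
    }
    if (is.unsorted(idx, strictly = TRUE)) {
      stop(what, " indices must be strictly increasing")
    }
    idx
  }
  structure(
    list(
      samples = samples,
      sampling_rate = as.numeric(sampling_rate),
      record_id = as.character(record_id),
      label = label,
      r_peaks = check_fiducials(r_peaks, "r_peaks"),
      t_ends = check_fiducials(t_ends, "t_ends")
    ),
    class = "pcg_record"
  )
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf(
    "<pcg_record '%s'> %d samples @ %g Hz (%.2f s)%s%s\n",
    x$record_id, length(x$samples), x$sampling_rate,
    length(x$samples) / x$sampling_rate,
    if (!is.null(x$label)) paste0(", label=", x$label) else "",
    if (!is.null(x$r_peaks)) sprintf(", %d R peaks", length(x$r_peaks)) else ""
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param record A [pcg_record()].
#' @export
pcg_duration <- function(record) length(record$samples) / record$sampling_rate

#' Resample a PCG recording
#'
#' Polyphase resampling (via [signal::resample()]) with anti-alias
#' filtering when downsampling. ECG fiducial indices are rescaled to the
#' new rate.
#'
#' @param record A [pcg_record()].
#' @param target_rate New sampling rate in Hz (> 0).
#' @return A resampled [pcg_record()].
#' @export
pcg_resample <- function(record, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("target_rate must be a single positive number")
  }
  if (target_rate == record$sampling_rate) return(record)
  fr <- as_fraction(target_rate / record$sampling_rate)
  y <- signal::resample(record$samples, fr$p, fr$q)
  n_out <- as.integer(round(length(record$samples) * target_rate /
                              record$sampling_rate))
  y <- y[seq_len(min(n_out, length(y)))]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  scale_idx <- function(idx) {
    if (is.null(idx)) return(NULL)
    pmin(as.integer(round(idx * target_rate / record$sampling_rate)),
         n_out - 1L)
  }
  pcg_record(y, target_rate, record_id = record$record_id,
             label = record$label,
             r_peaks = scale_idx(record$r_peaks),
             t_ends = scale_idx(record$t_ends))
}

# small rational approximation for resampling ratios
as_fraction <- function(r, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("cannot express rate ratio ", r, " as a small fraction")
}

#' Slice a signal into overlapping analysis frames
#'
#' Frame `i` (0-based) covers samples `[i*hop, i*hop + frame_length)`; a
#' trailing partial frame is dropped. The window function is applied to
#' each frame.
#'
#' @param x Numeric vector, or a [pcg_record()].
#' @param frame_length Frame length in samples.
#' @param hop Hop (frame advance) in samples, `0 < hop <= frame_length`.
#' @param window Window name: `"hamming"`, `"hanning"` or `"rectangular"`.
#' @return A `frame_set`: list with `frames` (frame_length x n_frames
#'   matrix, window applied), `frame_length`, `hop`, `window`,
#'   `sampling_rate` (if known).
#' @export
frame_signal <- function(x, frame_length, hop, window = "hamming") {
  sampling_rate <- NA_real_
  if (inherits(x, "pcg_record")) {
    sampling_rate <- x$sampling_rate
    x <- x$samples
  }
  frame_length <- as.integer(frame_length)
  hop <- as.integer(hop)
  n <- length(x)
  if (frame_length > n) stop("frame_length (", frame_length,
                             ") exceeds signal length (", n, ")")
  if (hop <= 0L || hop > frame_length) stop("need 0 < hop <= frame_length")
  n_frames <- (n - frame_length) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(frame_length), starts, `+`)
  frames <- matrix(x[idx], nrow = frame_length)
  w <- window_vector(window, frame_length)
  frames <- frames * w
  structure(
    list(frames = frames, frame_length = frame_length, hop = hop,
         window = window, sampling_rate = sampling_rate),
    class = "frame_set"
  )
}

window_vector <- function(window, n) {
  switch(match.arg(window, c("hamming", "hanning", "rectangular")),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    hanning = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    rectangular = rep(1, n)
  )
}

#' Number of frames in a frame set
#' @param fs A `frame_set`.
#' @export
n_frames <- function(fs) ncol(fs$frames)

#' Read a dataset manifest
#'
#' @param path CSV with columns `path,label`; relative paths are resolved
#'   against the manifest's directory.
#' @return A data.frame with absolute `path`, `label`, and `fiducials`
#'   (path to the fiducial CSV when present next to the WAV, else NA).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m))) {
    stop("manifest must have columns 'path' and 'label'")
  }
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                file.path(base, m$path))
  fid <- sub("\\.wav$", "_fiducials.csv", abs)
  m$path <- abs
  m$fiducials <- ifelse(file.exists(fid), fid, NA_character_)
  m
}

#' Read ECG fiducials for a record
#'
#' @param path CSV with columns `sample_index,kind` where kind is `R` or
#'   `Tend`; indices are 0-based sample positions.
#' @return List with integer vectors `r_peaks` and `t_ends`.
#' @export
read_fiducials <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_index", "kind") %in% names(f))) {
    stop("fiducial file must have columns 'sample_index' and 'kind'")
  }
  list(
    r_peaks = sort(as.integer(f$sample_index[f$kind == "R"])),
    t_ends = sort(as.integer(f$sample_index[f$kind == "Tend"]))
  )
}

#' Load a manifest row as a pcg_record
#'
#' @param row One row of [read_manifest()] output.
#' @param target_rate Optional rate to resample to after reading.
#' @export
load_record <- function(row, target_rate = NULL) {
  rec <- read_wav(row$path)
  if (!is.na(row$fiducials)) {
    fid <- read_fiducials(row$fiducials)
    rec <- pcg_record(rec$samples, rec$sampling_rate,
                      record_id = rec$record_id, label = row$label,
                      r_peaks = fid$r_peaks, t_ends = fid$t_ends)
  } else {
    rec$label <- match.arg(tolower(row$label), c("normal", "chd"))
  }
  if (!is.null(target_rate)) rec <- pcg_resample(rec, target_rate)
  rec
}
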