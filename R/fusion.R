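#' Detect elevated-energy frames within each cardiac cycle
#'
#' Frame energy is the channel mean of the MFSC matrix. For each cardiac
#' cycle the threshold is the mean frame energy over that cycle; a
#' sliding window of `window` seconds (stride one frame) whose mean
#' energy strictly exceeds the threshold marks all of its frames as
#' high-energy. The mask is the union over window positions. This gates
#' where S1 and S2 (the loud, information-rich phases) sit.
#'
#' @param M An `mfsc_matrix` (frames x channels) or plain matrix.
#' @param cycles Integer matrix/data.frame with columns `start`,`end`
#'   (0-based half-open frame bounds of complete cycles), e.g.
#'   `cycle_bounds_frames` from [build_envelope_matrix()], or a
#'   [segment_map()].
#' @param window Sliding-window length in seconds (default 0.2).
#' @param hop Frame hop in samples (taken from `M`'s attributes when
#'   absent).
#' @param sampling_rate Sampling rate in Hz (ditto).
#' @return Logical per-frame mask; frames outside complete cycles are
#'   `FALSE`.
#' @export
detect_high_energy <- function(M, cycles, window = 0.2,
                               hop = attr(M, "hop"),
                               sampling_rate = attr(M, "sampling_rate")) {
  if (window <= 0) stop("window must be > 0")
  if (inherits(cycles, "segment_map")) {
    cs <- cycle_starts(cycles)
    cycles <- cbind(start = as.integer(cs), end = as.integer(attr(cs, "ends")))
  }
  cycles <- as.matrix(cycles)
  energy <- rowMeans(unclass(M))
  n_fr <- length(energy)
  w <- max(1L, as.integer(round(window * sampling_rate / hop)))
  mask <- rep(FALSE, n_fr)
  for (i in seq_len(nrow(cycles))) {
    lo <- cycles[i, 1] + 1L
    hi <- min(cycles[i, 2], n_fr)
    len <- hi - lo + 1L
    if (len <= 0L) next
    if (w > len) stop("window (", w, " frames) longer than cycle (", len,
                      " frames)")
    e <- energy[lo:hi]
    thr <- mean(e)
    cm <- cumsum(c(0, e))
    wm <- (cm[(w + 1L):(len + 1L)] - cm[1:(len - w + 1L)]) / w
    hit <- which(wm > thr)
    for (s in hit) mask[(lo + s - 1L):(lo + s + w - 2L)] <- TRUE
  }
  mask
}

#' Energy-gated local overlay of two feature maps
#'
#' Where the high-energy mask is true the maps are summed
#' (`W = M + G`); elsewhere they are averaged (`W = (M + G)/2`). No other
#' transformation is applied.
#'
#' @param M,G Equal-shape matrices (frames x channels).
#' @param mask Logical per-frame vector, length `nrow(M)`.
#' @return A `fused_map`: the fused matrix `W` with attributes
#'   `high_energy_mask`, `hop`, `sampling_rate`.
#' @export
local_overlay <- function(M, G, mask) {
  Mm <- unclass(M); Gm <- unclass(G)
  attributes(Mm) <- list(dim = dim(Mm))
  attributes(Gm) <- list(dim = dim(Gm))
  if (!identical(dim(Mm), dim(Gm))) {
    stop(sprintf("shape mismatch: M is %dx%d but G is %dx%d",
                 nrow(Mm), ncol(Mm), nrow(Gm), ncol(Gm)))
  }
  if (length(mask) != nrow(Mm)) stop("mask length must equal frame count")
  S <- Mm + Gm
  W <- S / 2
  W[mask, ] <- S[mask, ]
  attr(W, "high_energy_mask") <- mask
  attr(W, "hop") <- attr(M, "hop")
  attr(W, "sampling_rate") <- attr(M, "sampling_rate")
  class(W) <- c("fused_map", "matrix")
  W
}

#' Broadcast a per-cycle envelope matrix onto the MFSC frame grid
#'
#' The envelope matrix has one row per cardiac cycle (columns = position
#' within the cycle). Each MFSC frame inside a complete cycle is mapped
#' to its cycle row and within-cycle position; the scalar envelope value
#' there is replicated across all MFSC channels. Frames outside complete
#' cycles get 0 (the centered envelope's mean level).
#'
#' @param env An `envelope_matrix` from [build_envelope_matrix()].
#' @param n_frames Number of MFSC frames.
#' @param n_channels Number of MFSC channels.
#' @return n_frames x n_channels matrix.
#' @export
envelope_frame_map <- function(env, n_frames, n_channels) {
  g <- numeric(n_frames)
  cb <- env$cycle_bounds_frames
  n_col <- ncol(env$G)
  for (i in seq_len(nrow(cb))) {
    lo <- cb[i, "start"] + 1L
    hi <- min(cb[i, "end"], n_frames)
    if (lo > hi) next
    pos <- seq(lo, hi)
    frac <- (pos - lo) / max(hi - lo, 1L)
    col <- pmin(n_col, 1L + as.integer(round(frac * (n_col - 1L))))
    g[pos] <- env$G[i, col]
  }
  matrix(g, nrow = n_frames, ncol = n_channels)
}

#' Fuse MFSC and envelope features for one recording
#'
#' Convenience wrapper: builds the frame-aligned envelope map, detects
#' the high-energy (S1/S2) gate, and applies the local overlay. Modes
#' `"mfsc-only"` and `"envelope-only"` pass through a single map for
#' ablation runs.
#'
#' @param M An `mfsc_matrix`.
#' @param env An `envelope_matrix`.
#' @param segmap The [segment_map()] used for `env`.
#' @param mode `"overlay"`, `"mfsc-only"`, or `"envelope-only"`.
#' @param window High-energy window in seconds.
#' @return A `fused_map` matrix.
#' @export
fuse_features <- function(M, env, segmap,
                          mode = c("overlay", "mfsc-only", "envelope-only"),
                          window = 0.2) {
  mode <- match.arg(mode)
  Gmap <- envelope_frame_map(env, nrow(M), ncol(M))
  if (mode == "mfsc-only") {
    W <- unclass(M); attributes(W) <- list(dim = dim(W))
  } else if (mode == "envelope-only") {
    W <- Gmap
  } else {
    mask <- detect_high_energy(M, env$cycle_bounds_frames, window = window)
    return(local_overlay(M, Gmap, mask))
  }
  attr(W, "hop") <- attr(M, "hop")
  attr(W, "sampling_rate") <- attr(M, "sampling_rate")
  class(W) <- c("fused_map", "matrix")
  W
}

#' Write / read a feature matrix with a JSON sidecar
#'
#' The matrix goes to a plain-text TSV; axis metadata (hop, sampling
#' rate, mask) to `<path>.json`.
#'
#' @param W Matrix (possibly `fused_map`/`mfsc_matrix`).
#' @param path Output TSV path.
#' @export
write_feature_map <- function(W, path) {
  utils::write.table(unclass(W), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    n_frames = nrow(W), n_channels = ncol(W),
    hop = attr(W, "hop"), sampling_rate = attr(W, "sampling_rate"),
    high_energy_mask = attr(W, "high_energy_mask")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_feature_map
#' @export
read_feature_map <- function(path) {
  W <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(W) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(W, "hop") <- meta$hop
    attr(W, "sampling_rate") <- meta$sampling_rate
    if (!is.null(meta$high_energy_mask)) {
      attr(W, "high_energy_mask") <- meta$high_energy_mask
    }
  }
  W
}
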