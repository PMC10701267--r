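#' Specification for a synthetic phonocardiogram
#'
#' Describes one synthetic PCG recording: quasi-periodic cardiac cycles of
#' `cycle_mean` seconds (per-cycle Gaussian jitter truncated at three
#' standard deviations), S1 and S2 tone bursts with Gaussian envelopes,
#' an optional class-dependent murmur, and additive white noise.
#'
#' Defaults follow pediatric auscultation: a cardiac cycle of about 0.8 s
#' with S1 and S2 each lasting about 0.2 s. S1 is centered at the cycle
#' onset (where the ECG R peak falls) and S2 begins about 40% into the
#' cycle, so the systolic gap is shorter than the diastolic gap, as in a
#' real cardiac cycle.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param duration Recording length, s.
#' @param cycle_mean Mean cardiac cycle length, s.
#' @param cycle_jitter_sd Per-cycle standard deviation of cycle length, s.
#' @param s1_duration,s2_duration Burst lengths of S1 and S2, s.
#' @param s1_freq,s2_freq Dominant burst frequencies, Hz.
#' @param murmur_kind `"none"`, `"systolic"` (band-limited noise between S1
#'   and S2) or `"continuous"` (spanning the whole cycle).
#' @param murmur_snr Heart-sound-to-murmur power ratio, dB (smaller =
#'   louder murmur).
#' @param noise_snr Signal-to-background-noise power ratio, dB.
#' @param seed Integer seed; identical specs give bit-identical output.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(sampling_rate = 2000, duration = 10,
                       cycle_mean = 0.8, cycle_jitter_sd = 0.02,
                       s1_duration = 0.2, s2_duration = 0.2,
                       s1_freq = 50, s2_freq = 70,
                       murmur_kind = c("none", "systolic", "continuous"),
                       murmur_snr = 6, noise_snr = 20, seed = 1L) {
  spec <- list(
    sampling_rate = sampling_rate, duration = duration,
    cycle_mean = cycle_mean, cycle_jitter_sd = cycle_jitter_sd,
    s1_duration = s1_duration, s2_duration = s2_duration,
    s1_freq = s1_freq, s2_freq = s2_freq,
    murmur_kind = match.arg(murmur_kind),
    murmur_snr = murmur_snr, noise_snr = noise_snr,
    seed = as.integer(seed)
  )
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

validate_synth_spec <- function(spec) {
  pos <- c("sampling_rate", "duration", "cycle_mean",
           "s1_duration", "s2_duration", "s1_freq", "s2_freq")
  for (f in pos) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("synth_spec field '", f, "' must be a single positive number")
    }
  }
  if (spec$cycle_jitter_sd < 0) stop("synth_spec field 'cycle_jitter_sd' must be >= 0")
  if (spec$cycle_mean <= spec$s1_duration + spec$s2_duration) {
    stop("synth_spec field 'cycle_mean' must exceed s1_duration + s2_duration")
  }
  invisible(spec)
}

# fraction of the inter-burst gap assigned to systole (rest is diastole);
# systole is physiologically the shorter interval
SYSTOLIC_GAP_FRACTION <- 0.3
S1_AMPLITUDE <- 1.0
S2_AMPLITUDE <- 0.8
T_END_LEAD <- 0.02  # T-wave end precedes S2 onset by this many seconds

#' Generate one synthetic heart-sound recording with ground truth
#'
#' Builds the waveform as Gaussian-windowed tone bursts for S1 and S2 in
#' each cycle, a murmur component per `murmur_kind` (zero-mean noise
#' band-passed 100-400 Hz, gated by the systolic window or the whole
#' cycle), and additive white noise at `noise_snr`. Ground truth contains
#' the per-sample phase labels, the ECG fiducials implied by the
#' construction (R peak at each S1 onset, T-wave end just before each S2
#' onset), and the class label (`"chd"` iff a murmur is present).
#'
#' @param spec A [synth_spec()].
#' @return List with `record` (a [pcg_record()]) and `truth` (list with
#'   `states` factor of per-sample labels, `r_peaks`, `t_ends`,
#'   `class_label`, `n_cycles`, `cycle_starts`).
#' @export
gen_heart_sound <- function(spec) {
  spec <- validate_synth_spec(spec)
  fs <- spec$sampling_rate
  n <- as.integer(round(spec$duration * fs))
  set.seed(spec$seed)

  # per-cycle lengths with truncated Gaussian jitter
  max_cycles <- ceiling(spec$duration / max(spec$cycle_mean -
                          3 * spec$cycle_jitter_sd, 1e-6)) + 2L
  jit <- stats::rnorm(max_cycles, 0, spec$cycle_jitter_sd)
  jit <- pmin(pmax(jit, -3 * spec$cycle_jitter_sd), 3 * spec$cycle_jitter_sd)
  cycle_len <- pmax(spec$cycle_mean + jit,
                    spec$s1_duration + spec$s2_duration + 0.05)
  starts <- cumsum(c(0, cycle_len))

  hs <- numeric(n)
  states <- rep(4L, n)  # default diastole for any tail samples
  r_peaks <- integer(0)
  t_ends <- integer(0)
  cycle_starts <- integer(0)
  tt <- (seq_len(n) - 1) / fs

  burst <- function(center, dur, freq, amp) {
    sigma <- dur / 6
    lo <- max(1L, floor((center - dur) * fs) + 1L)
    hi <- min(n, ceiling((center + dur) * fs) + 1L)
    if (lo > hi) return(invisible(NULL))
    t_loc <- tt[lo:hi] - center
    hs[lo:hi] <<- hs[lo:hi] +
      amp * exp(-t_loc^2 / (2 * sigma^2)) * sin(2 * pi * freq * t_loc)
    invisible(NULL)
  }

  i <- 1L
  while (starts[i] * fs < n - 0.5) {
    s0 <- starts[i]
    L <- cycle_len[i]
    gap <- L - spec$s1_duration - spec$s2_duration
    sys_dur <- SYSTOLIC_GAP_FRACTION * gap
    s1_on <- s0
    s1_off <- s0 + spec$s1_duration
    s2_on <- s1_off + sys_dur
    s2_off <- s2_on + spec$s2_duration
    complete <- (s0 + L) * fs <= n + 0.5

    burst(s1_on + spec$s1_duration / 2, spec$s1_duration, spec$s1_freq,
          S1_AMPLITUDE)
    burst(s2_on + spec$s2_duration / 2, spec$s2_duration, spec$s2_freq,
          S2_AMPLITUDE)

    idx <- function(t) as.integer(floor(t * fs))
    seg <- function(a, b, code) {
      lo <- max(0L, idx(a)); hi <- min(n - 1L, idx(b) - 1L)
      if (lo <= hi) states[(lo:hi) + 1L] <<- code
    }
    seg(s1_on, s1_off, 1L)
    seg(s1_off, s2_on, 2L)
    seg(s2_on, s2_off, 3L)
    seg(s2_off, s0 + L, 4L)

    # ECG fiducials exist even for a cycle the recording cuts short
    if (idx(s1_on) < n) r_peaks <- c(r_peaks, idx(s1_on))
    if (idx(s2_on - T_END_LEAD) < n) {
      t_ends <- c(t_ends, idx(s2_on - T_END_LEAD))
    }
    if (complete) cycle_starts <- c(cycle_starts, idx(s1_on))
    i <- i + 1L
  }

  # murmur component
  murmur <- numeric(n)
  if (spec$murmur_kind != "none") {
    raw <- stats::rnorm(n)
    bp <- signal::butter(2, c(100, 400) / (fs / 2), type = "pass")
    band <- as.numeric(signal::filter(bp, raw))
    gate <- if (spec$murmur_kind == "continuous") {
      rep(1, n)
    } else {
      g <- numeric(n)
      for (k in seq_len(i - 1L)) {
        a <- starts[k] + spec$s1_duration
        b <- a + SYSTOLIC_GAP_FRACTION *
          (cycle_len[k] - spec$s1_duration - spec$s2_duration)
        lo <- max(1L, floor(a * fs) + 1L)
        hi <- min(n, floor(b * fs))
        if (lo <= hi) g[lo:hi] <- 1
      }
      g
    }
    band <- band * gate
    p_band <- mean(band^2)
    p_hs <- mean(hs^2)
    if (p_band > 0) {
      murmur <- band * sqrt(p_hs / p_band / 10^(spec$murmur_snr / 10))
    }
  }

  clean <- hs + murmur
  p_clean <- mean(clean^2)
  noise <- stats::rnorm(n) * sqrt(p_clean / 10^(spec$noise_snr / 10))
  x <- clean + noise
  x <- x / max(abs(x)) * 0.9

  label <- if (spec$murmur_kind == "none") "normal" else "chd"
  record <- pcg_record(x, fs, record_id = sprintf("synth_seed%d", spec$seed),
                       label = label, r_peaks = r_peaks, t_ends = t_ends)
  truth <- list(
    states = factor(pcg_states()[states], levels = pcg_states()),
    r_peaks = r_peaks,
    t_ends = t_ends,
    class_label = label,
    n_cycles = length(cycle_starts),
    cycle_starts = cycle_starts
  )
  list(record = record, truth = truth)
}

#' Canonical ordering of the four heart-sound phases
#' @return `c("S1", "systole", "S2", "diastole")`.
#' @export
pcg_states <- function() c("S1", "systole", "S2", "diastole")

#' Generate a labeled synthetic dataset on disk
#'
#' Writes one 16-bit WAV and one ECG-fiducial CSV per record plus a
#' manifest CSV (`path,label`). Normal records carry no murmur; CHD
#' records carry `chd_murmur`. Per-record seeds are derived
#' deterministically from `seed` by counter-based splitting, so the same
#' call always produces byte-identical files.
#'
#' @param n_normal,n_chd Number of records per class (>= 0).
#' @param out_dir Output directory (created if needed).
#' @param spec_template A [synth_spec()] whose non-murmur fields are used
#'   for every record.
#' @param seed Top-level integer seed.
#' @param chd_murmur Murmur kind for the CHD class.
#' @return Path of the manifest CSV, invisibly; the manifest data.frame
#'   as attribute `"manifest"`.
#' @export
gen_dataset <- function(n_normal, n_chd, out_dir,
                        spec_template = synth_spec(), seed = 1L,
                        chd_murmur = c("systolic", "continuous")) {
  if (n_normal < 0 || n_chd < 0) stop("record counts must be >= 0")
  chd_murmur <- match.arg(chd_murmur)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  labels <- c(rep("normal", n_normal), rep("chd", n_chd))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- spec_template
    sp$seed <- derive_seed(seed, i)
    sp$murmur_kind <- if (labels[i] == "chd") chd_murmur else "none"
    class(sp) <- "synth_spec"
    g <- gen_heart_sound(sp)
    id <- sprintf("%s_%03d", labels[i], i)
    wav <- file.path(out_dir, paste0(id, ".wav"))
    write_wav(g$record, wav)
    fid <- data.frame(
      sample_index = c(g$truth$r_peaks, g$truth$t_ends),
      kind = c(rep("R", length(g$truth$r_peaks)),
               rep("Tend", length(g$truth$t_ends)))
    )
    fid <- fid[order(fid$sample_index), ]
    utils::write.csv(fid, file.path(out_dir, paste0(id, "_fiducials.csv")),
                     row.names = FALSE)
    rows[[i]] <- data.frame(path = paste0(id, ".wav"), label = labels[i])
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), label = character(0))
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(structure(manifest_path, manifest = manifest))
}

# counter-based per-record stream: deterministic, order-independent
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 100003 + index * 7919) %% 2147483647)
}
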