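#' Extract the fused feature map of one recording
#'
#' Runs the full per-record feature chain: frame the signal, compute the
#' MFSC matrix, segment the recording (ECG-guided when fiducials are
#' present, otherwise with the supplied duration-constrained HMM), build
#' the per-cycle envelope matrix, and apply the energy-gated local
#' overlay.
#'
#' @param record A [pcg_record()].
#' @param dhmm Optional `duration_hmm` used when the record has no ECG
#'   fiducials.
#' @param mode Fusion mode passed to [fuse_features()].
#' @param frame_ms,hop_ms Frame length / hop in milliseconds.
#' @param n_filters,fft_size,f_lo,f_hi Mel filter-bank settings.
#' @param pool_region Envelope max-pooling region in samples.
#' @return A `fused_map` matrix (frames x Mel channels); the segment map
#'   is attached as attribute `"segmap"`.
#' @export
extract_feature_map <- function(record, dhmm = NULL,
                                mode = c("overlay", "mfsc-only",
                                         "envelope-only"),
                                frame_ms = 25, hop_ms = 10,
                                n_filters = 64L, fft_size = 512L,
                                f_lo = 25, f_hi = NULL,
                                pool_region = 3L) {
  mode <- match.arg(mode)
  fs_hz <- record$sampling_rate
  if (is.null(f_hi)) f_hi <- fs_hz / 2
  frame_length <- round(frame_ms / 1000 * fs_hz)
  hop <- round(hop_ms / 1000 * fs_hz)
  segmap <- if (!is.null(record$r_peaks) && length(record$r_peaks) >= 2L) {
    label_from_ecg(record, hop = hop, frame_length = frame_length)
  } else if (!is.null(dhmm)) {
    dhmm_segment(record, dhmm, frame_length = frame_length, hop = hop)
  } else {
    stop("record has no ECG fiducials and no segmentation model was given")
  }
  fr <- frame_signal(record, frame_length, hop)
  bank <- build_mel_bank(n_filters, fft_size, fs_hz, f_lo, f_hi)
  M <- mfsc(fr, bank)
  env <- build_envelope_matrix(record, segmap, pool_region = pool_region)
  W <- fuse_features(M, env, segmap, mode = mode)
  attr(W, "segmap") <- segmap
  W
}

#' Extract feature maps for a whole manifest
#'
#' @param manifest Data frame from [read_manifest()].
#' @param target_rate Common sampling rate records are resampled to.
#' @param ... Passed to [extract_feature_map()].
#' @return List with `maps` (list of matrices), `labels` (0/1 vector)
#'   and `ids`.
#' @export
extract_dataset_features <- function(manifest, target_rate = 2000, ...) {
  maps <- vector("list", nrow(manifest))
  labels <- integer(nrow(manifest))
  ids <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- load_record(manifest[i, ], target_rate = target_rate)
    maps[[i]] <- extract_feature_map(rec, ...)
    labels[i] <- as.integer(identical(rec$label, "chd"))
    ids[i] <- rec$record_id
  }
  list(maps = maps, labels = labels, ids = ids)
}

#' Stratified train/test/validation split
#'
#' @param labels 0/1 vector.
#' @param fractions Length-3 vector `(train, test, validation)` summing
#'   to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `test`, `validation`.
#' @export
split_dataset <- function(labels, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  set.seed(seed)
  idx <- list(train = integer(0), test = integer(0), validation = integer(0))
  for (cl in unique(labels)) {
    pool <- sample(which(labels == cl))
    n <- length(pool)
    n_train <- round(fractions[1] * n)
    n_test <- round(fractions[2] * n)
    idx$train <- c(idx$train, pool[seq_len(n_train)])
    idx$test <- c(idx$test, pool[n_train + seq_len(min(n_test, n - n_train))])
    rest <- pool[-seq_len(min(n_train + n_test, n))]
    idx$validation <- c(idx$validation, rest)
  }
  lapply(idx, sort)
}

#' Run the full screening experiment on a synthetic cohort
#'
#' Generates `n_normal + n_chd` recordings, extracts fused feature maps,
#' splits 70/20/10 stratified by class, trains the classifier, and
#' evaluates on the held-out test split.
#'
#' @param n_normal,n_chd Cohort sizes.
#' @param config An [lcacnn_config()].
#' @param mode Fusion mode.
#' @param spec_template Generator settings ([synth_spec()]).
#' @param seed Master seed (generation, split, training).
#' @param fractions Split fractions.
#' @param out_dir Directory for the generated WAV dataset; a temporary
#'   directory by default.
#' @return List with `report` (test-split [eval_report()]), `model`,
#'   `split`, `probabilities`, `labels`.
#' @export
run_experiment <- function(n_normal = 100L, n_chd = 100L,
                           config = lcacnn_config(epochs = 25L),
                           mode = "overlay",
                           spec_template = synth_spec(),
                           seed = 1L,
                           fractions = c(0.7, 0.2, 0.1),
                           out_dir = NULL) {
  if (is.null(out_dir)) {
    out_dir <- tempfile("pcg_cohort_")
    on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  }
  manifest_path <- gen_dataset(n_normal, n_chd, out_dir,
                               spec_template = spec_template, seed = seed)
  manifest <- read_manifest(manifest_path)
  feats <- extract_dataset_features(manifest, mode = mode)
  split <- split_dataset(feats$labels, fractions, seed = seed)
  x_train <- stack_model_inputs(feats$maps[split$train], config$input_shape)
  y_train <- feats$labels[split$train]
  config$seed <- seed
  model <- train_lcacnn(x_train, y_train, config)
  x_test <- stack_model_inputs(feats$maps[split$test], config$input_shape)
  y_test <- feats$labels[split$test]
  p <- predict(model, x_test)
  report <- eval_report(confusion_counts(y_test, p))
  list(report = report, model = model, split = split,
       probabilities = p, labels = y_test,
       history = attr(model, "history"))
}
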