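# Shared synthetic fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_record <- function(seed = 3) {
  fixture(paste0("rec_", seed), function() {
    gen_heart_sound(synth_spec(seed = seed))
  })
}

# frame-level ground-truth states matching the default feature geometry
truth_frames <- function(g, frame_length = 50L, hop = 20L) {
  centers <- phonoscreen:::frame_center_samples(length(g$record$samples),
                                                hop, frame_length)
  as.character(g$truth$states[centers + 1L])
}

fitted_dhmm <- function() {
  fixture("dhmm", function() {
    labeled <- lapply(1:3, function(s) {
      g <- gen_heart_sound(synth_spec(seed = s))
      list(features = segmentation_features(g$record),
           segmap = label_from_ecg(g$record))
    })
    fit_dhmm(labeled)
  })
}
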