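# Shared trained-detector fixture, built once per test run and reused by
# the detector benchmark and end-to-end recovery tests. The training setup
# (200 positives, 400 negatives, 50 epochs) is the study condition of the
# synthetic benchmark, not a per-test knob.

.detector_fixture <- new.env(parent = emptyenv())

get_detector_fixture <- function() {
  if (!is.null(.detector_fixture$fx)) return(.detector_fixture$fx)
  cfg <- synthesis_config(seed = 101)
  tr <- synth_training_segments(cfg, 200, 400, seed = 102)
  ho <- synth_training_segments(cfg, 80, 160, seed = 103)
  model <- build_model(seed = 104)
  model <- train(model, tr$segments, tr$labels,
                 train_config(epochs = 50, seed = 104))
  scores <- vapply(ho$segments,
                   function(s) max(predict_frames(model, s)$prob), 0)
  r <- roc(scores, ho$labels)
  .detector_fixture$fx <- list(model = model, synth = cfg,
                               holdout = ho, scores = scores, roc = r,
                               balance = balance_threshold(r))
  .detector_fixture$fx
}

# compressed mel spectrogram of a clean, centered pulse (template source)
clean_pulse_spectrogram <- function(cfg, seed) {
  set.seed(seed)
  type <- sample(c("A", "B"), 1)
  pw <- synth_pulse(cfg$models[[type]], cfg$sampling_rate)
  seg <- numeric(2 * cfg$sampling_rate)
  i0 <- cfg$sampling_rate - round(length(pw) / 2)
  seg[i0:(i0 + length(pw) - 1)] <- pw
  compress(mel_spectrogram(seg, frontend_config())$mel, 0)
}
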