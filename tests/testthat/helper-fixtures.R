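# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fixture_truth <- function(lat = c(120, 280, 420), amp = c(12, 8, 7)) {
  tibble::tibble(component = c("P1", "N290", "P400"), latency = lat,
                 amp = amp)
}

# a small noiseless session reused by several files
fixture_clean_session <- function() {
  cached("clean_session", function() {
    co <- cohort_spec(1, n_sessions = 1, trials_checkerboard = 16,
                      trials_face_upright = 16, trials_face_inverted = 16,
                      noise_sd = 0, artifact_rate_amp = 0,
                      artifact_rate_flat = 0, gaze_gap_rate = 0.1)
    ses <- simulate_session(co, default_components(), fixture_truth(),
                            seed = 42)
    ses$prep_cb <- preprocess_trials(ses$recording, ses$events, "checkerboard")
    ses$prep_f <- preprocess_trials(ses$recording, ses$events, "faces")
    ses
  })
}

make_bump_wave <- function(lat = 120, amp = 10, width = 20,
                           time_axis = seq(-100, 600, by = 2)) {
  erp_waveform(amp * exp(-(time_axis - lat)^2 / (2 * width^2)), time_axis)
}

# hand-built 10-trial artifact fixture (checkerboard family):
#   trial 1  Oz spike +151 uV        -> excluded (amplitude)
#   trial 2  Oz spike exactly +150   -> retained (strict "exceeds")
#   trial 3  Oz flat                 -> excluded (flat)
#   trial 4  Cz spike -151           -> retained via mean(C3,C4)
#   trial 5  Cz and C3 spikes        -> excluded (no_reference)
#   trials 6-10 clean                -> retained
#   P8 spikes on trials 1-8 (8/10 = 80% -> channel excluded)
#   P7 spikes on trials 1-7 (7/10      -> channel retained)
fixture_artifact_trialset <- function() {
  fs <- 500
  channels <- c("Cz", "Oz", "C3", "C4", "P7", "P8")
  n_tr <- 10
  iti <- 1.0
  dur <- 10 + n_tr * iti
  n <- dur * fs
  data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  onset <- as.integer((5 + (seq_len(n_tr) - 1) * iti) * fs) + 1L
  # carrier: 5 uV half-sine over 100..400 ms so no channel is flat and the
  # baseline window stays zero
  carrier_idx <- seq(0.1 * fs, 0.4 * fs)
  carrier <- 5 * sin(pi * seq_along(carrier_idx) / length(carrier_idx))
  for (k in seq_len(n_tr)) for (ch in channels)
    data[ch, onset[k] + carrier_idx] <- carrier
  spike <- function(k, ch, val) {
    at <- onset[k] + round(0.2 * fs)
    data[ch, at] <<- val
  }
  spike(1, "Oz", 151)
  spike(2, "Oz", 150)
  data["Oz", onset[3] + carrier_idx] <- 0       # flat Oz on trial 3
  spike(4, "Cz", -151)
  spike(5, "Cz", 151); spike(5, "C3", 151)
  for (k in 1:8) spike(k, "P8", 151)
  for (k in 1:7) spike(k, "P7", 151)
  rec <- eeg_recording(data, fs, channels)
  events <- tibble::tibble(trial_id = seq_len(n_tr), onset_sample = onset,
                           condition = "checkerboard")
  ts <- segment(rec, events, pad = 3, channels = channels)
  ts$epochs <- ts$epochs[, ts$core_index, , drop = FALSE]
  ts$cropped <- TRUE
  for (k in seq_len(n_tr))
    ts$epochs[, , k] <- baseline_correct(ts$epochs[, , k], ts$time_axis)
  flag_artifacts(ts)
}
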