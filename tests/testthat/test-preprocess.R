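test_that("segmentation yields one 351-sample epoch per event", {
  rec <- eeg_recording(matrix(rnorm(2 * 60000), 2), 500, c("Oz", "Cz"))
  ev <- tibble::tibble(trial_id = 1:72,
                       onset_sample = seq(3000, by = 750, length.out = 72),
                       condition = "checkerboard")
  ts <- segment(rec, ev)
  expect_equal(dim(ts$epochs)[3], 72)
  expect_equal(length(ts$core_index), 351)      # (600 - (-100))/2 + 1
  expect_equal(range(ts$time_axis), c(-100, 600))
  expect_false(any(ts$trials$excluded))

  # t = 0 aligned to the onset sample
  k <- 5
  idx <- ev$onset_sample[k] + seq(-50, 300)
  expect_equal(ts$epochs[1, ts$core_index, k], unname(rec$data[1, idx]))

  # onset too close to the start: reflect-padded and logged
  ev2 <- tibble::tibble(trial_id = 1, onset_sample = 200,
                        condition = "checkerboard")
  ts2 <- segment(rec, ev2)
  expect_true(ts2$trials$padded[1])
  expect_false(ts2$trials$excluded[1])

  # onset so close that the core window is cut: excluded with reason
  ev3 <- tibble::tibble(trial_id = 1, onset_sample = 10,
                        condition = "checkerboard")
  ts3 <- segment(rec, ev3)
  expect_true(ts3$trials$excluded[1])
  expect_equal(ts3$trials$reason[1], "edge")

  expect_equal(nrow(segment(rec, ev[0, ])$trials), 0)
})

test_that("band-pass filter matches its designed transfer function", {
  fs <- 500
  n <- 3851                      # 3 s padding around a 0.7 s epoch
  tt <- (0:(n - 1)) / fs
  mid <- 1000:2800
  for (f0 in c(10, 50)) {
    x <- 100 * sin(2 * pi * f0 * tt)
    y <- bandpass_filter(x, fs)
    measured <- sqrt(mean(y[mid]^2)) / (100 / sqrt(2))
    designed <- bandpass_response(f0, fs)
    expect_lt(abs(20 * log10(measured) - 20 * log10(designed)), 1)
  }
  # passband: 10 Hz amplitude preserved within 5%
  x <- sin(2 * pi * 10 * tt)
  expect_lt(abs(max(abs(bandpass_filter(x, fs)[mid])) - 1), 0.05)
  # DC lies in the high-pass stopband; finite-segment step transients decay
  # slowly at a 0.1 Hz edge, so assert strong (not total) attenuation
  expect_lt(max(abs(bandpass_filter(rep(5, n), fs)[mid])), 0.15 * 5)
  expect_error(bandpass_filter(c(1, NA, 3), fs), "non-finite")
})

test_that("DFT line filter cancels listed frequencies and leaves others", {
  fs <- 500
  n <- 4000                       # integer cycles of 50 Hz at 500 Hz
  tt <- (0:(n - 1)) / fs
  x50 <- 37 * sin(2 * pi * 50 * tt + 0.7)
  expect_lt(max(abs(dft_line_filter(x50, fs))), 1e-6)
  x10 <- 5 * sin(2 * pi * 10 * tt)
  expect_lt(max(abs(dft_line_filter(x10, fs) - x10)), 1e-6)
  mix <- x50 + 12 * cos(2 * pi * 100 * tt) + x10
  expect_lt(max(abs(dft_line_filter(mix, fs) - x10)), 1e-6)
  # oracle: explicit normal equations for the same regression
  X <- cbind(sin(2 * pi * 50 * tt), cos(2 * pi * 50 * tt),
             sin(2 * pi * 100 * tt), cos(2 * pi * 100 * tt),
             sin(2 * pi * 150 * tt), cos(2 * pi * 150 * tt))
  beta <- solve(t(X) %*% X, t(X) %*% mix)
  expect_equal(dft_line_filter(mix, fs), as.numeric(mix - X %*% beta),
               tolerance = 1e-8)
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  ta <- seq(-100, 600, by = 2)
  expect_equal(baseline_correct(rep(7, 351), ta), rep(0, 351))
  x <- sin(ta / 50) + 3
  y <- baseline_correct(x, ta)
  expect_lt(abs(mean(y[ta >= -100 & ta <= 0])), 1e-9)
  expect_equal(baseline_correct(y, ta), y)
  m <- rbind(x, 2 * x)
  ym <- baseline_correct(m, ta)
  expect_lt(max(abs(rowMeans(ym[, ta <= 0]))), 1e-9)
  expect_error(baseline_correct(x, ta, c(700, 800)))
})

test_that("artifact flags apply strict thresholds with separate reasons", {
  ts <- fixture_artifact_trialset()
  expect_true(ts$flags[1, "Oz"])
  expect_equal(unname(ts$flag_reason[1, "Oz"]), "amplitude")
  expect_false(ts$flags[2, "Oz"])               # exactly 150 uV retained
  expect_true(ts$flags[3, "Oz"])
  expect_equal(unname(ts$flag_reason[3, "Oz"]), "flat")
  expect_true(ts$flags[4, "Cz"])
  expect_false(any(ts$flags[6:10, c("Oz", "Cz", "C3", "C4")]))
})

test_that("channel exclusion uses the inclusive 80% rule", {
  flags <- matrix(FALSE, 100, 2, dimnames = list(NULL, c("a", "b")))
  flags[1:80, 1] <- TRUE
  flags[1:79, 2] <- TRUE
  expect_equal(exclude_bad_channels(flags), "a")
  expect_length(exclude_bad_channels(matrix(FALSE, 10, 1,
                                            dimnames = list(NULL, "a"))), 0)
})

test_that("hand-built fixture: survivors and exclusions match manual enumeration", {
  ts <- fixture_artifact_trialset()
  bad <- exclude_bad_channels(ts$flags)
  expect_equal(bad, "P8")                       # 8/10 flagged -> excluded
  ts$bad_channels <- bad
  out <- apply_condition_rules(ts, family = "checkerboard")
  expect_equal(which(out$trials$excluded), c(1L, 3L, 5L))
  expect_equal(sum(!out$trials$excluded), 7)
  expect_equal(out$trials$reason[5], "no_reference")
  expect_equal(out$trials$reference_used[4], "mean(C3,C4)")
  expect_equal(out$trials$reference_used[2], "Cz")
})

test_that("re-referencing subtracts the right reference per trial", {
  ts <- fixture_artifact_trialset()
  ts <- rereference(ts, "Oz")
  core <- ts$epochs
  # trial 2: Oz minus Cz
  expect_equal(ts$analysis["Oz", , 2], core["Oz", , 2] - core["Cz", , 2])
  # trial 4: Cz flagged -> minus mean(C3, C4)
  expect_equal(ts$analysis["Oz", , 4],
               core["Oz", , 4] - (core["C3", , 4] + core["C4", , 4]) / 2)
  # flagging is independent of trial/channel order
  expect_error(rereference(ts, "Oz", ref_primary = "Pz"), "absent")
})

test_that("flag set equals injected artifact set on low-noise simulations", {
  co <- cohort_spec(1, n_sessions = 1, trials_checkerboard = 20,
                    trials_face_upright = 20, trials_face_inverted = 20,
                    noise_sd = 0.5, artifact_rate_amp = 0.08,
                    artifact_rate_flat = 0)
  ses <- simulate_session(co, default_components(), fixture_truth(), seed = 21)
  for (fam in c("checkerboard", "faces")) {
    ts <- preprocess_trials(ses$recording, ses$events, fam)
    conds <- if (fam == "checkerboard") "checkerboard"
             else c("face_upright", "face_inverted")
    fam_ids <- ses$events$trial_id[ses$events$condition %in% conds]
    inj <- ses$truth$artifacts
    inj <- inj[inj$trial_id %in% fam_ids & inj$channel %in% ts$channels, ]
    flagged <- which(ts$flags, arr.ind = TRUE)
    got <- tibble::tibble(trial_id = ts$trials$trial_id[flagged[, 1]],
                          channel = ts$channels[flagged[, 2]])
    expect_setequal(paste(got$trial_id, got$channel),
                    paste(inj$trial_id, inj$channel))
  }
})

test_that("flagging is invariant to trial and channel order", {
  ts <- fixture_artifact_trialset()
  perm_t <- c(5, 1, 9, 3, 2, 10, 4, 8, 6, 7)
  perm_c <- c(4, 1, 6, 2, 5, 3)
  ts2 <- ts
  ts2$epochs <- ts2$epochs[perm_c, , perm_t, drop = FALSE]
  ts2$channels <- ts2$channels[perm_c]
  ts2$trials <- ts2$trials[perm_t, ]
  ts2 <- flag_artifacts(ts2)
  expect_equal(unname(ts2$flags), unname(ts$flags[perm_t, perm_c]))
})
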