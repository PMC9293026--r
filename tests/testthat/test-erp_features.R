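test_that("peak detection handles strict maxima, plateaus and monotone runs", {
  p <- detect_peaks(c(0, 1, 0))
  expect_equal(p$index, 2)
  expect_equal(p$polarity, 1L)
  # two-sample plateau: the following sample (X + 1) is the peak
  p <- detect_peaks(c(0, 1, 1, 0))
  expect_equal(p$index, 3)
  # rising plateau is skipped
  expect_equal(nrow(detect_peaks(c(0, 1, 1, 2))), 0)
  expect_equal(nrow(detect_peaks(c(0, 1, 2, 3))), 0)
  # longer plateau: last sample of the run, both polarities
  p <- detect_peaks(c(0, 2, 2, 2, 1))
  expect_equal(p$index, 4)
  n <- detect_peaks(c(0, -3, -3, 0))
  expect_equal(n$polarity, -1L)
  expect_equal(n$index, 3)
  # interior negative plateau between higher endpoints: one peak at its end
  vp <- detect_peaks(c(5, 1, 1, 5))
  expect_equal(vp$index, 3)
  expect_equal(vp$polarity, -1L)
  expect_error(detect_peaks(c(1, 2)), "3 samples")
})

test_that("peak detection equals the brute-force oracle on all 3^6 sequences", {
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 6)))
  for (r in seq_len(nrow(grid))) {
    x <- grid[r, ]
    got <- detect_peaks(x)
    want <- oracle_peaks(x)
    expect_equal(nrow(got), nrow(want), info = paste(x, collapse = ","))
    if (nrow(want)) {
      expect_equal(got$index, as.integer(want[, 2]),
                   info = paste(x, collapse = ","))
      expect_equal(got$polarity, as.integer(want[, 1]),
                   info = paste(x, collapse = ","))
    }
  }
})

test_that("component peak selection picks the largest in-window peak, widening on demand", {
  ta <- seq(-100, 600, by = 2)
  two_bumps <- 4 * exp(-(ta - 80)^2 / 200) + 6 * exp(-(ta - 150)^2 / 200)
  w <- erp_waveform(two_bumps, ta)
  comp <- default_windows()$P1
  pr <- select_component_peak(detect_peaks(w), comp, w)
  expect_equal(pr$latency, 150)
  expect_false(pr$widened)
  # single peak just outside the primary window -> found after widening
  late <- make_bump_wave(lat = 214, width = 6)
  pr2 <- select_component_peak(detect_peaks(late), comp, late)
  expect_true(pr2$valid)
  expect_true(pr2$widened)
  expect_equal(pr2$latency, 214)
  # nothing anywhere in 30-220 ms -> invalid, no_peak
  flat <- erp_waveform(ta * 0.001, ta)   # monotone, no peaks at all
  pr3 <- select_component_peak(detect_peaks(flat), comp, flat)
  expect_false(pr3$valid)
  expect_equal(pr3$reject_reason, "no_peak")
  # negative component: most negative selected
  wn <- erp_waveform(-two_bumps, ta)
  compn <- component_window("N", -1, c(50, 200))
  prn <- select_component_peak(detect_peaks(wn), compn, wn)
  expect_equal(prn$latency, 150)
  expect_equal(prn$point_amp, min(wn$amplitude[ta >= 50 & ta <= 200]))
})

test_that("baseline-noise screen compares same-polarity point amplitudes", {
  ta <- seq(-100, 600, by = 2)
  mk <- function(base_amp, peak_amp) {
    x <- peak_amp * exp(-(ta - 120)^2 / (2 * 15^2)) +
      base_amp * exp(-(ta + 50)^2 / (2 * 10^2))
    erp_waveform(x, ta)
  }
  comp <- default_windows()$P1
  sel <- function(w) select_component_peak(detect_peaks(w), comp, w)
  w_bad <- mk(5, 4)
  expect_false(baseline_noise_check(w_bad, sel(w_bad)))
  w_ok <- mk(0, 4)
  expect_true(baseline_noise_check(w_ok, sel(w_ok)))
  # negative component: -6 exceeds -2 in the negative direction
  wn <- erp_waveform(-6 * exp(-(ta - 270)^2 / (2 * 15^2)) -
                       2 * exp(-(ta + 50)^2 / (2 * 10^2)), ta)
  compn <- default_windows()$N290
  prn <- select_component_peak(detect_peaks(wn), compn, wn)
  expect_true(baseline_noise_check(wn, prn))
})

test_that("windowed and fixed-window mean amplitudes match quadrature", {
  ta <- seq(-100, 600, by = 2)
  const <- erp_waveform(rep(5, length(ta)), ta)
  expect_equal(peak_window_amplitude(const, 120), 5)
  expect_equal(mean_amplitude(const, c(190, 350)), 5)
  # Gaussian bump: sampled mean against numeric quadrature of the kernel
  w <- make_bump_wave(lat = 120, amp = 10, width = 20)
  got <- peak_window_amplitude(w, 120)
  quad <- stats::integrate(function(t) 10 * exp(-t^2 / 800), -31, 31)$value / 62
  expect_equal(got, quad, tolerance = 0.01)
  # window clipped at the epoch edge
  edge <- erp_waveform(rep(1, length(ta)), ta)
  expect_equal(peak_window_amplitude(edge, 590), 1)
  expect_error(mean_amplitude(w, c(500, 700)), "outside")
  # odd function about the window centre averages to zero
  odd <- erp_waveform(ta - 270, ta)
  expect_equal(mean_amplitude(odd, c(190, 350)), 0)
})

test_that("trial subsampling is deterministic, balanced and fails soft", {
  ses <- fixture_clean_session()
  ts <- ses$prep_f
  i1 <- subsample_trials(ts, 10, seed = 5)
  i2 <- subsample_trials(ts, 10, seed = 5)
  expect_identical(i1, i2)
  expect_length(unique(i1), 10)
  ib <- subsample_trials(ts, 10, balance = TRUE, seed = 5)
  expect_equal(sum(ts$trials$condition[ib] == "face_upright"), 5)
  expect_equal(sum(ts$trials$condition[ib] == "face_inverted"), 5)
  # insufficient per-orientation trials -> unavailable, not an error
  expect_null(subsample_trials(ts, 40, balance = TRUE))
  expect_null(subsample_trials(ts, 1000))
  expect_length(subsample_trials(ts, 6, conditions = "face_upright",
                                 seed = 2), 6)
})

test_that("averaging is linear, re-baselined and channel-collapsed", {
  ses <- fixture_clean_session()
  ts <- ses$prep_f
  idx <- clean_trials(ts)[1:4]
  w <- average_trials(ts, idx, condition_set = "faces_all")
  manual <- apply(ts$analysis[, , idx, drop = FALSE], 2, mean)
  manual <- manual - mean(manual[ts$time_axis >= -100 & ts$time_axis <= 0])
  expect_equal(w$amplitude, manual)
  expect_equal(w$n_trials, 4)
  expect_error(average_trials(ts, integer(0)), "empty")
})

test_that("grand average screens by trial count and amplitude content", {
  ta <- seq(-100, 600, by = 2)
  strong <- make_bump_wave(amp = 10); strong$n_trials <- 20L
  weak <- make_bump_wave(amp = 0.9); weak$n_trials <- 50L
  few <- make_bump_wave(amp = 8); few$n_trials <- 5L
  ga <- grand_average(list(strong, weak, few))
  expect_equal(ga$amplitude, strong$amplitude)   # only `strong` eligible
  ga2 <- grand_average(list(strong, strong))
  expect_equal(ga2$amplitude, strong$amplitude)
  other <- make_bump_wave(amp = 6); other$n_trials <- 20L
  ga3 <- grand_average(list(strong, other))
  expect_equal(ga3$amplitude, (strong$amplitude + other$amplitude) / 2)
  expect_error(grand_average(list(weak, few)), "eligible")
})

test_that("feature extraction recovers simulator truth and propagates missingness", {
  ses <- fixture_clean_session()
  comps <- default_components()
  truth <- fixture_truth()
  w_cb <- average_trials(ses$prep_cb, clean_trials(ses$prep_cb),
                         condition_set = "checkerboard")
  fr <- extract_features(w_cb)
  lat_true <- truth_peak(comps, truth[1, ], c(50, 200), +1)
  expect_lt(abs(fr$p1_latency - lat_true), 2 + 1e-9)        # within 1 sample
  expect_lt(abs(fr$p1_amp / truth_win_amp(comps, truth[1, ], lat_true) - 1),
            0.02)
  w_f <- average_trials(ses$prep_f, clean_trials(ses$prep_f),
                        condition_set = "faces_all")
  frf <- extract_features(w_f)
  lat_n290 <- truth_peak(comps, truth[2:3, ], c(190, 350), -1)
  expect_lt(abs(frf$n290_latency - lat_n290), 2 + 1e-9)
  expect_lt(abs(frf$n290_peak_amp /
                  truth_win_amp(comps, truth[2:3, ], lat_n290) - 1), 0.02)
  expect_false("p1_latency" %in% names(frf))     # no P1 for faces
  # no N290 peak: N290 fields missing, P400 mean still computed
  ta <- seq(-100, 600, by = 2)
  pos_only <- erp_waveform(5 * exp(-(ta - 400)^2 / (2 * 50^2)), ta,
                           condition_set = "faces_all")
  fr2 <- extract_features(pos_only)
  expect_true(is.na(fr2$n290_latency))
  expect_true(is.na(fr2$n290_peak_amp))
  expect_false(fr2$n290_valid)
  expect_false(is.na(fr2$p400_mean_amp))
  expect_false("p400_latency" %in% names(fr2))   # P400 never gets peak measures
})

test_that("peak selection is invariant under time reversal with polarity flip", {
  set.seed(31)
  ta <- seq(-100, 600, by = 2)
  for (r in 1:20) {
    x <- as.numeric(stats::filter(rnorm(length(ta), 0, 3), rep(1 / 8, 8),
                                  circular = TRUE))
    w <- erp_waveform(x, ta)
    # time-reversed (mirrored around the axis midpoint 250 ms),
    # polarity-flipped copy on the same axis
    wr <- erp_waveform(-rev(x), ta)
    comp <- component_window("C", +1, c(120, 300))
    compr <- component_window("C", -1, c(500 - 300, 500 - 120))
    pr <- select_component_peak(detect_peaks(w), comp, w)
    prr <- select_component_peak(detect_peaks(wr), compr, wr)
    expect_equal(pr$valid, prr$valid)
    if (pr$valid) {
      expect_equal(prr$point_amp, -pr$point_amp)
      expect_equal(prr$latency, 500 - pr$latency)
    }
  }
})

test_that("recovery error grows gracefully with noise", {
  comps <- default_components()
  truth <- fixture_truth()
  rmse <- vapply(c(0, 5, 15), function(nsd) {
    errs <- vapply(1:6, function(r) {
      co <- cohort_spec(1, n_sessions = 1, trials_checkerboard = 24,
                        trials_face_upright = 0, trials_face_inverted = 0,
                        noise_sd = nsd, artifact_rate_amp = 0,
                        artifact_rate_flat = 0)
      ses <- simulate_session(co, comps, truth, seed = 500 + r)
      ts <- preprocess_trials(ses$recording, ses$events, "checkerboard")
      w <- average_trials(ts, clean_trials(ts), condition_set = "checkerboard")
      extract_features(w)$p1_latency - truth_peak(comps, truth[1, ],
                                                  c(50, 200), +1)
    }, 0)
    sqrt(mean(errs^2))
  }, 0)
  expect_lte(rmse[1], rmse[2] + 1e-9)
  expect_lte(rmse[2], rmse[3] + 1e-9)
  expect_lt(rmse[1], 2)
})
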