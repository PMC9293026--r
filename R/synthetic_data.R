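#' Component specification for the simulator
#'
#' Describes one ERP component as a Gaussian bump with per-subject
#' (between-session) and per-session (within-subject) variation in latency
#' and amplitude.  The variance ratio
#' `sd_between^2 / (sd_between^2 + sd_within^2)` is the analytic true ICC of
#' the corresponding feature, which is what makes reliability recovery
#' testable.
#'
#' @param name component label (`"P1"`, `"N290"`, `"P400"`).
#' @param channels target channel labels the bump is written to.
#' @param polarity `+1` or `-1`.
#' @param mu_latency,sd_latency_between,sd_latency_within latency mean and
#'   SDs, ms.
#' @param mu_amp,sd_amp_between,sd_amp_within amplitude mean and SDs,
#'   microvolts (magnitude; sign comes from `polarity`).
#' @param width Gaussian SD of the bump, ms.
#' @return A `component_spec` (named list).
#' @export
component_spec <- function(name, channels, polarity, mu_latency,
                           sd_latency_between, sd_latency_within,
                           mu_amp, sd_amp_between, sd_amp_within, width) {
  stopifnot(polarity %in% c(-1, 1), width > 0,
            sd_latency_between >= 0, sd_latency_within >= 0,
            sd_amp_between >= 0, sd_amp_within >= 0)
  structure(list(name = name, channels = channels, polarity = polarity,
                 mu_latency = mu_latency,
                 sd_latency_between = sd_latency_between,
                 sd_latency_within = sd_latency_within,
                 mu_amp = mu_amp, sd_amp_between = sd_amp_between,
                 sd_amp_within = sd_amp_within, width = width),
            class = "component_spec")
}

#' Default simulated components
#'
#' A positive occipital P1 at Oz, and a negative N290 / positive P400 pair
#' at P7/P8, with means placed centrally in the analysis windows
#' (P1 50--200 ms, N290 190--350 ms, P400 300--500 ms) and dispersions
#' chosen so that typical draws stay inside them.
#'
#' @return Named list of [component_spec()] objects.
#' @export
default_components <- function() {
  list(
    P1   = component_spec("P1", "Oz", +1, 120, 10, 6, 12, 3.0, 1.5, 18),
    N290 = component_spec("N290", c("P7", "P8"), -1, 280, 12, 8, 8, 2.5, 1.5, 28),
    P400 = component_spec("P400", c("P7", "P8"), +1, 420, 15, 10, 7, 2.5, 1.5, 50)
  )
}

#' Cohort specification for the simulator
#'
#' Defaults follow the trial budget of the acquisition paradigm this
#' pipeline targets: 72 checkerboard trials and 72 + 72 upright/inverted
#' face trials per session, two sessions per subject.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject (2 for test--retest use).
#' @param trials_checkerboard,trials_face_upright,trials_face_inverted
#'   trials per condition and session.
#' @param noise_sd single-channel background (pink) noise SD, microvolts;
#'   a white floor of `noise_sd / 4` is added on top.
#' @param pink_exponent spectral exponent of the 1/f background.
#' @param artifact_rate_amp probability per trial and channel of an injected
#'   high-amplitude artifact.
#' @param artifact_rate_flat probability per channel and session that the
#'   channel records flat.
#' @param gaze_gap_rate target fraction of gaze samples falling in tracking
#'   gaps.
#' @param common_mode_amp amplitude (microvolts) of a deterministic
#'   background shared by all channels; cancelled exactly by re-referencing
#'   and kept nonzero by default so reference channels carry signal even in
#'   noiseless simulations.
#' @param seed default master seed for [simulate_cohort()].
#' @return A `cohort_spec` (named list).
#' @export
cohort_spec <- function(n_subjects, n_sessions = 2,
                        trials_checkerboard = 72,
                        trials_face_upright = 72,
                        trials_face_inverted = 72,
                        noise_sd = 8, pink_exponent = 1,
                        artifact_rate_amp = 0.05,
                        artifact_rate_flat = 0.02,
                        gaze_gap_rate = 0.1,
                        common_mode_amp = 15,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, n_sessions >= 1,
            artifact_rate_amp >= 0, artifact_rate_amp <= 1,
            artifact_rate_flat >= 0, artifact_rate_flat <= 1,
            gaze_gap_rate >= 0, gaze_gap_rate < 1,
            noise_sd >= 0, common_mode_amp >= 0)
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 trials_checkerboard = trials_checkerboard,
                 trials_face_upright = trials_face_upright,
                 trials_face_inverted = trials_face_inverted,
                 noise_sd = noise_sd, pink_exponent = pink_exponent,
                 artifact_rate_amp = artifact_rate_amp,
                 artifact_rate_flat = artifact_rate_flat,
                 gaze_gap_rate = gaze_gap_rate,
                 common_mode_amp = common_mode_amp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Gaussian ERP kernel
#'
#' `polarity * amp * exp(-(t - latency)^2 / (2 * width^2))`, evaluated on a
#' time axis in ms.
#'
#' @param spec a [component_spec()] (supplies polarity and width).
#' @param latency bump centre, ms.
#' @param amp bump magnitude, microvolts.
#' @param time_axis uniform time axis, ms.
#' @return Numeric waveform, microvolts per time point.
#' @export
erp_kernel <- function(spec, latency, amp, time_axis) {
  spec$polarity * amp * exp(-(time_axis - latency)^2 / (2 * spec$width^2))
}

#' Evaluate the noiseless kernel sum of a condition
#'
#' Sums the kernels of the listed components at their true latencies and
#' amplitudes; this is the continuous ground-truth epoch waveform on the
#' target channels and the oracle for feature-recovery tests.
#'
#' @param components named list of [component_spec()].
#' @param truth tibble with columns `component`, `latency`, `amp` (one row
#'   per component to include).
#' @param t_ms times (ms) at which to evaluate.
#' @return Numeric vector, microvolts.
#' @export
kernel_sum <- function(components, truth, t_ms) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(truth))) {
    sp <- components[[truth$component[i]]]
    out <- out + erp_kernel(sp, truth$latency[i], truth$amp[i], t_ms)
  }
  out
}

# spectrally shaped 1/f^a noise, sd-normalized
pink_noise <- function(n, exponent = 1, sd = 1) {
  if (sd == 0 || n == 0) return(numeric(n))
  nf <- 2^ceiling(log2(max(n, 2)))
  f <- c(1, seq_len(nf / 2), rev(seq_len(nf / 2 - 1)))  # avoid f = 0
  spec <- 1 / f^(exponent / 2)
  spec[1] <- 0
  ph <- stats::runif(nf, 0, 2 * pi)
  z <- spec * exp(1i * ph)
  # enforce Hermitian symmetry for a real signal
  z[(nf / 2 + 2):nf] <- Conj(z[seq(nf / 2, 2)])
  z[nf / 2 + 1] <- Re(z[nf / 2 + 1])
  x <- Re(stats::fft(z, inverse = TRUE))[seq_len(n)]
  sd * (x - mean(x)) / stats::sd(x)
}

#' Draw latent between/within-subject scores
#'
#' The latent layer of the simulator: per-subject means with SD
#' `sd_between` plus independent per-session deviations with SD
#' `sd_within`, so the analytic ICC is
#' `sd_between^2 / (sd_between^2 + sd_within^2)`.
#'
#' @param n_subjects number of subjects.
#' @param sd_between,sd_within between- and within-subject SDs.
#' @param n_sessions sessions per subject.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return Tibble with columns `subject`, `session`, `score`.
#' @export
simulate_latent_scores <- function(n_subjects, sd_between, sd_within,
                                   n_sessions = 2, mu = 0, seed = 1L) {
  with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sd_between)
    tidyr::expand_grid(subject = seq_len(n_subjects),
                       session = seq_len(n_sessions)) |>
      dplyr::mutate(score = mu + b[.data$subject] +
                      stats::rnorm(dplyr::n(), 0, sd_within))
  })
}

condition_components <- function(condition) {
  if (condition == "checkerboard") "P1"
  else if (condition %in% FACE_CONDITIONS) c("N290", "P400") else character()
}

#' Simulate one recording session
#'
#' Builds a continuous 500-Hz 8-channel recording containing
#' condition-appropriate Gaussian components on their target channels,
#' 1/f + white background noise, a channel-common background (cancelled by
#' re-referencing), injected high-amplitude and flat-channel artifacts at
#' the configured rates (locations logged), plus an event table and a 60-Hz
#' gaze stream with tracking gaps.
#'
#' @param cohort a [cohort_spec()].
#' @param components named list of [component_spec()].
#' @param session_truth tibble with columns `component`, `latency`, `amp`:
#'   this subject's true parameters for this session (e.g. one
#'   subject-session slice of [simulate_cohort()]'s truth table).
#' @param seed integer seed for this session's randomness.
#' @return List with elements `recording` ([eeg_recording()]), `events`
#'   (tibble), `gaze` (tibble), and `truth` (list: component truth,
#'   artifact log, flat channels, event order).
#' @export
simulate_session <- function(cohort, components, session_truth, seed = 1L) {
  fs <- 500
  channels <- c("FPz", "Fz", "Cz", "Oz", "C3", "C4", "P7", "P8")
  with_seed(seed, {
    n_trials <- cohort$trials_checkerboard + cohort$trials_face_upright +
      cohort$trials_face_inverted
    conditions <- sample(c(rep("checkerboard", cohort$trials_checkerboard),
                           rep("face_upright", cohort$trials_face_upright),
                           rep("face_inverted", cohort$trials_face_inverted)))
    head_s <- 4.2; iti <- 1.4
    onset_t <- head_s + (seq_len(n_trials) - 1) * iti
    dur_s <- ceiling(head_s * 2 + n_trials * iti)
    n_samp <- dur_s * fs
    tt <- (seq_len(n_samp) - 1) / fs

    data <- matrix(0, length(channels), n_samp,
                   dimnames = list(channels, NULL))
    if (cohort$noise_sd > 0) {
      for (i in seq_along(channels)) {
        data[i, ] <- pink_noise(n_samp, cohort$pink_exponent, cohort$noise_sd) +
          stats::rnorm(n_samp, 0, cohort$noise_sd / 4)
      }
    }
    if (cohort$common_mode_amp > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      cm <- cohort$common_mode_amp *
        (sin(2 * pi * 0.7 * tt + ph[1]) + 0.6 * sin(2 * pi * 7.3 * tt + ph[2]))
      data <- sweep(data, 2, cm, "+")
    }

    onset_sample <- as.integer(floor(onset_t * fs + 0.5)) + 1L
    events <- tibble(trial_id = seq_len(n_trials),
                     onset_sample = onset_sample,
                     condition = conditions)

    # condition-appropriate kernels on their target channels
    rel <- seq(-0.2 * fs, 0.9 * fs)          # -200..900 ms, covers all bumps
    rel_ms <- rel * 1000 / fs
    for (k in seq_len(n_trials)) {
      comps <- condition_components(conditions[k])
      if (!length(comps)) next
      tr <- session_truth[session_truth$component %in% comps, , drop = FALSE]
      cols <- onset_sample[k] + rel
      keep <- cols >= 1 & cols <= n_samp
      for (i in seq_len(nrow(tr))) {
        sp <- components[[tr$component[i]]]
        w <- erp_kernel(sp, tr$latency[i], tr$amp[i], rel_ms)
        for (ch in sp$channels)
          data[ch, cols[keep]] <- data[ch, cols[keep]] + w[keep]
      }
    }

    # high-amplitude artifacts: square pulses inside the epoch window
    art <- which(matrix(stats::runif(n_trials * length(channels)) <
                          cohort$artifact_rate_amp,
                        n_trials, length(channels)), arr.ind = TRUE)
    artifact_log <- tibble(trial_id = integer(), channel = character(),
                           type = character())
    if (nrow(art)) {
      for (r in seq_len(nrow(art))) {
        k <- art[r, 1]; ch <- channels[art[r, 2]]
        t_on <- stats::runif(1, 0, 0.44)
        cols <- onset_sample[k] + seq(round(t_on * fs),
                                      round((t_on + 0.06) * fs))
        cols <- cols[cols >= 1 & cols <= n_samp]
        data[ch, cols] <- data[ch, cols] + sample(c(-250, 250), 1)
      }
      artifact_log <- tibble(trial_id = art[, 1],
                             channel = channels[art[, 2]],
                             type = "amplitude")
    }

    flat_channels <- channels[stats::runif(length(channels)) <
                                cohort$artifact_rate_flat]
    data[flat_channels, ] <- 0

    gaze <- simulate_gaze(dur_s, cohort$gaze_gap_rate)

    list(recording = eeg_recording(data, fs, channels),
         events = events, gaze = gaze,
         truth = list(components = session_truth,
                      artifacts = artifact_log,
                      flat_channels = flat_channels,
                      seed = seed))
  })
}

# 60 Hz gaze stream with alternating geometric valid/gap runs
simulate_gaze <- function(dur_s, gap_rate, fs_et = 60) {
  n <- floor(dur_s * fs_et)
  times <- (seq_len(n) - 1) / fs_et
  valid <- rep(TRUE, n)
  if (gap_rate > 0) {
    mean_gap <- 7                               # samples, ~117 ms at 60 Hz
    mean_valid <- mean_gap * (1 - gap_rate) / gap_rate
    pos <- 1 + stats::rgeom(1, 1 / mean_valid)
    while (pos <= n) {
      glen <- 1 + stats::rgeom(1, 1 / mean_gap)
      valid[pos:min(n, pos + glen - 1)] <- FALSE
      pos <- pos + glen + 1 + stats::rgeom(1, 1 / mean_valid)
    }
  }
  x <- 960 + stats::rnorm(n, 0, 40)
  y <- 540 + stats::rnorm(n, 0, 40)
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  tibble(time_s = times, x = x, y = y, valid = valid)
}

#' Simulate a paired-session cohort with known true reliability
#'
#' Draws per-subject latent component parameters (between-subject SD), then
#' per-session deviations (within-subject SD), simulates every session, and
#' returns the per-subject truth table together with the analytic true ICC
#' of each feature implied by the variance components.
#'
#' @param cohort a [cohort_spec()].
#' @param components named list of [component_spec()].
#' @param seed master seed; defaults to `cohort$seed`.
#' @return List with `sessions` (list of [simulate_session()] results, each
#'   tagged with `subject` and `session`), `truth` (tibble: subject,
#'   session, component, latency, amp), and `true_icc` (tibble: feature,
#'   true_icc).
#' @export
simulate_cohort <- function(cohort, components = default_components(),
                            seed = cohort$seed) {
  truth <- draw_cohort_truth(cohort, components, seed)
  sessions <- list()
  for (s in seq_len(cohort$n_subjects)) {
    for (v in seq_len(cohort$n_sessions)) {
      st <- truth[truth$subject == s & truth$session == v,
                  c("component", "latency", "amp")]
      ses <- simulate_session(cohort, components, st,
                              seed = derive_seed(seed, s, v, "session"))
      ses$subject <- s; ses$session <- v
      sessions[[length(sessions) + 1]] <- ses
    }
  }
  list(sessions = sessions, truth = truth,
       true_icc = true_icc_table(components))
}

draw_cohort_truth <- function(cohort, components, seed) {
  with_seed(derive_seed(seed, "truth"), {
    rows <- list()
    for (cn in names(components)) {
      sp <- components[[cn]]
      b_lat <- stats::rnorm(cohort$n_subjects, 0, sp$sd_latency_between)
      b_amp <- stats::rnorm(cohort$n_subjects, 0, sp$sd_amp_between)
      for (v in seq_len(cohort$n_sessions)) {
        rows[[length(rows) + 1]] <- tibble(
          subject = seq_len(cohort$n_subjects), session = v, component = cn,
          latency = sp$mu_latency + b_lat +
            stats::rnorm(cohort$n_subjects, 0, sp$sd_latency_within),
          amp = pmax(0.5, sp$mu_amp + b_amp +
                       stats::rnorm(cohort$n_subjects, 0, sp$sd_amp_within)))
      }
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$session)
  })
}

true_icc_table <- function(components) {
  icc_of <- function(sb, sw) if (sb == 0 && sw == 0) NA_real_
    else sb^2 / (sb^2 + sw^2)
  rows <- purrr::imap(components, function(sp, cn) {
    tibble(component = cn,
           latency_icc = icc_of(sp$sd_latency_between, sp$sd_latency_within),
           amp_icc = icc_of(sp$sd_amp_between, sp$sd_amp_within))
  })
  dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(-"component", names_to = "measure",
                        values_to = "true_icc") |>
    dplyr::mutate(feature = paste0(tolower(.data$component), "_",
                                   sub("_icc$", "", .data$measure))) |>
    dplyr::select("feature", "true_icc")
}
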