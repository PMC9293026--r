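#' Preprocessing configuration
#'
#' Defaults: 0.1--40 Hz zero-phase band-pass with 3 s padding, DFT line
#' filter at 50/100/150 Hz, -100..0 ms baseline, flat threshold 0.0001 uV,
#' amplitude threshold +-150 uV (strict "exceeds"), 80% bad-channel rule,
#' Oz analysis for checkerboards and P7/P8 for faces, Cz reference with
#' mean(C3, C4) fallback.
#'
#' @param bp_lo,bp_hi band-pass edges, Hz.
#' @param pad padding on each side of the epoch before filtering, seconds.
#' @param line_freqs line-noise frequencies for the DFT filter, Hz.
#' @param baseline baseline window `(lo, hi)`, ms.
#' @param flat_eps flat-signal threshold, microvolts.
#' @param amp_thresh amplitude threshold, microvolts.
#' @param bad_channel_prop flagged-trial proportion at or above which a
#'   channel is excluded.
#' @param analysis_channels named list: channels per condition family.
#' @param ref_primary,ref_fallback reference channel and fallback pair.
#' @return A named list of class `preproc_config`.
#' @export
preproc_config <- function(bp_lo = 0.1, bp_hi = 40, pad = 3,
                           line_freqs = c(50, 100, 150),
                           baseline = c(-100, 0),
                           flat_eps = 1e-4, amp_thresh = 150,
                           bad_channel_prop = 0.8,
                           analysis_channels = list(checkerboard = "Oz",
                                                    faces = c("P7", "P8")),
                           ref_primary = "Cz",
                           ref_fallback = c("C3", "C4")) {
  stopifnot(bp_lo < bp_hi, bad_channel_prop > 0, bad_channel_prop <= 1)
  structure(list(bp_lo = bp_lo, bp_hi = bp_hi, pad = pad,
                 line_freqs = line_freqs, baseline = baseline,
                 flat_eps = flat_eps, amp_thresh = amp_thresh,
                 bad_channel_prop = bad_channel_prop,
                 analysis_channels = analysis_channels,
                 ref_primary = ref_primary, ref_fallback = ref_fallback),
            class = "preproc_config")
}

#' Segment a recording into padded epochs
#'
#' Cuts one epoch per event, `window` ms around the onset, keeping `pad`
#' seconds of raw context on each side for filtering.  Context beyond the
#' recording edges is reflect-padded (logged in the trial table); an event
#' whose core window itself falls outside the recording is marked excluded
#' with reason `"edge"`.
#'
#' @param rec an [eeg_recording()].
#' @param events event tibble (`trial_id`, `onset_sample`, `condition`).
#' @param window epoch window `(lo, hi)` relative to onset, ms.
#' @param pad context on each side, seconds.
#' @param channels channels to keep (default all).
#' @return An `erp_trialset`: padded epoch array (channels x time x trials),
#'   core time axis, and a per-trial bookkeeping tibble.
#' @export
segment <- function(rec, events, window = c(-100, 600), pad = 3,
                    channels = rec$channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  events <- validate_events(events)
  fs <- rec$fs
  miss <- setdiff(channels, rec$channels)
  if (length(miss))
    abort(sprintf("channel(s) not in recording: %s",
                  paste(miss, collapse = ", ")))
  core_rel <- seq(round(window[1] / 1000 * fs), round(window[2] / 1000 * fs))
  pad_n <- round(pad * fs)
  rel <- seq(core_rel[1] - pad_n, core_rel[length(core_rel)] + pad_n)
  n_samp <- ncol(rec$data)
  n_tr <- nrow(events)

  epochs <- array(0, c(length(channels), length(rel), n_tr),
                  dimnames = list(channels, NULL, NULL))
  excluded <- logical(n_tr); reason <- rep(NA_character_, n_tr)
  padded <- logical(n_tr)
  reflect <- function(idx, n) {
    # reflect out-of-range indices around the record edges
    for (it in 1:3) idx <- ifelse(idx < 1, 2 - idx,
                                  ifelse(idx > n, 2 * n - idx, idx))
    pmin(pmax(idx, 1L), n)
  }
  for (k in seq_len(n_tr)) {
    core_idx <- events$onset_sample[k] + core_rel
    if (core_idx[1] < 1 || core_idx[length(core_idx)] > n_samp) {
      excluded[k] <- TRUE; reason[k] <- "edge"
      next
    }
    idx <- events$onset_sample[k] + rel
    if (idx[1] < 1 || idx[length(idx)] > n_samp) {
      padded[k] <- TRUE
      idx <- reflect(idx, n_samp)
    }
    epochs[, , k] <- rec$data[channels, idx, drop = FALSE]
  }
  structure(list(
    epochs = epochs,
    channels = channels, fs = fs, pad_n = pad_n,
    core_index = seq_along(core_rel) + pad_n,
    time_axis = core_rel * 1000 / fs,
    trials = tibble(trial_id = events$trial_id,
                    condition = events$condition,
                    excluded = excluded, reason = reason, padded = padded,
                    reference_used = NA_character_),
    flags = NULL, bad_channels = character(), analysis = NULL,
    cropped = FALSE
  ), class = "erp_trialset")
}

#' @export
print.erp_trialset <- function(x, ...) {
  cat(sprintf("<erp_trialset> %d trials x %d channels @ %g Hz, %s\n",
              nrow(x$trials), length(x$channels), x$fs,
              if (x$cropped) "cropped" else "padded"))
  cat(sprintf("  excluded: %d; flagged: %s\n", sum(x$trials$excluded),
              if (is.null(x$flags)) "not yet computed"
              else format(sum(x$flags))))
  invisible(x)
}

## ---- filters ---------------------------------------------------------------

butter_coefs <- function(fs, lo, hi) {
  if (!(lo < hi && hi < fs / 2)) abort("need bp_lo < bp_hi < fs/2.")
  signal::butter(4, c(lo, hi) * 2 / fs, type = "pass")
}

# single forward pass of an IIR filter, zero initial conditions
iir_pass <- function(x, b, a) {
  b <- b / a[1]; a <- a / a[1]
  y <- stats::filter(c(rep(0, length(b) - 1), x), b,
                     method = "convolution", sides = 1)
  y <- y[-seq_len(length(b) - 1)]
  if (length(a) > 1) y <- stats::filter(y, -a[-1], method = "recursive")
  as.numeric(y)
}

two_pass <- function(x, coefs) {
  rev(iir_pass(rev(iir_pass(x, coefs$b, coefs$a)), coefs$b, coefs$a))
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero
#' phase), so the magnitude response is the squared single-pass response and
#' peak latencies are preserved.  Apply to the padded segment and crop
#' afterwards; filter transients live in the padding.
#'
#' @param x numeric vector, or matrix with channels in rows.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, lo = 0.1, hi = 40) {
  if (!all(is.finite(x))) abort("non-finite samples in input to bandpass_filter.")
  coefs <- butter_coefs(fs, lo, hi)
  if (is.matrix(x)) t(apply(x, 1, two_pass, coefs = coefs))
  else two_pass(x, coefs)
}

#' Designed magnitude response of the band-pass filter
#'
#' Two-pass (zero-phase) magnitude of the 4th-order Butterworth band-pass at
#' frequencies `f`; the oracle for filter-contract tests.
#'
#' @param f frequencies, Hz.
#' @inheritParams bandpass_filter
#' @return Magnitude response (linear gain) at `f`.
#' @export
bandpass_response <- function(f, fs, lo = 0.1, hi = 40) {
  coefs <- butter_coefs(fs, lo, hi)
  w <- 2 * pi * f / fs
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(coefs$b) - 1))
    num <- sum(coefs$b * z)
    z <- exp(-1i * wi * (seq_along(coefs$a) - 1))
    abs(num / sum(coefs$a * z))
  }, 0)
  H^2   # two passes
}

#' DFT line-noise filter
#'
#' Least-squares fit of sine and cosine regressors at each listed frequency
#' over the (padded) segment, subtracted from the data.  Exact cancellation
#' of any sinusoid at a listed frequency when the segment spans an integer
#' number of cycles.
#'
#' @param x numeric vector, or matrix with channels in rows.
#' @param fs sampling rate, Hz.
#' @param freqs frequencies to remove, Hz.
#' @return Filtered data, same shape as `x`.
#' @export
dft_line_filter <- function(x, fs, freqs = c(50, 100, 150)) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1)
  n <- ncol(x)
  tt <- (seq_len(n) - 1) / fs
  X <- do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
  Q <- qr.Q(qr(X))
  out <- x - (x %*% Q) %*% t(Q)
  if (vec) as.numeric(out) else out
}

#' Baseline correction
#'
#' Subtracts the per-channel mean over the baseline window.
#'
#' @param x numeric vector, or matrix with channels in rows, time in
#'   columns aligned with `time_axis`.
#' @param time_axis time axis in ms.
#' @param window baseline window `(lo, hi)`, ms.
#' @return Baseline-corrected data, same shape as `x`.
#' @export
baseline_correct <- function(x, time_axis, window = c(-100, 0)) {
  if (window[2] < time_axis[1] || window[1] > time_axis[length(time_axis)])
    abort("baseline window outside the time axis.")
  idx <- window_indices(window, time_axis)
  if (!length(idx)) abort("empty baseline window.")
  if (is.matrix(x)) x - rowMeans(x[, idx, drop = FALSE])
  else x - mean(x[idx])
}

## ---- artifact flags and exclusion rules ------------------------------------

#' Flag flat and high-amplitude artifacts
#'
#' A channel is flagged within a trial if, over the epoch window, its
#' maximum absolute amplitude does not exceed `flat_eps` (flat) or any
#' sample strictly exceeds `+-amp_thresh` microvolts.  "Exceeds" is strict:
#' a peak at exactly the threshold is not flagged.
#'
#' @param ts a cropped, baseline-corrected `erp_trialset`.
#' @param flat_eps flat threshold, microvolts.
#' @param amp_thresh amplitude threshold, microvolts.
#' @return `ts` with `flags` (trials x channels logical matrix) and
#'   `flag_reason` (`"flat"`, `"amplitude"` or `NA`).
#' @export
flag_artifacts <- function(ts, flat_eps = 1e-4, amp_thresh = 150) {
  x <- core_epochs(ts)
  n_tr <- dim(x)[3]; n_ch <- dim(x)[1]
  flags <- matrix(FALSE, n_tr, n_ch, dimnames = list(NULL, ts$channels))
  reason <- matrix(NA_character_, n_tr, n_ch,
                   dimnames = list(NULL, ts$channels))
  for (k in seq_len(n_tr)) {
    m <- apply(abs(x[, , k, drop = FALSE]), 1, max)
    flat <- m <= flat_eps
    amp <- apply(x[, , k, drop = FALSE] > amp_thresh |
                   x[, , k, drop = FALSE] < -amp_thresh, 1, any)
    flags[k, ] <- flat | amp
    reason[k, flat] <- "flat"
    reason[k, amp & !flat] <- "amplitude"
  }
  ts$flags <- flags; ts$flag_reason <- reason
  ts
}

core_epochs <- function(ts) {
  if (ts$cropped) ts$epochs
  else ts$epochs[, ts$core_index, , drop = FALSE]
}

#' Channels excluded by the 80% rule
#'
#' A channel is excluded when artifacts are present on `prop` of the trials
#' or more (inclusive).
#'
#' @param flags trials x channels logical matrix.
#' @param prop exclusion proportion.
#' @return Character vector of excluded channel names.
#' @export
exclude_bad_channels <- function(flags, prop = 0.8) {
  if (nrow(flags) < 1) abort("need at least one trial.")
  frac <- colMeans(flags)
  colnames(flags)[frac >= prop]
}

#' Trial-wise fallback re-referencing
#'
#' Per trial: if the primary reference (Cz) is unflagged, subtract it from
#' the analysis channels; otherwise, if both fallback channels (C3, C4) are
#' unflagged, subtract their mean; otherwise exclude the trial
#' (reason `"no_reference"`).
#'
#' @param ts a flagged `erp_trialset`.
#' @param analysis_channels channels the re-referenced output is kept for.
#' @param ref_primary,ref_fallback reference channels.
#' @return `ts` with `analysis` (channels x time x trials array of
#'   re-referenced data) and updated trial table.
#' @export
rereference <- function(ts, analysis_channels, ref_primary = "Cz",
                        ref_fallback = c("C3", "C4")) {
  need <- c(analysis_channels, ref_primary, ref_fallback)
  miss <- setdiff(need, ts$channels)
  if (length(miss))
    abort(sprintf("reference/analysis channel(s) absent: %s",
                  paste(miss, collapse = ", ")))
  if (is.null(ts$flags)) abort("run flag_artifacts() before rereference().")
  x <- core_epochs(ts)
  n_tr <- dim(x)[3]
  out <- array(NA_real_, c(length(analysis_channels), dim(x)[2], n_tr),
               dimnames = list(analysis_channels, NULL, NULL))
  for (k in seq_len(n_tr)) {
    if (ts$trials$excluded[k]) next
    if (!ts$flags[k, ref_primary]) {
      ref <- x[ref_primary, , k]
      ts$trials$reference_used[k] <- ref_primary
    } else if (!any(ts$flags[k, ref_fallback])) {
      ref <- colMeans(x[ref_fallback, , k, drop = FALSE])
      ts$trials$reference_used[k] <- sprintf("mean(%s)",
                                             paste(ref_fallback, collapse = ","))
    } else {
      ts$trials$excluded[k] <- TRUE
      ts$trials$reason[k] <- "no_reference"
      ts$trials$reference_used[k] <- "none"
      next
    }
    out[, , k] <- sweep(x[analysis_channels, , k, drop = FALSE], 2, ref)
  }
  ts$analysis <- out
  ts
}

#' Apply per-family trial exclusion rules, then re-reference
#'
#' Checkerboard trials are excluded when Oz is flagged (or excluded as a bad
#' channel); face trials when P7 and/or P8 is.  Surviving trials are then
#' re-referenced trial-wise.
#'
#' @param ts a flagged `erp_trialset` containing one condition family.
#' @param cfg a [preproc_config()].
#' @param family `"checkerboard"` or `"faces"`.
#' @return `ts` with exclusions applied and `analysis` data filled in.
#' @export
apply_condition_rules <- function(ts, cfg = preproc_config(),
                                  family = c("checkerboard", "faces")) {
  family <- match.arg(family)
  chans <- cfg$analysis_channels[[family]]
  if (is.null(ts$flags)) abort("run flag_artifacts() first.")
  bad <- ts$bad_channels
  for (k in seq_len(nrow(ts$trials))) {
    if (ts$trials$excluded[k]) next
    hit <- any(ts$flags[k, chans]) || any(chans %in% bad)
    if (hit) {
      ts$trials$excluded[k] <- TRUE
      ts$trials$reason[k] <- "artifact_analysis_channel"
    }
  }
  rereference(ts, chans, cfg$ref_primary, cfg$ref_fallback)
}

#' Full preprocessing for one condition family
#'
#' Runs the fixed pipeline order: segment, band-pass, DFT line filter
#' (both on the padded segment), crop, baseline-correct, flag artifacts,
#' exclude bad channels (80% rule over the family's trials), apply the
#' family's trial-exclusion rules, and re-reference trial-wise.
#'
#' @param rec an [eeg_recording()].
#' @param events event tibble; only the family's conditions are used.
#' @param family `"checkerboard"` or `"faces"`.
#' @param cfg a [preproc_config()].
#' @return A cropped `erp_trialset` with `flags`, `bad_channels`,
#'   `analysis` data and the exclusion log in `$trials`.
#' @export
preprocess_trials <- function(rec, events, family = c("checkerboard", "faces"),
                              cfg = preproc_config()) {
  family <- match.arg(family)
  conds <- if (family == "checkerboard") "checkerboard" else FACE_CONDITIONS
  ev <- events[events$condition %in% conds, , drop = FALSE]
  chans <- unique(c(cfg$analysis_channels[[family]], cfg$ref_primary,
                    cfg$ref_fallback))
  if (!(cfg$bp_lo < cfg$bp_hi && cfg$bp_hi < rec$fs / 2))
    abort("invalid band-pass configuration for this sampling rate.")
  ts <- segment(rec, ev, pad = cfg$pad, channels = chans)
  coefs <- butter_coefs(ts$fs, cfg$bp_lo, cfg$bp_hi)
  n <- dim(ts$epochs)[2]
  tt <- (seq_len(n) - 1) / ts$fs
  X <- do.call(cbind, lapply(cfg$line_freqs, function(f)
    cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
  Q <- qr.Q(qr(X))
  for (k in seq_len(dim(ts$epochs)[3])) {
    if (ts$trials$excluded[k]) next
    for (i in seq_along(chans))
      ts$epochs[i, , k] <- two_pass(ts$epochs[i, , k], coefs)
    m <- ts$epochs[, , k]
    ts$epochs[, , k] <- m - (m %*% Q) %*% t(Q)
  }
  # crop away the padding, then baseline-correct
  ts$epochs <- ts$epochs[, ts$core_index, , drop = FALSE]
  ts$cropped <- TRUE
  for (k in seq_len(dim(ts$epochs)[3]))
    ts$epochs[, , k] <- baseline_correct(ts$epochs[, , k], ts$time_axis,
                                         cfg$baseline)
  ts <- flag_artifacts(ts, cfg$flat_eps, cfg$amp_thresh)
  keep <- !ts$trials$excluded
  ts$bad_channels <- exclude_bad_channels(ts$flags[keep, , drop = FALSE],
                                          cfg$bad_channel_prop)
  apply_condition_rules(ts, cfg, family)
}

#' Clean-trial index helper
#'
#' @param ts an `erp_trialset` after preprocessing.
#' @return Integer indices of retained (non-excluded) trials.
#' @export
clean_trials <- function(ts) which(!ts$trials$excluded)
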