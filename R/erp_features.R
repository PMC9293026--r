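#' Component analysis window
#'
#' @param name component label.
#' @param polarity `+1` (positive peak) or `-1` (negative peak).
#' @param window primary search window `(lo, hi)`, ms.
#' @param widen widening applied to each side when no peak is found in the
#'   primary window, ms.
#' @param measures subset of
#'   `c("peak_latency", "peak_amplitude", "mean_amplitude")`.
#' @return A `component_window` (named list).
#' @export
component_window <- function(name, polarity, window, widen = 20,
                             measures = c("peak_latency", "peak_amplitude",
                                          "mean_amplitude")) {
  stopifnot(polarity %in% c(-1, 1), window[1] < window[2], widen >= 0)
  structure(list(name = name, polarity = polarity, window = window,
                 widen = widen, measures = measures),
            class = "component_window")
}

#' Default component windows
#'
#' P1: most positive peak 50--200 ms (widened 30--220 ms); N290: most
#' negative peak 190--350 ms (widened 170--370 ms); P400: mean amplitude
#' only over 300--500 ms (its broad morphology makes single peaks
#' unreliable).
#'
#' @return Named list of [component_window()] objects.
#' @export
default_windows <- function() {
  list(
    P1   = component_window("P1", +1, c(50, 200),
                            measures = c("peak_latency", "peak_amplitude")),
    N290 = component_window("N290", -1, c(190, 350)),
    P400 = component_window("P400", +1, c(300, 500),
                            measures = "mean_amplitude")
  )
}

#' Averaged ERP waveform
#'
#' @param amplitude numeric vector, microvolts.
#' @param time_axis time axis, ms.
#' @param n_trials number of trials averaged.
#' @param channels channels averaged over.
#' @param condition_set label
#'   (`checkerboard`, `faces_all`, `faces_upright`, `faces_inverted`).
#' @param subject,session,seed provenance.
#' @return An `erp_waveform`.
#' @export
erp_waveform <- function(amplitude, time_axis, n_trials = NA_integer_,
                         channels = character(), condition_set = NA_character_,
                         subject = NA, session = NA, seed = NA) {
  stopifnot(length(amplitude) == length(time_axis))
  structure(list(amplitude = as.numeric(amplitude), time_axis = time_axis,
                 n_trials = n_trials, channels = channels,
                 condition_set = condition_set, subject = subject,
                 session = session, seed = seed),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s, %s trials, %d samples (%g..%g ms)\n",
              x$condition_set, format(x$n_trials), length(x$amplitude),
              min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

#' Randomly subsample clean trials
#'
#' Draws `n` clean trials without replacement; with `balance = TRUE`
#' (used for collapsed face averages) exactly `n/2` upright and `n/2`
#' inverted trials are drawn.  When too few clean trials are available the
#' subject/session is unavailable at this `n` and `NULL` is returned rather
#' than an error.
#'
#' @param ts an `erp_trialset` after preprocessing.
#' @param n number of trials to draw (even when `balance`).
#' @param balance balance upright/inverted face trials?
#' @param conditions optionally restrict candidates to these condition
#'   labels (e.g. a single orientation).
#' @param seed integer seed; draws are deterministic under it.
#' @return Integer trial indices, or `NULL` when unavailable.
#' @export
subsample_trials <- function(ts, n, balance = FALSE, conditions = NULL,
                             seed = 1L) {
  clean <- clean_trials(ts)
  if (!is.null(conditions))
    clean <- intersect(clean, which(ts$trials$condition %in% conditions))
  if (balance) {
    if (n %% 2 != 0) abort("balanced subsampling needs even `n`.")
    up <- intersect(clean, which(ts$trials$condition == "face_upright"))
    inv <- intersect(clean, which(ts$trials$condition == "face_inverted"))
    if (length(up) < n / 2 || length(inv) < n / 2) return(NULL)
    with_seed(seed, sort(c(resample(up, n / 2), resample(inv, n / 2))))
  } else {
    if (length(clean) < n) return(NULL)
    with_seed(seed, sort(resample(clean, n)))
  }
}

# sample() without its length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]

#' Average trials into an ERP waveform
#'
#' Means over the selected trials, then over the analysis channels, then
#' re-applies baseline correction (-100..0 ms).
#'
#' @param ts an `erp_trialset` with re-referenced `analysis` data.
#' @param indices trial indices (clean, e.g. from [subsample_trials()]).
#' @param channels channels to average; default all analysis channels.
#' @param condition_set provenance label for the result.
#' @param baseline baseline window, ms.
#' @param seed provenance: seed used for the subsample.
#' @return An [erp_waveform()].
#' @export
average_trials <- function(ts, indices, channels = NULL,
                           condition_set = NA_character_,
                           baseline = c(-100, 0), seed = NA) {
  if (is.null(ts$analysis)) abort("trialset has no re-referenced analysis data.")
  if (!length(indices)) abort("empty trial index set.")
  if (any(ts$trials$excluded[indices]))
    abort("cannot average excluded trials.")
  channels <- channels %||% dimnames(ts$analysis)[[1]]
  x <- ts$analysis[channels, , indices, drop = FALSE]
  avg <- apply(x, 2, mean)
  avg <- baseline_correct(avg, ts$time_axis, baseline)
  erp_waveform(avg, ts$time_axis, n_trials = length(indices),
               channels = channels, condition_set = condition_set,
               seed = seed)
}

#' Sample-wise peak identification
#'
#' Scans the waveform for positive and negative peaks.  A positive peak is
#' an interior sample strictly above both neighbours; a run of equal
#' samples (plateau) yields a peak at its **last** sample when the run is
#' preceded and followed by lower values (for the two-sample case: when
#' sample X equals sample X+1 and sample X+2 is lower, X+1 is the peak;
#' when sample X+2 is higher the run is part of a rising plateau and is
#' skipped).  Negative peaks mirror this.  Endpoints are never peaks.
#'
#' @param wave an [erp_waveform()], or a numeric vector with `time_axis`.
#' @param time_axis time axis in ms when `wave` is numeric.
#' @return Tibble with columns `polarity` (+1/-1), `index`, `latency`
#'   (ms), `amplitude`, ordered by index.
#' @export
detect_peaks <- function(wave, time_axis = NULL) {
  if (inherits(wave, "erp_waveform")) {
    x <- wave$amplitude; time_axis <- wave$time_axis
  } else {
    x <- as.numeric(wave)
    time_axis <- time_axis %||% seq_along(x)
  }
  n <- length(x)
  if (n < 3) abort("need at least 3 samples to detect peaks.")
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (j in seq_along(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (s == 1 || e == n) next                 # endpoints never peaks
    before <- x[s - 1]; v <- r$values[j]; after <- x[e + 1]
    if (before < v && after < v)
      out[[length(out) + 1]] <- c(+1, e)
    else if (before > v && after > v)
      out[[length(out) + 1]] <- c(-1, e)
  }
  if (!length(out))
    return(tibble(polarity = integer(), index = integer(),
                  latency = numeric(), amplitude = numeric()))
  m <- do.call(rbind, out)
  tibble(polarity = as.integer(m[, 1]), index = as.integer(m[, 2]),
         latency = time_axis[m[, 2]], amplitude = x[m[, 2]]) |>
    dplyr::arrange(.data$index)
}

#' Select the component peak from detected peaks
#'
#' Keeps peaks of the component's polarity inside its window; a single
#' match is selected directly, multiple matches by the largest amplitude in
#' the polarity direction (ties: earliest).  With no match the window is
#' widened by `widen` ms on each side and the search repeated (`widened`
#' flag set); still none marks the result invalid with reason `"no_peak"`.
#'
#' @param peaks tibble from [detect_peaks()].
#' @param comp a [component_window()].
#' @param wave the [erp_waveform()] the peaks came from.
#' @return One-row `peak_result` tibble: `component`, `polarity`,
#'   `latency`, `point_amp`, `win_amp` (filled by [extract_features()]),
#'   `valid`, `widened`, `reject_reason`.
#' @export
select_component_peak <- function(peaks, comp, wave) {
  pick <- function(window) {
    cand <- peaks[peaks$polarity == comp$polarity &
                    peaks$latency >= window[1] &
                    peaks$latency <= window[2], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    score <- comp$polarity * cand$amplitude
    cand[order(-score, cand$latency)[1], , drop = FALSE]
  }
  sel <- pick(comp$window); widened <- FALSE
  if (is.null(sel)) {
    sel <- pick(comp$window + c(-comp$widen, comp$widen))
    widened <- !is.null(sel)
  }
  if (is.null(sel)) {
    return(tibble(component = comp$name, polarity = comp$polarity,
                  latency = NA_real_, point_amp = NA_real_,
                  win_amp = NA_real_, valid = FALSE, widened = FALSE,
                  reject_reason = "no_peak"))
  }
  tibble(component = comp$name, polarity = comp$polarity,
         latency = sel$latency, point_amp = sel$amplitude,
         win_amp = NA_real_, valid = TRUE, widened = widened,
         reject_reason = "none")
}

#' Screen a selected peak against baseline noise
#'
#' Keeps the peak only if its **point** amplitude strictly exceeds, in the
#' polarity direction, the point amplitude of the largest same-polarity
#' detected peak inside the baseline window; kept when no same-polarity
#' baseline peak exists.  Point amplitudes (not 60-ms means) are used so the
#' comparison never averages across the baseline/stimulus boundary.
#'
#' @param wave the [erp_waveform()].
#' @param peak one-row `peak_result` from [select_component_peak()].
#' @param baseline baseline window, ms.
#' @param peaks optionally, the [detect_peaks()] table (recomputed if
#'   missing).
#' @return `TRUE` to keep, `FALSE` to reject as baseline noise.
#' @export
baseline_noise_check <- function(wave, peak, baseline = c(-100, 0),
                                 peaks = NULL) {
  stopifnot(isTRUE(peak$valid))
  peaks <- peaks %||% detect_peaks(wave)
  base <- peaks[peaks$polarity == peak$polarity &
                  peaks$latency >= baseline[1] &
                  peaks$latency <= baseline[2], , drop = FALSE]
  if (!nrow(base)) return(TRUE)
  peak$polarity * peak$point_amp > max(peak$polarity * base$amplitude)
}

#' Mean amplitude over a window centred on a peak
#'
#' Mean over `latency +- halfwidth` ms (60-ms window by default), clipped to
#' the epoch edges.
#'
#' @param wave an [erp_waveform()].
#' @param latency peak latency, ms.
#' @param halfwidth half-window, ms.
#' @return Microvolts.
#' @export
peak_window_amplitude <- function(wave, latency, halfwidth = 30) {
  win <- c(max(latency - halfwidth, min(wave$time_axis)),
           min(latency + halfwidth, max(wave$time_axis)))
  mean_amplitude(wave, win)
}

#' Mean amplitude over a fixed window
#'
#' @param wave an [erp_waveform()].
#' @param window `(lo, hi)` ms, inside the epoch.
#' @return Microvolts (arithmetic mean over the inclusive sample range).
#' @export
mean_amplitude <- function(wave, window) {
  if (window[1] < min(wave$time_axis) - 1e-9 ||
      window[2] > max(wave$time_axis) + 1e-9)
    abort("window outside the epoch.")
  mean(wave$amplitude[window_indices(window, wave$time_axis)])
}

#' Extract all applicable ERP features from an averaged waveform
#'
#' Checkerboards: P1 peak latency and 60-ms windowed amplitude.  Faces:
#' N290 peak latency, 60-ms windowed amplitude and 190--350 ms mean
#' amplitude, plus P400 mean amplitude (300--500 ms; never peak measures).
#' Peaks failing detection or the baseline-noise screen propagate as
#' missing values; measures not tied to the invalid peak are still
#' computed.
#'
#' @param wave an [erp_waveform()].
#' @param components named list of [component_window()]s; which apply is
#'   decided by `condition_set`.
#' @param condition_set `"checkerboard"`, `"faces_all"`, `"faces_upright"`
#'   or `"faces_inverted"`; defaults to the waveform's.
#' @param baseline baseline window for the noise screen, ms.
#' @return One-row tibble (a feature row): `subject`, `session`,
#'   `condition_set`, `n_trials`, `seed`, then the applicable measures.
#' @export
extract_features <- function(wave, components = default_windows(),
                             condition_set = wave$condition_set,
                             baseline = c(-100, 0)) {
  peaks <- detect_peaks(wave)
  peak_measures <- function(comp) {
    pr <- select_component_peak(peaks, comp, wave)
    if (pr$valid && !baseline_noise_check(wave, pr, baseline, peaks)) {
      pr$valid <- FALSE; pr$reject_reason <- "baseline_noise"
      pr$latency <- NA_real_; pr$point_amp <- NA_real_
    }
    if (pr$valid)
      pr$win_amp <- peak_window_amplitude(wave, pr$latency)
    pr
  }
  row <- tibble(subject = wave$subject, session = wave$session,
                condition_set = condition_set, n_trials = wave$n_trials,
                seed = wave$seed)
  if (condition_set == "checkerboard") {
    pr <- peak_measures(components$P1)
    row$p1_latency <- pr$latency
    row$p1_amp <- pr$win_amp
    row$p1_valid <- pr$valid
    row$p1_widened <- pr$widened
  } else {
    pr <- peak_measures(components$N290)
    row$n290_latency <- pr$latency
    row$n290_peak_amp <- pr$win_amp
    row$n290_valid <- pr$valid
    row$n290_widened <- pr$widened
    row$n290_mean_amp <- mean_amplitude(wave, components$N290$window)
    row$p400_mean_amp <- mean_amplitude(wave, components$P400$window)
  }
  row
}

#' Grand average with amplitude screening
#'
#' Mean over individual averages whose source had at least `min_trials`
#' clean trials and whose maximum absolute amplitude exceeds
#' `min_abs_amp` (averages without signal content are screened out).
#'
#' @param waves list of [erp_waveform()]s on a common time axis.
#' @param min_trials minimum clean trials per contributing average.
#' @param min_abs_amp amplitude screen, microvolts (strict "exceeds").
#' @return An [erp_waveform()]; errors when no wave is eligible.
#' @export
grand_average <- function(waves, min_trials = 10, min_abs_amp = 1) {
  ok <- vapply(waves, function(w) {
    (is.na(w$n_trials) || w$n_trials >= min_trials) &&
      max(abs(w$amplitude)) > min_abs_amp
  }, TRUE)
  if (!any(ok)) abort("no waveform eligible for the grand average.")
  keep <- waves[ok]
  amp <- rowMeans(vapply(keep, function(w) w$amplitude,
                         numeric(length(keep[[1]]$amplitude))))
  erp_waveform(amp, keep[[1]]$time_axis,
               n_trials = sum(vapply(keep, function(w) as.numeric(w$n_trials), 0)),
               condition_set = keep[[1]]$condition_set)
}
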