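#' Interpolate short gaze-tracking gaps
#'
#' Maximal runs of invalid samples lasting 150 ms or less (inclusive),
#' bounded by valid samples on both sides, become valid with linearly
#' interpolated coordinates.  Gap duration is measured from the last valid
#' sample before the gap to the first valid sample after it.  Longer gaps
#' and gaps touching either end of the stream are left untouched.  The
#' operation never invalidates a sample and is idempotent.
#'
#' @param gaze tibble with columns `time_s`, `x`, `y`, `valid`.
#' @param max_gap maximum gap duration to fill, seconds.
#' @return The gaze tibble with short interior gaps filled.
#' @export
interpolate_gaps <- function(gaze, max_gap = 0.150) {
  stopifnot(all(c("time_s", "x", "y", "valid") %in% names(gaze)))
  if (any(diff(gaze$time_s) < 0)) abort("gaze times must be non-decreasing.")
  v <- gaze$valid
  if (all(v) || !any(v)) return(gaze)
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (g in which(!r$values)) {
    s <- starts[g]; e <- ends[g]
    if (s == 1 || e == nrow(gaze)) next       # edge gaps have no anchor
    t0 <- gaze$time_s[s - 1]; t1 <- gaze$time_s[e + 1]
    if (t1 - t0 > max_gap + 1e-9) next   # tolerance for float time stamps
    w <- (gaze$time_s[s:e] - t0) / (t1 - t0)
    gaze$x[s:e] <- gaze$x[s - 1] + w * (gaze$x[e + 1] - gaze$x[s - 1])
    gaze$y[s:e] <- gaze$y[s - 1] + w * (gaze$y[e + 1] - gaze$y[s - 1])
    gaze$valid[s:e] <- TRUE
  }
  gaze
}

#' Proportional looking time within a trial window
#'
#' Fraction of the stimulus window (0--500 ms after onset by default)
#' covered by valid gaze.  Each sample covers the interval up to the next
#' sample (interval weighting), which is robust to irregular eye-tracker
#' sampling.  Apply [interpolate_gaps()] first.
#'
#' @param gaze gaze tibble (gap-interpolated).
#' @param onset_time trial onset, seconds.
#' @param window stimulus window relative to onset, seconds.
#' @param screen optional `c(width, height)`; when given, a sample must
#'   also lie on screen to count as looking.
#' @return Proportion in `[0, 1]`; 0 when no gaze samples fall in the
#'   window.
#' @export
trial_looking_proportion <- function(gaze, onset_time, window = c(0, 0.5),
                                     screen = NULL) {
  lo <- onset_time + window[1]; hi <- onset_time + window[2]
  n <- nrow(gaze)
  if (n == 0) return(0)
  # sample i covers [time_i, time_{i+1}); last sample gets the median step
  step <- stats::median(diff(gaze$time_s))
  t_start <- gaze$time_s
  t_end <- c(gaze$time_s[-1], gaze$time_s[n] + step)
  cover <- pmax(0, pmin(t_end, hi) - pmax(t_start, lo))
  ok <- gaze$valid
  if (!is.null(screen))
    ok <- ok & !is.na(gaze$x) & !is.na(gaze$y) &
      gaze$x >= 0 & gaze$x <= screen[1] & gaze$y >= 0 & gaze$y <= screen[2]
  sum(cover[ok]) / (hi - lo)
}

#' Score every trial's gaze validity
#'
#' A trial is valid when proportional looking time during the stimulus
#' window is 50% or above (inclusive).
#'
#' @param gaze gaze tibble; gaps are interpolated internally.
#' @param onset_times trial onsets, seconds.
#' @param trial_ids trial identifiers aligned with `onset_times`.
#' @param window stimulus window, seconds.
#' @param threshold validity threshold on the looking proportion.
#' @param screen optional screen bounds, see [trial_looking_proportion()].
#' @return Tibble: `trial_id`, `looking_proportion`, `valid`.
#' @export
score_gaze_trials <- function(gaze, onset_times, trial_ids = seq_along(onset_times),
                              window = c(0, 0.5), threshold = 0.5,
                              screen = NULL) {
  gaze <- interpolate_gaps(gaze)
  prop <- vapply(onset_times, function(on)
    trial_looking_proportion(gaze, on, window, screen), 0)
  tibble(trial_id = trial_ids, looking_proportion = prop,
         valid = prop >= threshold)
}

#' Session attentiveness
#'
#' Percentage of valid eye-tracking trials relative to the number of
#' presented trials.
#'
#' @param scores tibble from [score_gaze_trials()].
#' @param n_presented total number of presented trials (>= 1).
#' @return Percentage in `[0, 100]`.
#' @export
session_attentiveness <- function(scores, n_presented) {
  if (n_presented < 1) abort("`n_presented` must be at least 1.")
  100 * sum(scores$valid) / n_presented
}

#' Highly-attentive subsample rule
#'
#' A subject is highly attentive when at least `threshold` percent of
#' trials were attended in *both* sessions (inclusive).  A missing session
#' gives `FALSE` with a `reason` attribute.
#'
#' @param pct_session1,pct_session2 attentiveness percentages.
#' @param threshold percentage threshold.
#' @return Logical.
#' @export
highly_attentive <- function(pct_session1, pct_session2, threshold = 60) {
  if (is.na(pct_session1) || is.na(pct_session2)) {
    return(structure(FALSE, reason = "session missing"))
  }
  pct_session1 >= threshold && pct_session2 >= threshold
}
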