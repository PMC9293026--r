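#' Intraclass correlation ICC(3,1)
#'
#' Two-way fixed-effects, single-measure, consistency ICC (Shrout & Fleiss
#' case 3,1): `(MS_R - MS_E) / (MS_R + (k - 1) MS_E)`, where `MS_R` is the
#' between-subject mean square and `MS_E` the residual mean square of the
#' subjects x sessions ANOVA.  The 95% CI and one-tailed p-value come from
#' the F statistic `MS_R / MS_E` on `(n - 1, (n - 1)(k - 1))` degrees of
#' freedom.  Rows with any missing value are dropped pairwise and the
#' retained `n` reported; negative estimates are reported as computed.
#'
#' @param scores an n x k numeric matrix or data frame of scores (k = 2
#'   sessions or halves), one row per subject.
#' @param conf confidence level.
#' @return An `icc_result`: `icc`, `ci_low`, `ci_high`, `p_value`, `n`,
#'   `k`, `band`, `ms_r`, `ms_e`, and `undefined` (TRUE when all retained
#'   scores are identical so the ratio is undefined).
#' @export
icc31 <- function(scores, conf = 0.95) {
  x <- as.matrix(scores)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2) abort("need at least two scores per subject.")
  if (n < 3) abort("need at least 3 complete subjects for ICC(3,1).")

  grand <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))

  if (ms_r + (k - 1) * ms_e <= .Machine$double.eps * max(1, abs(grand))^2) {
    res <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, n = n, k = k, band = NA_character_,
                ms_r = ms_r, ms_e = ms_e, undefined = TRUE)
    return(structure(res, class = "icc_result"))
  }
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (ms_e > 0) {
    f_obs <- ms_r / ms_e
    alpha <- 1 - conf
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  } else {
    ci <- c(icc, icc); p <- 0
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 n = n, k = k, band = categorize_icc(icc),
                 ms_r = ms_r, ms_e = ms_e, undefined = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined)
    cat("<icc_result> undefined (no variance between or within subjects)\n")
  else
    cat(sprintf(
      "<icc_result> ICC(3,1) = %.3f [%.3f, %.3f], p = %.3g, n = %d (%s)\n",
      x$icc, x$ci_low, x$ci_high, x$p_value, x$n, x$band))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value, n = x$n, band = x$band %||% NA_character_)
}

#' @rdname tidiers
#' @export
glance.icc_result <- function(x, ...) {
  tibble(icc = x$icc, ms_r = x$ms_r, ms_e = x$ms_e, n = x$n, k = x$k,
         undefined = x$undefined)
}

#' Interpretation band of an ICC value
#'
#' Below .40 poor; .40 to just under .60 fair; .60 to .75 good; above .75
#' excellent.
#'
#' @param value finite ICC value(s).
#' @return Character vector of bands.
#' @export
categorize_icc <- function(value) {
  dplyr::case_when(value < 0.40 ~ "poor",
                   value < 0.60 ~ "fair",
                   value <= 0.75 ~ "good",
                   TRUE ~ "excellent")
}

#' Test-retest reliability table across trial counts
#'
#' For each (condition set, feature, trial count) cell, pairs subjects'
#' session-1 and session-2 scores (pairwise-complete: a subject missing at
#' one `n` is excluded only from that cell) and computes ICC(3,1).
#'
#' @param features a feature-row tibble covering two sessions (long over
#'   subjects/sessions, wide over measures), as produced by
#'   [extract_features()] + [dplyr::bind_rows()].
#' @param measures feature columns to analyse; defaults to every numeric
#'   measure present.
#' @return Tibble: `condition_set`, `feature`, `n_trials`, `n_subjects`,
#'   `icc`, `ci_low`, `ci_high`, `p_value`, `band`.
#' @export
test_retest_table <- function(features, measures = NULL) {
  measures <- measures %||%
    intersect(c("p1_latency", "p1_amp", "n290_latency", "n290_peak_amp",
                "n290_mean_amp", "p400_mean_amp", "dtw_direction"),
              names(features))
  long <- features |>
    dplyr::select(dplyr::all_of(c("subject", "session", "condition_set",
                                  "n_trials", measures))) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "feature",
                        values_to = "score")
  cells <- long |>
    tidyr::pivot_wider(names_from = "session", values_from = "score",
                       names_prefix = "s") |>
    dplyr::group_by(.data$condition_set, .data$feature, .data$n_trials)
  dplyr::group_modify(cells, function(df, key) {
    m <- as.matrix(df[, c("s1", "s2")])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3)
      return(tibble(n_subjects = nrow(m), icc = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    band = NA_character_))
    r <- icc31(m)
    tibble(n_subjects = r$n, icc = r$icc, ci_low = r$ci_low,
           ci_high = r$ci_high, p_value = r$p_value, band = r$band)
  }) |> dplyr::ungroup()
}

#' Split clean trials into alternating halves
#'
#' Draws `n` clean trials at random, then alternates them in draw order:
#' odd positions to half A, even to half B.
#'
#' @param ts an `erp_trialset` after preprocessing.
#' @param n number of trials to draw (even).
#' @param seed integer seed.
#' @return List with integer index vectors `A` and `B` (each `n/2`), or
#'   `NULL` when fewer than `n` clean trials are available.
#' @export
split_half <- function(ts, n, seed = 1L) {
  if (n %% 2 != 0) abort("split-half needs even `n`.")
  clean <- clean_trials(ts)
  if (length(clean) < n) return(NULL)
  drawn <- with_seed(seed, resample(clean, n))
  list(A = drawn[seq(1, n, by = 2)], B = drawn[seq(2, n, by = 2)])
}

#' Within-session internal consistency
#'
#' ICC(3,1) between features computed from split halves A and B, per
#' (condition set, feature, trial count, session) cell.
#'
#' @param features_a,features_b feature-row tibbles for halves A and B
#'   (matching subjects/sessions/trial counts).
#' @param measures feature columns to analyse.
#' @return Tibble like [test_retest_table()]'s, with a `session` column.
#' @export
internal_consistency <- function(features_a, features_b, measures = NULL) {
  measures <- measures %||%
    intersect(c("p1_latency", "p1_amp", "n290_latency", "n290_peak_amp",
                "n290_mean_amp", "p400_mean_amp", "dtw_direction"),
              names(features_a))
  prep <- function(df, half) {
    df |>
      dplyr::select(dplyr::all_of(c("subject", "session", "condition_set",
                                    "n_trials", measures))) |>
      tidyr::pivot_longer(dplyr::all_of(measures), names_to = "feature",
                          values_to = half)
  }
  joined <- dplyr::inner_join(prep(features_a, "A"), prep(features_b, "B"),
                              by = c("subject", "session", "condition_set",
                                     "n_trials", "feature"))
  joined |>
    dplyr::group_by(.data$condition_set, .data$feature, .data$n_trials,
                    .data$session) |>
    dplyr::group_modify(function(df, key) {
      m <- as.matrix(df[, c("A", "B")])
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) < 3)
        return(tibble(n_subjects = nrow(m), icc = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, band = NA_character_,
                      undefined = NA))
      r <- icc31(m)
      tibble(n_subjects = r$n, icc = r$icc, ci_low = r$ci_low,
             ci_high = r$ci_high, p_value = r$p_value, band = r$band,
             undefined = r$undefined)
    }) |> dplyr::ungroup()
}

#' Face inversion effect (upright minus inverted)
#'
#' Elementwise difference of shared numeric measures between matched
#' upright and inverted feature rows; missing values propagate.
#'
#' @param upright,inverted feature-row tibbles for the two orientations.
#' @return Tibble of differences with `condition_set = "inversion_effect"`.
#' @export
inversion_effect <- function(upright, inverted) {
  keys <- intersect(c("subject", "session", "n_trials"), names(upright))
  measures <- intersect(names(upright), names(inverted))
  measures <- setdiff(measures[vapply(upright[measures], is.numeric, TRUE)],
                      c(keys, "seed"))
  j <- dplyr::inner_join(upright, inverted, by = keys,
                         suffix = c("_up", "_inv"))
  out <- j[keys]
  for (m in measures) out[[m]] <- j[[paste0(m, "_up")]] - j[[paste0(m, "_inv")]]
  out$condition_set <- "inversion_effect"
  as_tibble(out)
}

#' Paired t-test between upright and inverted features
#'
#' Standard paired t statistic on subjects with at least `min_trials` clean
#' trials in each condition; two-sided p, df = n - 1.  A zero-variance
#' difference is flagged rather than reported as an infinite t.
#'
#' @param x,y paired numeric vectors (e.g. upright and inverted scores).
#' @param min_trials minimum clean-trial count per condition; applied when
#'   `n_x`/`n_y` are given.
#' @param n_x,n_y optional clean-trial counts aligned with `x`/`y`.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y`, `n`, `degenerate`.
#' @export
paired_t <- function(x, y, min_trials = 20, n_x = NULL, n_y = NULL) {
  keep <- stats::complete.cases(x, y)
  if (!is.null(n_x)) keep <- keep & n_x >= min_trials
  if (!is.null(n_y)) keep <- keep & n_y >= min_trials
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) abort("need at least 2 complete pairs after the trial filter.")
  d <- x - y
  if (stats::sd(d) == 0) {
    # identical columns: t = 0, p = 1; constant nonzero difference:
    # undefined t, flagged
    zero <- all(d == 0)
    return(tibble(t = if (zero) 0 else NA_real_, df = n - 1,
                  p_value = if (zero) 1 else NA_real_,
                  mean_x = mean(x), mean_y = mean(y),
                  sd_x = stats::sd(x), sd_y = stats::sd(y), n = n,
                  degenerate = !zero))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y),
         sd_x = stats::sd(x), sd_y = stats::sd(y), n = n,
         degenerate = FALSE)
}
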