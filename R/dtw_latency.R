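#' Dynamic time warping between two waveform segments
#'
#' Aligns an individual waveform segment to a reference segment of the same
#' length by dynamic programming over the local cost
#' `|ref[i] - ind[j]|` (or squared difference), with steps (1,1), (0,1),
#' (1,0) and boundary-to-boundary alignment.  Ties in the accumulated cost
#' prefer the diagonal step, then the step advancing the individual index,
#' which makes the identity path unique: aligning a waveform with itself
#' always yields direction 0 exactly.
#'
#' The *direction* statistic is the signed area between the warping path
#' and the main diagonal of the cost matrix, normalised by the area under
#' the diagonal: `sum(j - i) / (N (N - 1) / 2)` over path vertices.  Zero
#' means identical timing; positive means the individual waveform lags the
#' reference (longer latency); negative means it leads.
#'
#' @param ref reference segment (numeric, length N >= 2).
#' @param ind individual segment (same length).
#' @param metric `"abs"` or `"sq"` local cost.
#' @return A `dtw_result`: `direction`, `path` (tibble `i`, `j`), `cost`
#'   (total accumulated distance), `n`.
#' @export
dtw_align <- function(ref, ind, metric = c("abs", "sq")) {
  metric <- match.arg(metric)
  n <- length(ref)
  if (n < 2 || length(ind) != n)
    abort("segments must have equal length N >= 2.")
  if (!all(is.finite(ref)) || !all(is.finite(ind)))
    abort("non-finite values in DTW input.")
  local <- abs(outer(ref, ind, "-"))
  if (metric == "sq") local <- local^2

  D <- matrix(Inf, n, n)
  D[1, 1] <- local[1, 1]
  for (j in 2:n) D[1, j] <- D[1, j - 1] + local[1, j]
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + local[i, 1]
    for (j in 2:n)
      D[i, j] <- local[i, j] + min(D[i - 1, j - 1], D[i, j - 1], D[i - 1, j])
  }

  # backtrack; on ties prefer diagonal, then the step advancing j
  path <- matrix(NA_integer_, 2 * n, 2)
  i <- n; j <- n; p <- 1
  path[p, ] <- c(i, j)
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1 }
    else if (j == 1) { i <- i - 1 }
    else {
      cand <- c(D[i - 1, j - 1], D[i, j - 1], D[i - 1, j])
      k <- which.min(cand)          # which.min takes the first on ties
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) { j <- j - 1 }
      else { i <- i - 1 }
    }
    p <- p + 1
    path[p, ] <- c(i, j)
  }
  path <- path[p:1, , drop = FALSE]
  direction <- sum(path[, 2] - path[, 1]) / (n * (n - 1) / 2)
  structure(list(direction = direction,
                 path = tibble(i = path[, 1], j = path[, 2]),
                 cost = D[n, n], n = n, metric = metric),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> N = %d, direction = %.4f, cost = %.3f (%s metric)\n",
              x$n, x$direction, x$cost, x$metric))
  invisible(x)
}

#' DTW direction of an individual waveform against a reference
#'
#' Crops both waveforms to the component window (e.g. the P1 window
#' 50--200 ms for checkerboards, the N290 window 190--350 ms for faces),
#' aligns them and returns the signed, normalised warping-path area.  The
#' reference is typically the grand average.
#'
#' @param individual an [erp_waveform()].
#' @param reference an [erp_waveform()] on the same time axis (e.g. from
#'   [grand_average()]).
#' @param window component window `(lo, hi)`, ms.
#' @param metric local cost metric, `"abs"` or `"sq"`.
#' @return The direction scalar (dimensionless).
#' @export
dtw_direction <- function(individual, reference, window,
                          metric = c("abs", "sq")) {
  if (window[1] < min(individual$time_axis) - 1e-9 ||
      window[2] > max(individual$time_axis) + 1e-9)
    abort("window outside the epoch.")
  if (length(individual$amplitude) != length(reference$amplitude))
    abort("individual and reference must share the sampling grid.")
  idx <- window_indices(window, individual$time_axis)
  dtw_align(reference$amplitude[idx], individual$amplitude[idx],
            metric = metric)$direction
}

#' @rdname tidiers
#' @export
tidy.dtw_result <- function(x, ...) {
  tibble(direction = x$direction, cost = x$cost, n = x$n,
         path_length = nrow(x$path), metric = x$metric)
}
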