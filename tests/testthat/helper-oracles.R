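# Independent brute-force oracles used across the suite.

# Peak oracle, written from the rule's definition rather than run-length
# encoding: index p is a positive peak iff the next sample is strictly
# lower and scanning left over any plateau of equal values reaches a
# strictly lower sample without hitting the start of the series.
oracle_peaks <- function(x) {
  n <- length(x)
  out <- list()
  for (p in seq_len(n)) {
    if (p == n) next
    for (sign in c(1, -1)) {
      if (sign * x[p + 1] >= sign * x[p]) next
      s <- p
      while (s > 1 && x[s - 1] == x[p]) s <- s - 1
      if (s == 1) next
      if (sign * x[s - 1] < sign * x[p])
        out[[length(out) + 1]] <- c(sign, p)
    }
  }
  if (!length(out)) return(matrix(numeric(), 0, 2))
  do.call(rbind, out)
}

# Exhaustive DTW oracle: enumerate every monotone boundary-to-boundary
# path for small N and return the minimum total cost and the per-path
# signed areas of all minimizers.
oracle_dtw <- function(ref, ind, metric = "abs") {
  n <- length(ref)
  local <- abs(outer(ref, ind, "-"))
  if (metric == "sq") local <- local^2
  best <- Inf; areas <- numeric()
  walk <- function(i, j, cost, area) {
    cost <- cost + local[i, j]
    if (cost > best + 1e-12) return()
    area <- area + (j - i)
    if (i == n && j == n) {
      if (cost < best - 1e-12) { best <<- cost; areas <<- area }
      else areas <<- c(areas, area)
      return()
    }
    if (i < n && j < n) walk(i + 1, j + 1, cost, area)
    if (j < n) walk(i, j + 1, cost, area)
    if (i < n) walk(i + 1, j, cost, area)
  }
  walk(1, 1, 0, 0)
  list(cost = best, directions = unique(areas) / (n * (n - 1) / 2))
}

# ICC(3,1) oracle from explicit double sums over the definition of the
# two-way ANOVA sums of squares.
oracle_icc31 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_r <- 0
  for (i in seq_len(n)) ss_r <- ss_r + k * (sum(m[i, ]) / k - grand)^2
  ss_c <- 0
  for (j in seq_len(k)) ss_c <- ss_c + n * (sum(m[, j]) / n - grand)^2
  ss_t <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_t <- ss_t + (m[i, j] - grand)^2
  ms_r <- ss_r / (n - 1)
  ms_e <- (ss_t - ss_r - ss_c) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}

# paired t oracle by the textbook formula, explicit sums
oracle_paired_t <- function(x, y) {
  n <- length(x)
  d <- x - y
  dbar <- sum(d) / n
  sd_d <- sqrt(sum((d - dbar)^2) / (n - 1))
  t <- dbar / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# continuous-truth helpers for feature recovery: fine-grid peak of the
# noiseless kernel sum and the discrete 60-ms window mean of that truth
truth_peak <- function(components, truth, window, polarity, step = 0.01) {
  tg <- seq(window[1], window[2], by = step)
  y <- kernel_sum(components, truth, tg)
  tg[if (polarity > 0) which.max(y) else which.min(y)]
}

truth_win_amp <- function(components, truth, latency, halfwidth = 30,
                          sample_ms = 2) {
  mean(kernel_sum(components, truth,
                  latency + seq(-halfwidth, halfwidth, by = sample_ms)))
}
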