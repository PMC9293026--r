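#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

CONDITION_VOCAB <- c("checkerboard", "face_upright", "face_inverted",
                     "animal_upright", "animal_inverted")

FACE_CONDITIONS <- c("face_upright", "face_inverted")

#' Derive a reproducible sub-seed from a master seed
#'
#' Sub-seeds for subsampling, splitting and simulation are derived from one
#' master seed and a list of labels (subject, session, condition set, trial
#' count, stage, ...) with a polynomial rolling hash, so that every random
#' draw in a run is reproducible and independent draws do not share a stream.
#'
#' @param master integer master seed.
#' @param ... labels identifying the draw; coerced to character.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "s01", 2, "faces_all", 20)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(c(format(master), vapply(list(...), as.character, "")),
               collapse = "\r")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# run expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# ms -> index into a time axis (nearest sample, ties round half up)
ms_to_index <- function(time_ms, axis_ms) {
  step <- axis_ms[2] - axis_ms[1]
  idx <- floor((time_ms - axis_ms[1]) / step + 0.5) + 1
  as.integer(pmin(pmax(idx, 1L), length(axis_ms)))
}

# inclusive index range of a (lo, hi) ms window on a time axis
window_indices <- function(window, axis_ms) {
  i1 <- ms_to_index(window[1], axis_ms)
  i2 <- ms_to_index(window[2], axis_ms)
  seq.int(i1, i2)
}
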