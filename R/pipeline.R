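PIPELINE_KEYS <- c("out_dir", "master_seed", "simulate", "preproc", "dtw",
                   "grids", "reliability", "split_half",
                   "attentiveness_threshold", "grand_average")

#' Default analysis configuration
#'
#' Trial-count grids follow the reliability design: checkerboards
#' 10--50 + all, collapsed faces 10--100 + all (balanced
#' upright/inverted), single orientations 10--60 + all.
#'
#' @param n_subjects,seed simulator size and master seed for a
#'   simulate-then-analyse run.
#' @param out_dir output directory.
#' @return A nested list accepted by [run_pipeline()].
#' @export
default_config <- function(n_subjects = 10, seed = 1L,
                           out_dir = tempfile("erp_run_")) {
  list(
    out_dir = out_dir,
    master_seed = as.integer(seed),
    simulate = unclass(cohort_spec(n_subjects, seed = seed)),
    preproc = unclass(preproc_config())[c("bp_lo", "bp_hi", "pad",
                                          "flat_eps", "amp_thresh",
                                          "bad_channel_prop")],
    dtw = list(metric = "abs"),
    grids = list(checkerboard = c(10, 20, 30, 40, 50),
                 faces_all = seq(10, 100, by = 10),
                 orientation = seq(10, 60, by = 10),
                 include_all = TRUE),
    reliability = list(min_trials_paired = 20),
    split_half = TRUE,
    attentiveness_threshold = 60,
    grand_average = list(min_trials = 10, min_abs_amp = 1)
  )
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  base <- default_config()
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      unknown <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(unknown))
        abort(sprintf("unknown config key(s) under '%s': %s", k,
                      paste(unknown, collapse = ", ")))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  if (base$preproc$bp_hi >= 500 / 2)
    abort("config error: bp_hi must be below half the 500 Hz sampling rate.")
  if (base$preproc$bp_lo >= base$preproc$bp_hi)
    abort("config error: bp_lo must be below bp_hi.")
  base
}

condition_set_defs <- function() {
  list(checkerboard   = list(family = "checkerboard", balance = FALSE,
                             conditions = NULL, grid = "checkerboard"),
       faces_all      = list(family = "faces", balance = TRUE,
                             conditions = NULL, grid = "faces_all"),
       faces_upright  = list(family = "faces", balance = FALSE,
                             conditions = "face_upright", grid = "orientation"),
       faces_inverted = list(family = "faces", balance = FALSE,
                             conditions = "face_inverted", grid = "orientation"))
}

dtw_window_for <- function(set) {
  if (set == "checkerboard") default_windows()$P1$window
  else default_windows()$N290$window
}

#' Inclusion rates across trial-count cutoffs
#'
#' For each cutoff, the percentage of subjects whose clean-trial count
#' reaches it, relative to (a) the full roster and (b) the subjects with
#' any usable data (count of at least 1).  Percentages are non-increasing
#' in the cutoff.
#'
#' @param counts clean-trial count per rostered subject (0 for subjects
#'   without data).
#' @param cutoffs trial-count cutoffs.
#' @param n_roster roster size; defaults to `length(counts)`.
#' @return Tibble: `cutoff`, `n_included`, `pct_roster`, `pct_with_data`.
#' @export
inclusion_rates <- function(counts, cutoffs = c(1, 10, 20, 30, 40, 50),
                            n_roster = length(counts)) {
  if (n_roster < 1) abort("empty roster.")
  n_data <- sum(counts >= 1)
  purrr::map_dfr(cutoffs, function(cut) {
    inc <- sum(counts >= cut)
    tibble(cutoff = cut, n_included = inc,
           pct_roster = 100 * inc / n_roster,
           pct_with_data = if (n_data > 0) 100 * inc / n_data else 0)
  })
}

preprocess_session_families <- function(rec, events, pcfg) {
  list(checkerboard = preprocess_trials(rec, events, "checkerboard", pcfg),
       faces = preprocess_trials(rec, events, "faces", pcfg))
}

grid_for <- function(cfg, def, ts, conditions = NULL) {
  g <- cfg$grids[[def$grid]]
  labs <- as.character(g)
  if (isTRUE(cfg$grids$include_all)) labs <- c(labs, "all")
  labs
}

n_available <- function(ts, def) {
  clean <- clean_trials(ts)
  if (!is.null(def$conditions))
    clean <- intersect(clean, which(ts$trials$condition %in% def$conditions))
  if (def$balance) {
    up <- intersect(clean, which(ts$trials$condition == "face_upright"))
    inv <- intersect(clean, which(ts$trials$condition == "face_inverted"))
    2 * min(length(up), length(inv))
  } else length(clean)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates a cohort (or accepts one already simulated), preprocesses both
#' condition families, scores gaze validity and attentiveness, extracts ERP
#' features over the trial-count grids (with derived, logged sub-seeds),
#' computes DTW direction against the grand averages, and produces
#' test-retest, split-half, inversion-effect and inclusion-rate tables plus
#' a plain-text report in the output directory.  Deterministic under
#' `master_seed`.
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file with the same structure; unknown keys are rejected.
#' @param cohort optionally, a pre-built [simulate_cohort()] result to
#'   analyse instead of simulating from `config$simulate`.
#' @return Invisibly, a list with the output directory and the main tables.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$master_seed
  pcfg <- preproc_config(bp_lo = cfg$preproc$bp_lo, bp_hi = cfg$preproc$bp_hi,
                         pad = cfg$preproc$pad, flat_eps = cfg$preproc$flat_eps,
                         amp_thresh = cfg$preproc$amp_thresh,
                         bad_channel_prop = cfg$preproc$bad_channel_prop)
  if (is.null(cohort)) {
    cs <- cohort_spec(n_subjects = cfg$simulate$n_subjects,
                      n_sessions = cfg$simulate$n_sessions,
                      trials_checkerboard = cfg$simulate$trials_checkerboard,
                      trials_face_upright = cfg$simulate$trials_face_upright,
                      trials_face_inverted = cfg$simulate$trials_face_inverted,
                      noise_sd = cfg$simulate$noise_sd,
                      pink_exponent = cfg$simulate$pink_exponent,
                      artifact_rate_amp = cfg$simulate$artifact_rate_amp,
                      artifact_rate_flat = cfg$simulate$artifact_rate_flat,
                      gaze_gap_rate = cfg$simulate$gaze_gap_rate,
                      common_mode_amp = cfg$simulate$common_mode_amp,
                      seed = seed)
    cohort <- simulate_cohort(cs, seed = seed)
  }
  sets <- condition_set_defs()
  seed_log <- list(); excl_log <- list()
  gaze_rows <- list(); count_rows <- list()
  prep <- list(); all_waves <- list()

  for (ses in cohort$sessions) {
    key <- sprintf("s%03d_v%d", ses$subject, ses$session)
    fams <- preprocess_session_families(ses$recording, ses$events, pcfg)
    prep[[key]] <- list(subject = ses$subject, session = ses$session,
                        fams = fams)
    for (fam in names(fams)) {
      tr <- fams[[fam]]$trials
      ex <- tr[tr$excluded, c("trial_id", "reason")]
      if (nrow(ex))
        excl_log[[length(excl_log) + 1]] <-
          dplyr::mutate(ex, subject = ses$subject, session = ses$session,
                        family = fam)
    }
    sc <- score_gaze_trials(ses$gaze,
                            (ses$events$onset_sample - 1) / ses$recording$fs,
                            ses$events$trial_id)
    gaze_rows[[key]] <- tibble(subject = ses$subject, session = ses$session,
                               attentiveness = session_attentiveness(
                                 sc, nrow(ses$events)))
    for (set in names(sets)) {
      def <- sets[[set]]
      ts <- fams[[def$family]]
      count_rows[[paste(key, set)]] <-
        tibble(subject = ses$subject, session = ses$session,
               condition_set = set, n_clean = n_available(ts, def))
      # full-trial average for the grand average and the "all" cells
      avail <- n_available(ts, def)
      if (avail >= 1) {
        n_all <- if (def$balance) avail - avail %% 2 else avail
        if (n_all >= 1) {
          sseed <- derive_seed(seed, ses$subject, ses$session, set, "all",
                               "subsample")
          seed_log[[length(seed_log) + 1]] <-
            tibble(subject = ses$subject, session = ses$session,
                   condition_set = set, n_trials = "all", seed = sseed)
          idx <- subsample_trials(ts, n_all, balance = def$balance,
                                  conditions = def$conditions, seed = sseed)
          w <- average_trials(ts, idx, condition_set = set, seed = sseed)
          w$subject <- ses$subject; w$session <- ses$session
          all_waves[[set]] <- c(all_waves[[set]], list(w))
        }
      }
    }
  }

  gref <- purrr::map(all_waves, function(ws)
    tryCatch(grand_average(ws, cfg$grand_average$min_trials,
                           cfg$grand_average$min_abs_amp),
             error = function(e) NULL))

  feat_rows <- list(); sh_a <- list(); sh_b <- list()
  for (p in prep) {
    for (set in names(sets)) {
      def <- sets[[set]]
      ts <- p$fams[[def$family]]
      for (lab in grid_for(cfg, def, ts)) {
        n <- if (lab == "all") {
          av <- n_available(ts, def)
          if (def$balance) av - av %% 2 else av
        } else as.integer(lab)
        if (n < 1) next
        sseed <- derive_seed(seed, p$subject, p$session, set, lab, "subsample")
        idx <- subsample_trials(ts, n, balance = def$balance,
                                conditions = def$conditions, seed = sseed)
        if (is.null(idx)) next
        w <- average_trials(ts, idx, condition_set = set, seed = sseed)
        w$subject <- p$subject; w$session <- p$session
        fr <- extract_features(w)
        fr$n_trials <- lab
        if (!is.null(gref[[set]]))
          fr$dtw_direction <- dtw_direction(w, gref[[set]],
                                            dtw_window_for(set),
                                            metric = cfg$dtw$metric)
        feat_rows[[length(feat_rows) + 1]] <- fr
      }
      # split halves (checkerboard and collapsed faces)
      if (isTRUE(cfg$split_half) && set %in% c("checkerboard", "faces_all")) {
        for (lab in setdiff(grid_for(cfg, def, ts), "all")) {
          n <- as.integer(lab)
          hseed <- derive_seed(seed, p$subject, p$session, set, lab, "split")
          halves <- split_half(ts, n, seed = hseed)
          if (is.null(halves)) next
          for (h in c("A", "B")) {
            w <- average_trials(ts, halves[[h]], condition_set = set,
                                seed = hseed)
            w$subject <- p$subject; w$session <- p$session
            fr <- extract_features(w)
            fr$n_trials <- lab
            if (h == "A") sh_a[[length(sh_a) + 1]] <- fr
            else sh_b[[length(sh_b) + 1]] <- fr
          }
        }
      }
    }
  }

  features <- dplyr::bind_rows(feat_rows)
  counts <- dplyr::bind_rows(count_rows)
  gaze_tbl <- dplyr::bind_rows(gaze_rows)

  trt <- test_retest_table(features)
  ic <- if (length(sh_a))
    internal_consistency(dplyr::bind_rows(sh_a), dplyr::bind_rows(sh_b))
  else NULL

  up <- dplyr::filter(features, .data$condition_set == "faces_upright")
  inv <- dplyr::filter(features, .data$condition_set == "faces_inverted")
  inv_eff <- if (nrow(up) && nrow(inv)) inversion_effect(up, inv) else NULL
  inv_trt <- if (!is.null(inv_eff) && nrow(inv_eff)) {
    tryCatch(test_retest_table(inv_eff), error = function(e) NULL)
  } else NULL

  # paired inversion test at session 1, >= 20 clean trials per orientation
  pt <- tryCatch({
    c_up <- dplyr::filter(counts, .data$condition_set == "faces_upright",
                          .data$session == 1)
    c_inv <- dplyr::filter(counts, .data$condition_set == "faces_inverted",
                           .data$session == 1)
    u1 <- dplyr::filter(up, .data$session == 1, .data$n_trials == "all") |>
      dplyr::left_join(c_up[c("subject", "n_clean")], by = "subject")
    i1 <- dplyr::filter(inv, .data$session == 1, .data$n_trials == "all") |>
      dplyr::left_join(c_inv[c("subject", "n_clean")], by = "subject")
    j <- dplyr::inner_join(u1, i1, by = "subject", suffix = c("_up", "_inv"))
    purrr::map_dfr(c("n290_latency", "n290_peak_amp", "n290_mean_amp",
                     "p400_mean_amp", "dtw_direction"), function(m) {
      cu <- paste0(m, "_up"); ci <- paste0(m, "_inv")
      if (!all(c(cu, ci) %in% names(j))) return(NULL)
      dplyr::mutate(paired_t(j[[cu]], j[[ci]],
                             min_trials = cfg$reliability$min_trials_paired,
                             n_x = j$n_clean_up, n_y = j$n_clean_inv),
                    feature = m, .before = 1)
    })
  }, error = function(e) NULL)

  # attentiveness and inclusion accounting
  att <- tidyr::pivot_wider(gaze_tbl, names_from = "session",
                            values_from = "attentiveness",
                            names_prefix = "v")
  if (!"v2" %in% names(att)) att$v2 <- NA_real_
  att <- dplyr::mutate(att, highly_attentive = purrr::map2_lgl(
    .data$v1, .data$v2,
    ~ as.logical(highly_attentive(.x, .y, cfg$attentiveness_threshold))))
  incl <- counts |>
    dplyr::filter(.data$session == 1) |>
    dplyr::group_by(.data$condition_set) |>
    dplyr::group_modify(function(df, key) {
      cc <- df$n_clean[match(seq_len(max(df$subject)), df$subject)]
      cc[is.na(cc)] <- 0
      inclusion_rates(cc, cutoffs = c(1, 10, 20, 30, 40, 50))
    }) |> dplyr::ungroup()

  write_table(features, file.path(cfg$out_dir, "features.csv"))
  write_table(trt, file.path(cfg$out_dir, "test_retest.csv"))
  if (!is.null(ic)) write_table(ic, file.path(cfg$out_dir,
                                              "internal_consistency.csv"))
  if (!is.null(inv_trt)) write_table(inv_trt,
                                     file.path(cfg$out_dir,
                                               "inversion_test_retest.csv"))
  if (!is.null(pt)) write_table(pt, file.path(cfg$out_dir, "paired_t.csv"))
  write_table(incl, file.path(cfg$out_dir, "inclusion.csv"))
  write_table(gaze_tbl, file.path(cfg$out_dir, "attentiveness.csv"))
  write_table(counts, file.path(cfg$out_dir, "clean_trial_counts.csv"))
  if (length(excl_log))
    write_table(dplyr::bind_rows(excl_log),
                file.path(cfg$out_dir, "exclusion_log.tsv"), "tsv")
  if (length(seed_log))
    write_table(dplyr::bind_rows(seed_log),
                file.path(cfg$out_dir, "seeds.tsv"), "tsv")
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config_resolved.yaml"))

  report <- c(
    sprintf("erpreliab pipeline run (master seed %d)", seed),
    sprintf("subjects: %d, sessions per subject: %d",
            length(unique(counts$subject)), length(unique(counts$session))),
    sprintf("feature rows: %d", nrow(features)),
    sprintf("test-retest cells: %d", nrow(trt)),
    sprintf("highly attentive subjects: %s",
            format(sum(att$highly_attentive, na.rm = TRUE))))
  writeLines(report, file.path(cfg$out_dir, "report.txt"))

  invisible(list(out_dir = cfg$out_dir, features = features,
                 test_retest = trt, internal_consistency = ic,
                 inversion_test_retest = inv_trt, paired_t = pt,
                 inclusion = incl, attentiveness = att, counts = counts,
                 grand_averages = gref))
}
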