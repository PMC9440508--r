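#' Evaluation experiment configuration
#'
#' @param protocol One of `"subject_dependent"`, `"leave_one_out"`,
#'   `"best_subject_transfer"`.
#' @param decoder Which decoder to evaluate: `"multi"` (the pair-selection
#'   scheme), `"single"` (one d = 3 filter) or `"three"` (three d = 1
#'   filters).
#' @param channels EMG channels used (default all four; e.g.
#'   `c("biceps", "triceps")` for the two-channel ablation).
#' @param train_fraction Fraction of windows used for training in the
#'   subject-dependent folds (default 0.75).
#' @param n_folds Number of random folds (default 10).
#' @param validation_fraction Fraction of the training windows used by
#'   [select_combinations()] (default 0.2).
#' @param split `"folds"` (contiguous random 75/25 blocks) or `"session"`
#'   (first session trains, second tests).
#' @param seed Master seed; all fold and validation placements derive from
#'   it deterministically.
#' @param preprocess A [preprocess_config()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(protocol = c("subject_dependent", "leave_one_out",
                                           "best_subject_transfer"),
                              decoder = c("multi", "single", "three"),
                              channels = emg_channels(),
                              train_fraction = 0.75, n_folds = 10,
                              validation_fraction = 0.2,
                              split = c("folds", "session"),
                              seed = 1,
                              preprocess = preprocess_config()) {
  protocol <- match.arg(protocol)
  decoder <- match.arg(decoder)
  split <- match.arg(split)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_emgk("emgk_parameter_error", "train_fraction must be in (0, 1)")
  }
  if (n_folds < 1) stop_emgk("emgk_parameter_error", "n_folds must be >= 1")
  structure(
    list(protocol = protocol, decoder = decoder, channels = channels,
         train_fraction = train_fraction, n_folds = n_folds,
         validation_fraction = validation_fraction, split = split,
         seed = seed, preprocess = preprocess),
    class = "experiment_config"
  )
}

# Window every session of a subject at the envelope level (normalization is
# deferred so protocols can derive constants from training windows only).
subject_segments <- function(subject, config) {
  lapply(subject$sessions, function(s) {
    if (s$preprocessing_state == "raw") s <- envelope_session(s, config$preprocess)
    window_session(s, config$preprocess)
  })
}

fit_decoder_for <- function(train_segs, config, selection_seed) {
  switch(config$decoder,
    multi = fit_multi_decoder(
      train_segs,
      selection = select_combinations(
        train_segs, validation_fraction = config$validation_fraction,
        seed = selection_seed, channels = config$channels
      )
    ),
    single = fit_single_decoder(train_segs, channels = config$channels),
    three = fit_three_decoder(train_segs, channels = config$channels)
  )
}

# Train on `train_segs`, decode each test segment, score pooled windows.
evaluate_split <- function(train_segs, test_segs, config, selection_seed,
                           subject_id, fold_id) {
  np <- windowed_norm_params(train_segs)
  train_n <- lapply(train_segs, normalize_windowed, params = np,
                    config = config$preprocess)
  test_n <- lapply(test_segs, normalize_windowed, params = np,
                   config = config$preprocess)
  decoder <- fit_decoder_for(train_n, config, selection_seed)
  actual <- do.call(rbind, lapply(test_n, function(s) s$states))
  decoded <- do.call(rbind, lapply(test_n, function(s) {
    decode_kinematics(decoder, s$measurements)
  }))
  score_decoding(actual, decoded, subject_id = subject_id, fold_id = fold_id)
}

#' Subject-dependent evaluation
#'
#' For every subject: the subject's windowed data are split into a
#' contiguous test block covering `1 - train_fraction` of the windows at a
#' seeded random offset (the rest train), repeated for `n_folds` folds;
#' alternatively (`split = "session"`) the first session trains and the
#' second tests. Normalization constants come from the training windows
#' only. Returns one CC/RMSE/NRMSE row per subject, fold and parameter.
#'
#' @param cohort List of subjects as produced by [generate_cohort()] (each a
#'   list with `subject_id` and `sessions`).
#' @param config An [experiment_config()].
#' @return An object of class `score_report` (a data.frame); see
#'   [summarize_report()].
#' @export
run_subject_dependent <- function(cohort, config = experiment_config()) {
  rows <- list()
  for (si in seq_along(cohort)) {
    subject <- cohort[[si]]
    segs <- tryCatch(subject_segments(subject, config),
                     emgk_validation_error = function(e) NULL)
    if (is.null(segs)) {
      message(sprintf("skipping subject %s: too short to window",
                      subject$subject_id))
      next
    }
    if (config$split == "session") {
      if (length(segs) < 2) {
        message(sprintf("skipping subject %s: session split needs 2 sessions",
                        subject$subject_id))
        next
      }
      rows[[length(rows) + 1]] <- evaluate_split(
        segs[1], segs[2], config,
        selection_seed = (config$seed * 7919L + si) %% 2147483647L,
        subject_id = subject$subject_id, fold_id = 1L
      )
      next
    }
    caps <- vapply(segs, function(s) s$n_windows, numeric(1))
    for (fold in seq_len(config$n_folds)) {
      fold_seed <- (config$seed * 7919L + si * 613L + fold) %% 2147483647L
      test_len <- round((1 - config$train_fraction) * sum(caps))
      room <- pmax(0, caps - test_len + 1)
      pick <- with_local_seed(fold_seed, {
        seg_i <- sample.int(length(segs), 1, prob = room)
        start <- sample.int(room[seg_i], 1)
        c(seg_i, start)
      })
      sp <- split_segment_around(segs[[pick[1]]], pick[2], test_len)
      train_segs <- c(segs[-pick[1]], sp$train)
      rows[[length(rows) + 1]] <- evaluate_split(
        train_segs, list(sp$validation), config,
        selection_seed = fold_seed + 1L,
        subject_id = subject$subject_id, fold_id = fold
      )
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("score_report", class(report))
  report
}

#' Leave-one-subject-out evaluation
#'
#' For each held-out subject, the windowed sessions of all remaining
#' subjects are normalized per subject, pooled by concatenation, and used to
#' select and fit the decoder; the held-out subject's sessions (normalized
#' with their own constants) are then decoded and scored.
#'
#' @inheritParams run_subject_dependent
#' @return A `score_report` with one fold per held-out subject.
#' @export
run_leave_one_out <- function(cohort, config = experiment_config()) {
  if (length(cohort) < 2) {
    stop_emgk("emgk_validation_error", "leave-one-out needs >= 2 subjects")
  }
  all_segs <- lapply(cohort, function(su) {
    segs <- subject_segments(su, config)
    np <- windowed_norm_params(segs)
    lapply(segs, normalize_windowed, params = np, config = config$preprocess)
  })
  rows <- list()
  for (si in seq_along(cohort)) {
    train_segs <- do.call(c, all_segs[-si])
    decoder <- fit_decoder_for(
      train_segs, config,
      selection_seed = (config$seed * 104729L + si) %% 2147483647L
    )
    test_segs <- all_segs[[si]]
    actual <- do.call(rbind, lapply(test_segs, function(s) s$states))
    decoded <- do.call(rbind, lapply(test_segs, function(s) {
      decode_kinematics(decoder, s$measurements)
    }))
    rows[[length(rows) + 1]] <- score_decoding(
      actual, decoded, subject_id = cohort[[si]]$subject_id, fold_id = 1L
    )
  }
  report <- do.call(rbind, rows)
  class(report) <- c("score_report", class(report))
  report
}

#' Best-subject transfer evaluation
#'
#' Trains the decoder on one donor subject only and decodes every other
#' subject. If `donor` is `NULL`, the donor is the subject with the highest
#' mean subject-dependent CC (computed with the same configuration).
#'
#' @inheritParams run_subject_dependent
#' @param donor Subject id of the training donor, or `NULL` to pick the best
#'   subject-dependent performer.
#' @return A `score_report` with one fold per recipient subject.
#' @export
run_best_subject_transfer <- function(cohort, config = experiment_config(),
                                      donor = NULL) {
  ids <- vapply(cohort, function(su) su$subject_id, character(1))
  if (is.null(donor)) {
    sd_cfg <- config
    sd_cfg$protocol <- "subject_dependent"
    sd_report <- run_subject_dependent(cohort, sd_cfg)
    mean_cc <- tapply(sd_report$cc, sd_report$subject, mean, na.rm = TRUE)
    donor <- names(which.max(mean_cc))
  }
  if (!donor %in% ids) {
    stop_emgk("emgk_validation_error", "unknown donor subject '%s'", donor)
  }
  di <- match(donor, ids)
  all_segs <- lapply(cohort, function(su) {
    segs <- subject_segments(su, config)
    np <- windowed_norm_params(segs)
    lapply(segs, normalize_windowed, params = np, config = config$preprocess)
  })
  decoder <- fit_decoder_for(
    all_segs[[di]], config,
    selection_seed = (config$seed * 15485863L + di) %% 2147483647L
  )
  rows <- list()
  for (si in setdiff(seq_along(cohort), di)) {
    test_segs <- all_segs[[si]]
    actual <- do.call(rbind, lapply(test_segs, function(s) s$states))
    decoded <- do.call(rbind, lapply(test_segs, function(s) {
      decode_kinematics(decoder, s$measurements)
    }))
    rows[[length(rows) + 1]] <- score_decoding(
      actual, decoded, subject_id = cohort[[si]]$subject_id, fold_id = 1L
    )
  }
  report <- do.call(rbind, rows)
  attr(report, "donor") <- donor
  class(report) <- c("score_report", class(report))
  report
}

#' Summarize a score report
#'
#' Per-subject mean and standard deviation over folds for each parameter,
#' plus a grand row per parameter computed as the mean (and sd) of the
#' per-subject means -- never a silent pooling of all folds.
#'
#' @param report A `score_report`.
#' @return List with data.frames `per_subject` and `grand`.
#' @export
summarize_report <- function(report) {
  agg <- stats::aggregate(cbind(cc, nrmse) ~ subject + parameter,
                          data = report, FUN = mean, na.action = stats::na.omit)
  sds <- stats::aggregate(cbind(cc, nrmse) ~ subject + parameter,
                          data = report, FUN = stats::sd,
                          na.action = stats::na.omit)
  per_subject <- data.frame(
    subject = agg$subject, parameter = agg$parameter,
    cc_mean = agg$cc, cc_sd = sds$cc,
    nrmse_mean = agg$nrmse, nrmse_sd = sds$nrmse
  )
  g <- lapply(split(per_subject, per_subject$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               cc_mean = mean(d$cc_mean), cc_sd = stats::sd(d$cc_mean),
               nrmse_mean = mean(d$nrmse_mean),
               nrmse_sd = stats::sd(d$nrmse_mean))
  })
  grand <- do.call(rbind, g)
  rownames(grand) <- NULL
  list(per_subject = per_subject, grand = grand)
}

#' Write a score report as tidy CSV
#'
#' @param report A `score_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  df[c("cc", "rmse", "nrmse")] <-
    lapply(df[c("cc", "rmse", "nrmse")],
           function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
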