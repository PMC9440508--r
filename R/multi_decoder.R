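# Run code with a local, restorable RNG stream so seeded helpers do not
# disturb the caller's random state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Candidate state pairs
#'
#' The three two-parameter filter states considered by the multi-filter
#' scheme, in canonical order.
#'
#' @return Named list of character pairs: `theta_x`, `theta_y`, `x_y`.
#' @export
candidate_pairs <- function() {
  list(theta_x = c("theta", "x"),
       theta_y = c("theta", "y"),
       x_y = c("x", "y"))
}

split_segment_around <- function(seg, start, len) {
  m <- seg$n_windows
  idx_val <- seq(start, start + len - 1)
  before <- seq_len(start - 1)
  after <- if (start + len <= m) seq(start + len, m) else integer(0)
  take <- function(ix) {
    if (length(ix) < 2) return(NULL)
    windowed_session(seg$states[ix, , drop = FALSE],
                     seg$measurements[ix, , drop = FALSE],
                     dt_window = seg$dt_window,
                     window_times = seg$window_times[ix],
                     state_labels = seg$state_labels,
                     channels = seg$channels)
  }
  list(validation = take(idx_val),
       train = Filter(Negate(is.null), list(take(before), take(after))))
}

#' Select the best state-pair filter per parameter
#'
#' The model-selection step of the multi-filter scheme. A contiguous
#' validation block covering `validation_fraction` of each training segment
#' is drawn at a seeded random offset (for a single training session this is
#' one contiguous block of the requested fraction; contiguity respects the
#' temporal dependence the filter exploits and prevents leakage across
#' adjacent windows). A Kalman filter is fitted for each of the three
#' candidate pairs on the remaining windows; each filter decodes the
#' validation block(s); and, for each parameter, the pair with the highest
#' validation CC among the two pairs containing it is recorded as the winner
#' (ties broken by lower NRMSE, then canonical pair order). The validation
#' windows are folded back into training for the final fit
#' ([fit_multi_decoder()]).
#'
#' @param train A [windowed_session()] or list of training segments.
#' @param validation_fraction Fraction of windows used for validation
#'   (default 0.2, must be in (0, 0.5]).
#' @param seed Integer seed for the validation-block placement.
#' @param channels Optional EMG channel subset.
#' @return An object of class `decoder_selection`: winners per parameter,
#'   the full validation score table, and the block location.
#' @export
select_combinations <- function(train, validation_fraction = 0.2, seed = NULL,
                                channels = NULL) {
  if (validation_fraction <= 0 || validation_fraction > 0.5) {
    stop_emgk("emgk_parameter_error",
              "validation_fraction must be in (0, 0.5]")
  }
  segs <- if (inherits(train, "windowed_session")) list(train) else train
  m_total <- sum(vapply(segs, function(s) s$n_windows, numeric(1)))
  v_total <- round(validation_fraction * m_total)
  if (v_total < 20) {
    stop_emgk("emgk_validation_error",
              "validation block would have %d windows; need >= 20", v_total)
  }
  # one contiguous block per segment, sized in proportion to the segment,
  # at a seeded random offset; with a single training segment this is one
  # contiguous block of the requested fraction
  v_lens <- round(validation_fraction *
                    vapply(segs, function(s) s$n_windows, numeric(1)))
  starts <- with_local_seed(seed, {
    vapply(seq_along(segs), function(i) {
      room <- segs[[i]]$n_windows - v_lens[i] + 1
      if (v_lens[i] < 2 || room < 1) NA_integer_ else sample.int(room, 1)
    }, integer(1))
  })
  fit_segs <- list()
  val_blocks <- list()
  for (i in seq_along(segs)) {
    if (is.na(starts[i])) {
      fit_segs <- c(fit_segs, segs[i])
    } else {
      sp <- split_segment_around(segs[[i]], starts[i], v_lens[i])
      fit_segs <- c(fit_segs, sp$train)
      val_blocks <- c(val_blocks, list(sp$validation))
    }
  }
  if (!length(val_blocks)) {
    stop_emgk("emgk_validation_error", "no segment can host a validation block")
  }

  pairs <- candidate_pairs()
  scores <- list()
  val_states <- do.call(rbind, lapply(val_blocks, function(b) b$states))
  for (pn in names(pairs)) {
    model <- fit_kalman_model(fit_segs, pairs[[pn]], channels)
    dec <- do.call(rbind, lapply(val_blocks, function(b) {
      decode_sequence(b$measurements, model)
    }))
    for (p in pairs[[pn]]) {
      a <- val_states[, p]
      cc <- tryCatch(pearson_cc(a, dec[, p]),
                     emgk_degenerate_error = function(e) NA_real_)
      nr <- tryCatch(nrmse(a, dec[, p]),
                     emgk_degenerate_error = function(e) rmse(a, dec[, p]))
      scores[[length(scores) + 1]] <-
        data.frame(pair = pn, parameter = p, cc = cc, nrmse = nr,
                   stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, scores)

  winners <- list()
  for (p in kin_params()) {
    cand <- scores[scores$parameter == p, , drop = FALSE]
    cand <- cand[match(names(pairs)[vapply(pairs, function(pr) p %in% pr,
                                           logical(1))], cand$pair), ]
    if (all(is.na(cand$cc))) {
      warn_emgk("emgk_degenerate_warning",
                "validation CC undefined for '%s' (constant block); ranking by NRMSE", p)
      ord <- order(cand$nrmse)
    } else {
      ord <- order(-cand$cc, cand$nrmse)
    }
    winners[[p]] <- cand$pair[ord[1]]
  }

  blk <- which(!is.na(starts))
  structure(
    list(candidate_pairs = pairs,
         validation_fraction = validation_fraction,
         per_parameter_winner = winners,
         validation_scores = scores,
         validation_block = list(segment = blk[1], start = starts[blk[1]],
                                 length = v_lens[blk[1]],
                                 segments = blk, starts = starts[blk],
                                 lengths = v_lens[blk]),
         seed = seed,
         channels = channels),
    class = "decoder_selection"
  )
}

#' @export
print.decoder_selection <- function(x, ...) {
  cat("<decoder_selection>\n")
  for (p in names(x$per_parameter_winner)) {
    cat(sprintf("  %-6s -> %s\n", p, x$per_parameter_winner[[p]]))
  }
  invisible(x)
}

#' Fit the multi-filter decoder
#'
#' Fits one pair Kalman model per *distinct* winning pair on the full
#' training data (validation block folded back in) and records which decoded
#' component serves each kinematic parameter. Normally two filters cover the
#' three parameters; if three distinct pairs win, all three are fitted and a
#' warning notes the departure from the two-filter layout.
#'
#' @param train A [windowed_session()] or list of training segments.
#' @param selection A `decoder_selection` from [select_combinations()]
#'   computed on this training data; if `NULL` it is computed here.
#' @param ... Passed to [select_combinations()] when `selection` is `NULL`.
#' @return An object of class `multi_kf_decoder`.
#' @export
fit_multi_decoder <- function(train, selection = NULL, ...) {
  if (is.null(selection)) selection <- select_combinations(train, ...)
  winners <- unlist(selection$per_parameter_winner)
  distinct <- unique(winners)
  if (length(distinct) == 3) {
    warn_emgk("emgk_selection_warning",
              "three distinct winning pairs; decoder uses three filters instead of two")
  }
  models <- lapply(distinct, function(pn) {
    fit_kalman_model(train, selection$candidate_pairs[[pn]],
                     selection$channels)
  })
  names(models) <- distinct
  structure(
    list(models = models, selection = selection,
         assignment = winners),
    class = "multi_kf_decoder"
  )
}

#' @export
print.multi_kf_decoder <- function(x, ...) {
  cat(sprintf("<multi_kf_decoder> %d filter(s): %s\n",
              length(x$models), paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' Fit the single-filter baseline
#'
#' One Kalman filter whose state is all three parameters (d = 3).
#'
#' @param train A [windowed_session()] or list of training segments.
#' @param channels Optional EMG channel subset.
#' @return An object of class `single_kf_decoder`.
#' @export
fit_single_decoder <- function(train, channels = NULL) {
  structure(
    list(model = fit_kalman_model(train, kin_params(), channels)),
    class = "single_kf_decoder"
  )
}

#' Fit the three-filter baseline
#'
#' A separate scalar-state Kalman filter (d = 1) per parameter.
#'
#' @param train A [windowed_session()] or list of training segments.
#' @param channels Optional EMG channel subset.
#' @return An object of class `three_kf_decoder`.
#' @export
fit_three_decoder <- function(train, channels = NULL) {
  models <- lapply(kin_params(), function(p) {
    fit_kalman_model(train, p, channels)
  })
  names(models) <- kin_params()
  structure(list(models = models), class = "three_kf_decoder")
}

#' Decode kinematics with a fitted decoder
#'
#' Runs the decoder's filter(s) independently over the same EMG measurement
#' sequence and assembles the M x 3 decoded `[theta, x, y]` matrix, each
#' column taken from the filter that serves that parameter.
#'
#' @param decoder A `multi_kf_decoder`, `single_kf_decoder` or
#'   `three_kf_decoder`.
#' @param measurements M x channels matrix of EMG envelopes.
#' @return M x 3 matrix with columns `theta`, `x`, `y`.
#' @export
decode_kinematics <- function(decoder, measurements) {
  UseMethod("decode_kinematics")
}

empty_decode <- function() {
  matrix(numeric(0), nrow = 0, ncol = 3,
         dimnames = list(NULL, kin_params()))
}

#' @export
decode_kinematics.multi_kf_decoder <- function(decoder, measurements) {
  if (nrow(as.matrix(measurements)) == 0) return(empty_decode())
  unserved <- setdiff(kin_params(), names(decoder$assignment))
  if (length(unserved)) {
    stop_emgk("emgk_validation_error", "parameter(s) unserved by any filter: %s",
              paste(unserved, collapse = ", "))
  }
  decoded <- lapply(decoder$models, decode_sequence,
                    measurements = measurements)
  out <- sapply(kin_params(), function(p) {
    decoded[[decoder$assignment[[p]]]][, p]
  })
  colnames(out) <- kin_params()
  out
}

#' @export
decode_kinematics.single_kf_decoder <- function(decoder, measurements) {
  if (nrow(as.matrix(measurements)) == 0) return(empty_decode())
  decode_sequence(measurements, decoder$model)[, kin_params(), drop = FALSE]
}

#' @export
decode_kinematics.three_kf_decoder <- function(decoder, measurements) {
  if (nrow(as.matrix(measurements)) == 0) return(empty_decode())
  out <- sapply(kin_params(), function(p) {
    decode_sequence(measurements, decoder$models[[p]])[, 1]
  })
  colnames(out) <- kin_params()
  out
}

#' Serialize a fitted decoder bundle to JSON
#'
#' @param decoder A `multi_kf_decoder`.
#' @param path Optional output path.
#' @return JSON string.
#' @export
decoder_to_json <- function(decoder, path = NULL) {
  doc <- list(
    assignment = as.list(decoder$assignment),
    validation_scores = decoder$selection$validation_scores,
    models = lapply(decoder$models, function(m) {
      jsonlite::fromJSON(model_to_json(m))
    })
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
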