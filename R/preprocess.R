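#' Preprocessing configuration
#'
#' Parameters of the fixed signal-conditioning pipeline: RMS envelope
#' extraction (EMG only), per-channel min--max normalization, amplitude
#' rescaling and non-overlapping windowing.
#'
#' @param rms_window RMS smoothing window length in seconds. Default 0.1 s,
#'   matched to the decoder step.
#' @param dt_window Decoder window length in seconds (default 0.1 s).
#' @param emg_scale Constant multiplier applied to normalized EMG
#'   (default `1e3`).
#' @param kin_scale Constant multiplier applied to normalized kinematics
#'   (default `1e2`).
#' @param window_reduce How samples inside a window are reduced: `"mean"`
#'   (default) or `"last"`.
#' @param apply_digital_filters If `TRUE`, apply software equivalents of the
#'   acquisition high-pass (10 Hz) and anti-alias low-pass (500 Hz) filters
#'   to raw EMG before envelope extraction. Off by default: envelope-level
#'   inputs (including all synthetic sessions) need no filtering.
#' @param highpass_hz,lowpass_hz Filter cutoffs in Hz.
#' @param normalize_scope `"training"` (normalization constants estimated on
#'   training data and applied to test data) or `"per_session"`.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(rms_window = 0.1, dt_window = 0.1,
                              emg_scale = 1e3, kin_scale = 1e2,
                              window_reduce = c("mean", "last"),
                              apply_digital_filters = FALSE,
                              highpass_hz = 10, lowpass_hz = 500,
                              normalize_scope = c("training", "per_session")) {
  window_reduce <- match.arg(window_reduce)
  normalize_scope <- match.arg(normalize_scope)
  if (rms_window <= 0 || dt_window <= 0) {
    stop_emgk("emgk_parameter_error", "window lengths must be positive")
  }
  if (emg_scale <= 0 || kin_scale <= 0) {
    stop_emgk("emgk_parameter_error", "scale factors must be positive")
  }
  structure(
    list(rms_window = rms_window, dt_window = dt_window,
         emg_scale = emg_scale, kin_scale = kin_scale,
         window_reduce = window_reduce,
         apply_digital_filters = apply_digital_filters,
         highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
         normalize_scope = normalize_scope),
    class = "preprocess_config"
  )
}

#' Min-max normalize a signal
#'
#' Shifts a signal to zero minimum and scales it to unit maximum:
#' `(k - min k) / max(k - min k)`. Applied per channel, per session, to both
#' kinematics and EMG envelopes before rescaling.
#'
#' @param signal Numeric vector, length at least 2, non-constant.
#' @return Numeric vector in `[0, 1]` with min exactly 0 and max exactly 1.
#' @export
normalize_minmax <- function(signal) {
  if (length(signal) < 2) {
    stop_emgk("emgk_validation_error", "signal must have length >= 2")
  }
  lo <- min(signal)
  shifted <- signal - lo
  hi <- max(shifted)
  if (hi == 0) {
    stop_emgk("emgk_degenerate_error",
              "constant signal: min-max normalization is undefined")
  }
  shifted / hi
}

#' RMS envelope of a signal
#'
#' Windowed root-mean-square amplitude: element `i` is the square root of the
#' mean of squared samples in a centered window, truncated at the signal
#' edges. This is the linear-envelope representation of surface EMG consumed
#' by the decoder.
#'
#' @param signal Numeric vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param rms_window Window length in seconds; must span at least one sample.
#' @return Non-negative numeric vector, same length as `signal`.
#' @export
rms_envelope <- function(signal, sampling_rate, rms_window = 0.1) {
  if (rms_window <= 0) {
    stop_emgk("emgk_parameter_error", "rms_window must be positive")
  }
  w <- max(1L, round(rms_window * sampling_rate))
  n <- length(signal)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- c(0, cumsum(signal^2))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

apply_acquisition_filters <- function(signal, sampling_rate, config) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop_emgk("emgk_parameter_error",
              "digital filtering requires the 'signal' package")
  }
  nyq <- sampling_rate / 2
  hp <- signal::butter(4, config$highpass_hz / nyq, type = "high")
  out <- signal::filtfilt(hp, signal)
  if (config$lowpass_hz < nyq) {
    lp <- signal::butter(4, config$lowpass_hz / nyq, type = "low")
    out <- signal::filtfilt(lp, out)
  }
  out
}

#' Extract EMG envelopes in a session
#'
#' Applies (optionally) the acquisition-equivalent digital filters and then
#' [rms_envelope()] to every EMG channel of a raw session. Kinematic channels
#' pass through unchanged.
#'
#' @param session A raw [subject_session()].
#' @param config A [preprocess_config()].
#' @return The session with `preprocessing_state = "envelope"`.
#' @export
envelope_session <- function(session, config = preprocess_config()) {
  if (session$preprocessing_state != "raw") {
    stop_emgk("emgk_state_error",
              "envelope extraction expects a raw session, got '%s'",
              session$preprocessing_state)
  }
  emg <- session$emg
  for (j in seq_len(ncol(emg))) {
    ch <- emg[, j]
    if (isTRUE(config$apply_digital_filters)) {
      ch <- apply_acquisition_filters(ch, session$sampling_rate, config)
    }
    emg[, j] <- rms_envelope(ch, session$sampling_rate, config$rms_window)
  }
  session$emg <- emg
  session$preprocessing_state <- "envelope"
  validate_session(session)
  session
}

#' Normalize all channels of a session
#'
#' Min-max normalizes every kinematic and EMG channel ([normalize_minmax()]).
#' When `ref` (a set of per-channel minima/maxima from training data) is
#' supplied, those constants are used instead of the session's own, so test
#' sessions can be normalized without touching their own statistics.
#'
#' @param session An envelope-state [subject_session()].
#' @param ref Optional normalization reference from [session_norm_params()].
#' @return The session with `preprocessing_state = "normalized"`.
#' @export
normalize_session <- function(session, ref = NULL) {
  if (!session$preprocessing_state %in% c("raw", "envelope")) {
    stop_emgk("emgk_state_error", "session already normalized")
  }
  if (is.null(ref)) ref <- session_norm_params(session)
  nm <- function(v, lo, hi) (v - lo) / (hi - lo)
  session$theta <- nm(session$theta, ref$lo["theta"], ref$hi["theta"])
  session$x <- nm(session$x, ref$lo["x"], ref$hi["x"])
  session$y <- nm(session$y, ref$lo["y"], ref$hi["y"])
  for (ch in emg_channels()) {
    session$emg[, ch] <- nm(session$emg[, ch], ref$lo[ch], ref$hi[ch])
  }
  session$preprocessing_state <- "normalized"
  session$scales <- c(kin = 1, emg = 1)
  session
}

#' Per-channel normalization constants of a session
#'
#' @param session A `subject_session`.
#' @return List with named vectors `lo` and `hi` (per-channel min and max).
#' @export
session_norm_params <- function(session) {
  vals <- c(
    list(theta = session$theta, x = session$x, y = session$y),
    stats::setNames(lapply(emg_channels(), function(ch) session$emg[, ch]),
                    emg_channels())
  )
  lo <- vapply(vals, min, numeric(1))
  hi <- vapply(vals, max, numeric(1))
  if (any(hi - lo == 0)) {
    stop_emgk("emgk_degenerate_error",
              "constant channel(s): %s",
              paste(names(vals)[hi - lo == 0], collapse = ", "))
  }
  list(lo = lo, hi = hi)
}

#' Rescale a normalized session
#'
#' Multiplies EMG channels by `emg_scale` (default 1000) and kinematic
#' channels by `kin_scale` (default 100), the constant amplitude factors used
#' to bring the normalized signals to the acquisition device's working range.
#'
#' @param session A normalized [subject_session()].
#' @param config A [preprocess_config()].
#' @param inverse If `TRUE`, undo a previous rescale.
#' @return The rescaled session (still `preprocessing_state = "normalized"`).
#' @export
rescale_session <- function(session, config = preprocess_config(),
                            inverse = FALSE) {
  if (session$preprocessing_state != "normalized") {
    stop_emgk("emgk_state_error", "rescale expects a normalized session")
  }
  k <- if (inverse) 1 / config$kin_scale else config$kin_scale
  e <- if (inverse) 1 / config$emg_scale else config$emg_scale
  cur <- if (is.null(session$scales)) c(kin = 1, emg = 1) else session$scales
  session$theta <- session$theta * k
  session$x <- session$x * k
  session$y <- session$y * k
  session$emg <- session$emg * e
  session$scales <- c(kin = unname(cur["kin"]) * k,
                      emg = unname(cur["emg"]) * e)
  validate_session(session)
  session
}

#' Window a session into decoder frames
#'
#' Cuts the session into consecutive non-overlapping bins of `dt_window`
#' seconds (`M = floor(duration / dt_window)` of them) and reduces the
#' samples in each bin by the configured reduction (mean by default),
#' yielding the state and measurement matrices the decoder operates on.
#'
#' @param session An envelope-or-later [subject_session()].
#' @param config A [preprocess_config()].
#' @return A [windowed_session()].
#' @export
window_session <- function(session, config = preprocess_config()) {
  if (session$preprocessing_state == "raw") {
    stop_emgk("emgk_state_error",
              "window_session expects an envelope or normalized session")
  }
  dt <- config$dt_window
  n <- length(session$time)
  duration <- n / session$sampling_rate
  m <- floor(duration / dt)
  if (m < 2) {
    stop_emgk("emgk_validation_error",
              "session too short to window: duration %.3g s < 2 windows", duration)
  }
  # small epsilon guards against samples falling just below an exact
  # window boundary through floating-point division
  bin <- floor((session$time - session$time[1]) / dt + 1e-9) + 1L
  keep <- bin <= m
  bin <- bin[keep]
  fbin <- factor(bin, levels = seq_len(m))
  if (any(tabulate(bin, nbins = m) == 0)) {
    stop_emgk("emgk_validation_error",
              "empty window bin: sample times too sparse for dt_window = %g", dt)
  }
  reduce <- function(v) {
    v <- v[keep]
    if (config$window_reduce == "mean") {
      as.numeric(tapply(v, fbin, mean))
    } else {
      as.numeric(tapply(v, fbin, function(z) z[length(z)]))
    }
  }
  states <- cbind(theta = reduce(session$theta),
                  x = reduce(session$x),
                  y = reduce(session$y))
  meas <- vapply(emg_channels(), function(ch) reduce(session$emg[, ch]),
                 numeric(m))
  windowed_session(states, meas, dt_window = dt,
                   window_times = session$time[1] + dt * (seq_len(m) - 1))
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: optional digital filters and RMS envelope (EMG only), then
#' min-max normalization of all channels, amplitude rescaling, and windowing.
#' Re-running the pipeline on its own output raises a state error.
#'
#' @param session A raw or envelope-state [subject_session()].
#' @param config A [preprocess_config()].
#' @param norm_ref Optional training-derived normalization constants
#'   ([session_norm_params()]).
#' @return A [windowed_session()].
#' @export
preprocess_session <- function(session, config = preprocess_config(),
                               norm_ref = NULL) {
  if (session$preprocessing_state == "raw") {
    session <- envelope_session(session, config)
  } else if (session$preprocessing_state != "envelope") {
    stop_emgk("emgk_state_error",
              "preprocess_session expects a raw or envelope session, got '%s'",
              session$preprocessing_state)
  }
  session <- normalize_session(session, ref = norm_ref)
  session <- rescale_session(session, config)
  window_session(session, config)
}

#' Per-column normalization constants of windowed data
#'
#' Used by the evaluation protocols to derive normalization constants from
#' training windows only and apply them to test windows.
#'
#' @param w A [windowed_session()] or list of them (segments pooled).
#' @return List with `state_lo/state_hi` and `meas_lo/meas_hi` vectors.
#' @export
windowed_norm_params <- function(w) {
  segs <- if (inherits(w, "windowed_session")) list(w) else w
  st <- do.call(rbind, lapply(segs, function(s) s$states))
  me <- do.call(rbind, lapply(segs, function(s) s$measurements))
  rng <- function(m, f) apply(m, 2, f)
  p <- list(state_lo = rng(st, min), state_hi = rng(st, max),
            meas_lo = rng(me, min), meas_hi = rng(me, max))
  flat <- which(p$state_hi - p$state_lo == 0)
  if (length(flat)) {
    warn_emgk("emgk_degenerate_warning",
              "constant state column(s) in training windows: %s",
              paste(colnames(st)[flat], collapse = ", "))
    p$state_hi[flat] <- p$state_lo[flat] + 1
  }
  flat_m <- which(p$meas_hi - p$meas_lo == 0)
  if (length(flat_m)) p$meas_hi[flat_m] <- p$meas_lo[flat_m] + 1
  p
}

#' Normalize and rescale windowed data with given constants
#'
#' Affine-transforms each state column to `kin_scale * (v - lo) / (hi - lo)`
#' and each measurement column to `emg_scale * (v - lo) / (hi - lo)` using
#' constants from [windowed_norm_params()] (typically computed on training
#' windows). Values outside the training range map outside `[0, scale]`,
#' which the decoder tolerates by design.
#'
#' @param w A [windowed_session()].
#' @param params Constants from [windowed_norm_params()].
#' @param config A [preprocess_config()] supplying the scales.
#' @return The transformed `windowed_session`.
#' @export
normalize_windowed <- function(w, params, config = preprocess_config()) {
  st <- w$states
  for (j in seq_len(ncol(st))) {
    st[, j] <- config$kin_scale * (st[, j] - params$state_lo[j]) /
      (params$state_hi[j] - params$state_lo[j])
  }
  me <- w$measurements
  for (j in seq_len(ncol(me))) {
    me[, j] <- config$emg_scale * (me[, j] - params$meas_lo[j]) /
      (params$meas_hi[j] - params$meas_lo[j])
  }
  w$states <- st
  w$measurements <- me
  w
}
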