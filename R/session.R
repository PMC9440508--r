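#' @keywords internal
"_PACKAGE"

#' Canonical EMG channel names
#'
#' The four surface-EMG channels recorded over the biceps, triceps, anterior
#' deltoid and lateral deltoid, in canonical column order.
#'
#' @return Character vector of length 4.
#' @export
emg_channels <- function() c("biceps", "triceps", "ant_deltoid", "lat_deltoid")

#' Canonical kinematic parameter names
#'
#' The decoded movement parameters: interior elbow angle `theta` (degrees),
#' wrist horizontal position `x` and wrist vertical position `y`.
#'
#' @return Character vector of length 3.
#' @export
kin_params <- function() c("theta", "x", "y")

preprocess_states <- function() c("raw", "envelope", "normalized", "windowed")

stop_emgk <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "emgk_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_emgk <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "emgk_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Construct a subject recording session
#'
#' A session holds the time-aligned kinematics (elbow angle, wrist x/y) and
#' the four EMG channels for one recording of one subject, together with the
#' stage of preprocessing the signals have reached.
#'
#' @param subject_id,session_id Identifier strings.
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param theta Elbow angle per sample. Degrees while raw; dimensionless after
#'   normalization.
#' @param x,y Wrist position per sample, in the motion-capture calibration
#'   units; dimensionless after normalization.
#' @param emg Numeric matrix with one row per sample and the four canonical
#'   channels ([emg_channels()]) as columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param preprocessing_state One of `"raw"`, `"envelope"`, `"normalized"`.
#' @param scales Optional named numeric `c(kin = , emg = )` recording the
#'   amplitude rescaling applied after normalization.
#'
#' @return An object of class `subject_session`.
#' @seealso [read_session()], [write_session()], [preprocess_session()]
#' @export
subject_session <- function(subject_id, session_id, time, theta, x, y, emg,
                            sampling_rate,
                            preprocessing_state = "raw",
                            scales = NULL) {
  emg <- as.matrix(emg)
  if (is.null(colnames(emg))) colnames(emg) <- emg_channels()
  s <- structure(
    list(
      subject_id = as.character(subject_id),
      session_id = as.character(session_id),
      time = as.numeric(time),
      theta = as.numeric(theta),
      x = as.numeric(x),
      y = as.numeric(y),
      emg = emg,
      sampling_rate = as.numeric(sampling_rate),
      preprocessing_state = preprocessing_state,
      scales = scales
    ),
    class = "subject_session"
  )
  validate_session(s)
}

#' Validate a subject session
#'
#' Checks the invariants of a [subject_session()]: equal channel lengths of at
#' least 2, strictly increasing sample times, no missing values, a known
#' preprocessing state, and -- once normalized -- all channels within
#' `[0, 1]` up to the recorded rescaling constants. Violations raise
#' classed errors; nothing is silently repaired.
#'
#' @param s A `subject_session`.
#' @return `s`, invisibly unchanged, if valid.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "subject_session")) {
    stop_emgk("emgk_validation_error", "not a subject_session object")
  }
  n <- length(s$time)
  lens <- c(length(s$theta), length(s$x), length(s$y), nrow(s$emg))
  if (any(lens != n)) {
    stop_emgk("emgk_validation_error",
              "channel lengths differ: time=%d theta=%d x=%d y=%d emg=%d",
              n, lens[1], lens[2], lens[3], lens[4])
  }
  if (n < 2) stop_emgk("emgk_validation_error", "session has fewer than 2 samples")
  if (ncol(s$emg) != 4 || !identical(colnames(s$emg), emg_channels())) {
    stop_emgk("emgk_schema_error",
              "emg must have the 4 canonical channels: %s",
              paste(emg_channels(), collapse = ", "))
  }
  bad <- which(!stats::complete.cases(
    cbind(s$time, s$theta, s$x, s$y, s$emg)
  ))
  if (length(bad) > 0) {
    stop_emgk("emgk_validation_error", "NaN/NA values at rows: %s",
              paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(diff(s$time) <= 0)) {
    stop_emgk("emgk_validation_error",
              "sample times are not strictly increasing")
  }
  if (!s$preprocessing_state %in% preprocess_states()) {
    stop_emgk("emgk_validation_error", "unknown preprocessing_state '%s'",
              s$preprocessing_state)
  }
  if (identical(s$preprocessing_state, "normalized")) {
    sc <- s$scales
    kin_scale <- if (is.null(sc)) 1 else unname(sc["kin"])
    emg_scale <- if (is.null(sc)) 1 else unname(sc["emg"])
    tol <- 1e-9
    kin <- c(s$theta, s$x, s$y)
    if (min(kin) < -tol * kin_scale || max(kin) > kin_scale * (1 + tol)) {
      stop_emgk("emgk_validation_error",
                "normalized kinematics outside [0, %g]", kin_scale)
    }
    if (min(s$emg) < -tol * emg_scale || max(s$emg) > emg_scale * (1 + tol)) {
      stop_emgk("emgk_validation_error",
                "normalized EMG outside [0, %g]", emg_scale)
    }
  }
  invisible(s)
}

#' @export
print.subject_session <- function(x, ...) {
  cat(sprintf(
    "<subject_session> subject=%s session=%s n=%d fs=%g Hz state=%s\n",
    x$subject_id, x$session_id, length(x$time), x$sampling_rate,
    x$preprocessing_state
  ))
  invisible(x)
}

#' Construct a windowed session
#'
#' The decoder-facing representation: kinematic states and EMG measurements
#' averaged over consecutive non-overlapping time windows (100 ms by
#' default).
#'
#' @param states Numeric matrix, one row per window, columns named by
#'   `state_labels`.
#' @param measurements Numeric matrix, one row per window, columns named by
#'   `channels`.
#' @param dt_window Window length in seconds.
#' @param window_times Optional window start times; defaults to
#'   `dt_window * (0:(M-1))`.
#' @param state_labels Names for the state columns (subset of
#'   [kin_params()] order for real sessions).
#' @param channels Names for the measurement columns.
#'
#' @return An object of class `windowed_session`.
#' @export
windowed_session <- function(states, measurements, dt_window = 0.1,
                             window_times = NULL,
                             state_labels = kin_params(),
                             channels = emg_channels()) {
  states <- as.matrix(states)
  measurements <- as.matrix(measurements)
  if (dt_window <= 0) stop_emgk("emgk_validation_error", "dt_window must be > 0")
  m <- nrow(states)
  if (m < 2) stop_emgk("emgk_validation_error", "windowed session needs M >= 2")
  if (nrow(measurements) != m) {
    stop_emgk("emgk_validation_error",
              "states (%d) and measurements (%d) differ in window count",
              m, nrow(measurements))
  }
  colnames(states) <- state_labels
  colnames(measurements) <- channels
  if (is.null(window_times)) window_times <- dt_window * (seq_len(m) - 1)
  structure(
    list(
      states = states, measurements = measurements,
      dt_window = dt_window, n_windows = m,
      window_times = as.numeric(window_times),
      state_labels = state_labels, channels = channels
    ),
    class = "windowed_session"
  )
}

#' @export
print.windowed_session <- function(x, ...) {
  cat(sprintf(
    "<windowed_session> M=%d dt=%g s states=[%s] channels=[%s]\n",
    x$n_windows, x$dt_window,
    paste(x$state_labels, collapse = ","),
    paste(x$channels, collapse = ",")
  ))
  invisible(x)
}

canonical_columns <- function() {
  c("time", "theta", "x", "y",
    paste0("emg_", emg_channels()))
}

#' Read a session file
#'
#' Sessions are stored as CSV with one header row preceded by a `#`-prefixed
#' metadata block (`subject_id`, `session_id`, `sampling_rate`,
#' `preprocessing_state`, and `dt_window` for windowed files). A schema map
#' lets files with arbitrary source column names be ingested.
#'
#' @param path Path to a session CSV.
#' @param schema Optional named character vector mapping canonical column
#'   names (`time`, `theta`, `x`, `y`, `emg_biceps`, `emg_triceps`,
#'   `emg_ant_deltoid`, `emg_lat_deltoid`) to the names used in the file.
#'
#' @return A [subject_session()], or a [windowed_session()] if the file's
#'   metadata says `preprocessing_state: windowed`.
#' @export
read_session <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_emgk("emgk_io_error", "file not found: %s", path)
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      key <- trimws(substr(kv, 1, pos - 1))
      meta[[key]] <- trimws(substr(kv, pos + 1, nchar(kv)))
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  state <- if (is.null(meta$preprocessing_state)) "raw" else meta$preprocessing_state

  if (identical(state, "windowed")) {
    need <- c("time", "theta", "x", "y", paste0("emg_", emg_channels()))
    present <- intersect(need, names(df))
    st_cols <- intersect(c("theta", "x", "y"), present)
    ch_cols <- sub("^emg_", "", grep("^emg_", present, value = TRUE))
    return(windowed_session(
      states = as.matrix(df[st_cols]),
      measurements = as.matrix(df[paste0("emg_", ch_cols)]),
      dt_window = as.numeric(meta$dt_window %||% 0.1),
      window_times = df$time,
      state_labels = st_cols, channels = ch_cols
    ))
  }

  want <- canonical_columns()
  colmap <- stats::setNames(want, want)
  if (!is.null(schema)) colmap[names(schema)] <- schema
  missing_cols <- colmap[!colmap %in% names(df)]
  if (length(missing_cols) > 0) {
    stop_emgk("emgk_schema_error", "missing column(s): %s",
              paste(sprintf("%s (for %s)", missing_cols, names(missing_cols)),
                    collapse = ", "))
  }
  emg <- as.matrix(df[colmap[paste0("emg_", emg_channels())]])
  colnames(emg) <- emg_channels()
  scales <- NULL
  if (!is.null(meta$kin_scale) || !is.null(meta$emg_scale)) {
    scales <- c(kin = as.numeric(meta$kin_scale %||% 1),
                emg = as.numeric(meta$emg_scale %||% 1))
  }
  subject_session(
    subject_id = meta$subject_id %||% "unknown",
    session_id = meta$session_id %||% "unknown",
    time = df[[colmap["time"]]],
    theta = df[[colmap["theta"]]],
    x = df[[colmap["x"]]],
    y = df[[colmap["y"]]],
    emg = emg,
    sampling_rate = as.numeric(meta$sampling_rate %||%
                                 (1 / stats::median(diff(df[[colmap["time"]]])))),
    preprocessing_state = state,
    scales = scales
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session file
#'
#' Writes a [subject_session()] or [windowed_session()] to the CSV-with-
#' metadata format read by [read_session()]. Values are written with 15
#' significant digits so that a read-back round trip reproduces the session
#' to floating-point text precision.
#'
#' @param session A `subject_session` or `windowed_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) stop_emgk("emgk_io_error",
                                                "cannot open '%s' for writing", path))
  on.exit(close(con), add = TRUE)
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  if (inherits(session, "windowed_session")) {
    writeLines(c(
      "# preprocessing_state: windowed",
      sprintf("# dt_window: %s", fmt(session$dt_window))
    ), con)
    df <- data.frame(time = session$window_times, check.names = FALSE)
    st <- session$states
    colnames(st) <- session$state_labels
    me <- session$measurements
    colnames(me) <- paste0("emg_", session$channels)
    df <- cbind(df, as.data.frame(st), as.data.frame(me))
  } else {
    validate_session(session)
    hdr <- c(
      sprintf("# subject_id: %s", session$subject_id),
      sprintf("# session_id: %s", session$session_id),
      sprintf("# sampling_rate: %s", fmt(session$sampling_rate)),
      sprintf("# preprocessing_state: %s", session$preprocessing_state)
    )
    if (!is.null(session$scales)) {
      hdr <- c(hdr,
               sprintf("# kin_scale: %s", fmt(session$scales[["kin"]])),
               sprintf("# emg_scale: %s", fmt(session$scales[["emg"]])))
    }
    writeLines(hdr, con)
    emg <- session$emg
    colnames(emg) <- paste0("emg_", emg_channels())
    df <- cbind(
      data.frame(time = session$time, theta = session$theta,
                 x = session$x, y = session$y),
      as.data.frame(emg)
    )
  }
  df[] <- lapply(df, fmt)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
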