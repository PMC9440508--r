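#' Specification for the linear-Gaussian session generator
#'
#' Defines a ground-truth state-space system for validating the estimators
#' and the filter: stable transition `A0`, observation `H0` mapping the state
#' to the EMG channels, and PSD noise covariances `W0` (process) and `Q0`
#' (measurement).
#'
#' @param A0 d x d transition matrix, spectral radius <= 1.
#' @param H0 channels x d observation matrix.
#' @param W0,Q0 PSD covariance matrices (d x d and channels x channels).
#' @param M Number of windows to keep.
#' @param burn_in Initial windows discarded before recording (default 100).
#' @param seed Integer seed.
#' @param r0 Initial state (default zero vector).
#' @param state_labels Labels for the state components (defaults to the
#'   first d of [kin_params()]).
#' @return An object of class `linear_gen_spec`.
#' @export
linear_gen_spec <- function(A0, H0, W0, Q0, M, burn_in = 100, seed = 1,
                            r0 = NULL, state_labels = NULL) {
  A0 <- as.matrix(A0); H0 <- as.matrix(H0)
  W0 <- as.matrix(W0); Q0 <- as.matrix(Q0)
  d <- nrow(A0)
  if (max(Mod(eigen(A0, only.values = TRUE)$values)) > 1 + 1e-12) {
    stop_emgk("emgk_parameter_error", "A0 spectral radius exceeds 1")
  }
  for (S in list(W0, Q0)) {
    if (min(eigen((S + t(S)) / 2, only.values = TRUE)$values) < -1e-10) {
      stop_emgk("emgk_parameter_error", "noise covariances must be PSD")
    }
  }
  if (is.null(r0)) r0 <- rep(0, d)
  if (is.null(state_labels)) state_labels <- kin_params()[seq_len(d)]
  structure(
    list(A0 = A0, H0 = H0, W0 = W0, Q0 = Q0, M = as.integer(M),
         burn_in = as.integer(burn_in), seed = seed, r0 = r0,
         state_labels = state_labels),
    class = "linear_gen_spec"
  )
}

# Draw n samples from N(0, S) via eigendecomposition (handles PSD S).
rmvn <- function(n, S) {
  d <- nrow(S)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  matrix(stats::rnorm(n * d), n, d) %*% t(L)
}

#' Simulate a session from a known linear-Gaussian system
#'
#' Iterates `r[n+1] = A0 r[n] + w[n]`, `z[n] = H0 r[n] + q[n]` with Gaussian
#' noise of covariance `W0` and `Q0`, discards the burn-in, and packages the
#' (true) states and (noisy) measurements as a windowed session. The raw
#' noise draws are returned so tests can check their sample covariances
#' directly.
#'
#' @param spec A [linear_gen_spec()].
#' @return List with `session` (a [windowed_session()] whose states are the
#'   true states), `states`, `process_noise`, `measurement_noise`.
#' @export
generate_linear_session <- function(spec) {
  d <- nrow(spec$A0)
  n_tot <- spec$M + spec$burn_in
  with_local_seed(spec$seed, {
    wdraw <- rmvn(n_tot, spec$W0)
    qdraw <- rmvn(n_tot, spec$Q0)
    r <- matrix(0, n_tot, d)
    cur <- spec$r0
    for (n in seq_len(n_tot)) {
      r[n, ] <- cur
      cur <- as.numeric(spec$A0 %*% cur) + wdraw[n, ]
      if (any(!is.finite(cur)) || max(abs(cur)) > 1e12) {
        stop_emgk("emgk_numeric_error",
                  "state diverged at step %d (unstable A0?)", n)
      }
    }
    z <- r %*% t(spec$H0) + qdraw
    keep <- seq(spec$burn_in + 1, n_tot)
    states <- r[keep, , drop = FALSE]
    colnames(states) <- spec$state_labels
    meas <- z[keep, , drop = FALSE]
    chans <- emg_channels()[seq_len(ncol(meas))]
    colnames(meas) <- chans
    list(
      session = windowed_session(states, meas,
                                 state_labels = spec$state_labels,
                                 channels = chans),
      states = states,
      process_noise = wdraw[keep, , drop = FALSE],
      measurement_noise = qdraw[keep, , drop = FALSE]
    )
  })
}

#' Specification for the synthetic arm-session generator
#'
#' Emulates the recording protocol: planar arm movements -- elbow
#' flexion/extension with or without shoulder flexion/extension --
#' interleaved with 2-3 s rests, captured as elbow angle, wrist position
#' from two-link forward kinematics, and four EMG envelopes whose activity
#' co-varies with joint motion.
#'
#' @param session_seconds Session length in seconds (the protocol uses 400 s
#'   and 200 s sessions).
#' @param sampling_rate Envelope sampling rate in Hz (default 100).
#' @param L1,L2 Upper-arm and forearm(+hand) link lengths in metres.
#' @param movement_mix Proportions of `elbow`-only, `shoulder_elbow` and
#'   `rest` events; must sum to 1.
#' @param rest_duration Range (seconds) of rest-event durations.
#' @param move_duration Range (seconds) of movement-event durations.
#' @param elbow_range Interior elbow-angle target range in degrees
#'   (180 = full extension).
#' @param shoulder_range Shoulder elevation target range in degrees
#'   (0 = horizontal).
#' @param gains Named per-muscle envelope gains.
#' @param tonic Weight of the posture-holding (position-dependent) envelope
#'   component.
#' @param phasic Weight of the movement (rectified joint-velocity) envelope
#'   component. The defaults make holding activity dominate, as it does for
#'   slow planar movements with sustained postures and frequent rests.
#' @param noise_sd Gaussian envelope noise standard deviation.
#' @param baseline Resting envelope level.
#' @param seed Integer seed.
#' @return An object of class `arm_gen_spec`.
#' @export
arm_gen_spec <- function(session_seconds = 400, sampling_rate = 100,
                         L1 = 0.30, L2 = 0.32,
                         movement_mix = c(elbow = 0.40, shoulder_elbow = 0.35,
                                          rest = 0.25),
                         rest_duration = c(2, 3),
                         move_duration = c(0.8, 2.0),
                         elbow_range = c(70, 170),
                         shoulder_range = c(-20, 90),
                         gains = c(biceps = 1, triceps = 1,
                                   ant_deltoid = 1, lat_deltoid = 0.4),
                         tonic = 1.0,
                         phasic = 0.35,
                         noise_sd = 0.04,
                         baseline = 0.05,
                         seed = 1) {
  if (abs(sum(movement_mix) - 1) > 1e-9) {
    stop_emgk("emgk_parameter_error", "movement_mix must sum to 1")
  }
  if (any(c(rest_duration, move_duration) <= 0)) {
    stop_emgk("emgk_parameter_error", "durations must be positive")
  }
  structure(
    list(session_seconds = session_seconds, sampling_rate = sampling_rate,
         L1 = L1, L2 = L2, movement_mix = movement_mix,
         rest_duration = rest_duration, move_duration = move_duration,
         elbow_range = elbow_range, shoulder_range = shoulder_range,
         gains = gains, tonic = tonic, phasic = phasic, noise_sd = noise_sd,
         baseline = baseline, seed = seed),
    class = "arm_gen_spec"
  )
}

# Minimum-jerk position profile on [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate one synthetic arm session
#'
#' Builds shoulder angle `phi(t)` and interior elbow angle `theta(t)` as
#' minimum-jerk segments between random targets, interleaved with rests;
#' computes the wrist position by two-link planar forward kinematics
#' `X = L1 cos(phi) + L2 cos(phi + theta')`,
#' `Y = L1 sin(phi) + L2 sin(phi + theta')` with `theta' = 180 - theta`
#' (interior-angle convention, 180 deg = full extension); and synthesizes
#' the four EMG envelopes as rectified joint-velocity signals plus a tonic
#' posture-holding component, Gaussian noise and a resting baseline, clipped
#' at zero. Signals are produced at the envelope level -- the decoder's
#' input representation -- so the session starts in `"envelope"` state.
#'
#' @param spec An [arm_gen_spec()].
#' @param subject_id,session_id Identifiers for the session.
#' @return A [subject_session()] with `preprocessing_state = "envelope"`.
#' @export
generate_arm_session <- function(spec, subject_id = "S01", session_id = "ses1") {
  fs <- spec$sampling_rate
  n <- ceiling(spec$session_seconds * fs)
  with_local_seed(spec$seed, {
    # event schedule: (type, duration) until the session is covered
    theta_seq <- numeric(0)  # interior elbow angle, degrees
    phi_seq <- numeric(0)    # shoulder elevation from horizontal, degrees
    cur_theta <- 160
    cur_phi <- 10
    types <- names(spec$movement_mix)
    while (length(theta_seq) < n) {
      type <- sample(types, 1, prob = spec$movement_mix)
      if (type == "rest") {
        dur <- stats::runif(1, spec$rest_duration[1], spec$rest_duration[2])
        len <- max(2L, round(dur * fs))
        theta_seq <- c(theta_seq, rep(cur_theta, len))
        phi_seq <- c(phi_seq, rep(cur_phi, len))
      } else {
        dur <- stats::runif(1, spec$move_duration[1], spec$move_duration[2])
        len <- max(2L, round(dur * fs))
        tau <- min_jerk(seq_len(len) / len)
        new_theta <- stats::runif(1, spec$elbow_range[1], spec$elbow_range[2])
        new_phi <- if (type == "shoulder_elbow") {
          stats::runif(1, spec$shoulder_range[1], spec$shoulder_range[2])
        } else {
          cur_phi
        }
        theta_seq <- c(theta_seq, cur_theta + (new_theta - cur_theta) * tau)
        phi_seq <- c(phi_seq, cur_phi + (new_phi - cur_phi) * tau)
        cur_theta <- new_theta
        cur_phi <- new_phi
      }
    }
    theta <- theta_seq[seq_len(n)]
    phi <- phi_seq[seq_len(n)]

    # forward kinematics (angles in radians; interior-angle convention)
    deg2rad <- pi / 180
    theta_p <- (180 - theta) * deg2rad
    phi_r <- phi * deg2rad
    x <- spec$L1 * cos(phi_r) + spec$L2 * cos(phi_r + theta_p)
    y <- spec$L1 * sin(phi_r) + spec$L2 * sin(phi_r + theta_p)

    # joint velocities in deg/s, normalized by a typical peak of 90 deg/s
    vel_theta <- c(0, diff(theta)) * fs / 90
    vel_phi <- c(0, diff(phi)) * fs / 90
    g <- spec$gains
    tn <- spec$tonic
    ph <- spec$phasic
    # deltoid holding activity scales with elevation above the resting hang
    phi_lift <- (phi - spec$shoulder_range[1]) / diff(spec$shoulder_range)
    env <- cbind(
      biceps = g["biceps"] * (ph * pmax(0, -vel_theta) +
                                tn * (180 - theta) / 120),
      triceps = g["triceps"] * (ph * pmax(0, vel_theta) +
                                  tn * 0.15 * (theta - 60) / 120),
      ant_deltoid = g["ant_deltoid"] * (ph * pmax(0, vel_phi) +
                                          tn * phi_lift),
      lat_deltoid = g["lat_deltoid"] * (0.4 * ph * abs(vel_phi) +
                                          tn * 0.6 * phi_lift)
    )
    colnames(env) <- emg_channels()
    env <- env + spec$baseline +
      matrix(stats::rnorm(n * 4, sd = spec$noise_sd), n, 4)
    env <- pmax(env, 0)

    subject_session(
      subject_id = subject_id, session_id = session_id,
      time = (seq_len(n) - 1) / fs,
      theta = theta, x = x, y = y, emg = env,
      sampling_rate = fs,
      preprocessing_state = "envelope"
    )
  })
}

#' Generate a synthetic subject cohort
#'
#' Emulates the study population: `n_subjects` subjects, each contributing
#' two sessions (400 s and 200 s by default), with per-subject jitter of the
#' envelope gains, link lengths and movement mix around the base
#' specification.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param base_spec An [arm_gen_spec()] shared by the cohort.
#' @param inter_subject_sd Relative spread of per-subject jitter (0 makes
#'   all subjects identical up to noise seeds).
#' @param seed Master seed; every subject's sessions derive from it.
#' @param session_seconds Lengths of the per-subject sessions.
#' @return List of subjects, each a list with `subject_id`, `sessions` (list
#'   of [subject_session()]), and the jittered `spec`.
#' @export
generate_cohort <- function(n_subjects = 10, base_spec = arm_gen_spec(),
                            inter_subject_sd = 0.15, seed = 1,
                            session_seconds = c(400, 200)) {
  if (n_subjects < 1) stop_emgk("emgk_parameter_error", "n_subjects must be >= 1")
  jitters <- with_local_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      list(gain = exp(stats::rnorm(4, sd = inter_subject_sd)),
           link = exp(stats::rnorm(2, sd = inter_subject_sd / 3)),
           mix = exp(stats::rnorm(3, sd = inter_subject_sd)))
    })
  })
  lapply(seq_len(n_subjects), function(i) {
    jit <- jitters[[i]]
    spec_i <- base_spec
    spec_i$gains <- base_spec$gains * jit$gain
    spec_i$L1 <- base_spec$L1 * jit$link[1]
    spec_i$L2 <- base_spec$L2 * jit$link[2]
    mix <- base_spec$movement_mix * jit$mix
    spec_i$movement_mix <- mix / sum(mix)
    sid <- sprintf("S%02d", i)
    sessions <- lapply(seq_along(session_seconds), function(k) {
      spec_k <- spec_i
      spec_k$session_seconds <- session_seconds[k]
      spec_k$seed <- (seed * 997L + i * 101L + k) %% 2147483647L
      generate_arm_session(spec_k, subject_id = sid,
                           session_id = sprintf("ses%d", k))
    })
    list(subject_id = sid, sessions = sessions, spec = spec_i)
  })
}
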