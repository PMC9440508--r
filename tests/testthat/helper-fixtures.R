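# Shared fixtures, all built in code.

toy_session <- function(n = 6, fs = 10, state = "raw", seed = 42) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  emg <- matrix(abs(rnorm(n * 4)), n, 4,
                dimnames = list(NULL, emg_channels()))
  subject_session(
    subject_id = "T01", session_id = "ses1",
    time = t,
    theta = 90 + 30 * sin(2 * pi * t),
    x = 0.4 + 0.1 * cos(2 * pi * t),
    y = 0.2 + 0.1 * sin(4 * pi * t),
    emg = emg,
    sampling_rate = fs,
    preprocessing_state = state
  )
}

random_session <- function(n = 50, fs = 20, seed = 1) {
  set.seed(seed)
  emg <- matrix(abs(rnorm(n * 4)) + 0.01, n, 4,
                dimnames = list(NULL, emg_channels()))
  subject_session(
    subject_id = sprintf("R%02d", seed %% 90), session_id = "sesA",
    time = cumsum(runif(n, 0.5, 1.5)) / fs,
    theta = runif(n, 60, 175), x = rnorm(n), y = rnorm(n),
    emg = emg, sampling_rate = fs
  )
}

# A well-conditioned 2-state / 4-channel ground-truth system.
default_linear_spec <- function(M = 2000, seed = 1,
                                W0 = diag(c(0.04, 0.09)),
                                Q0 = diag(c(0.25, 0.25, 0.16, 0.16))) {
  A0 <- matrix(c(0.95, 0.05, -0.03, 0.9), 2, 2)
  H0 <- matrix(c(1.0, 0.2,
                 -0.6, 0.8,
                 0.4, -0.9,
                 0.3, 0.5), 4, 2, byrow = TRUE)
  linear_gen_spec(A0, H0, W0, Q0, M = M, seed = seed)
}

# Windowed session with an exact linear state recurrence (no noise).
exact_windowed <- function(A, r0, M, H = NULL) {
  d <- length(r0)
  r <- matrix(0, M, d)
  r[1, ] <- r0
  for (n in 2:M) r[n, ] <- as.numeric(A %*% r[n - 1, ])
  if (is.null(H)) H <- matrix(rnorm(4 * d), 4, d)
  z <- r %*% t(H)
  colnames(z) <- emg_channels()
  windowed_session(r, z, state_labels = kin_params()[seq_len(d)])
}

# Ground truth where theta is decodable well only jointly with x: theta (fast)
# and x (slow drift) share channel 1, so only a filter carrying x in its
# state can split them by timescale; y is observed on its own channels.
selection_fixture_spec <- function(M = 3000, seed = 1) {
  A0 <- diag(c(0.7, 0.995, 0.9))
  H0 <- matrix(c(1.0, 1.0, 0,
                 0.8, 0,   0,
                 0,   0,   1.0,
                 0,   0,  -0.7), 4, 3, byrow = TRUE)
  W0 <- diag(c(0.05, 0.005, 0.03))
  Q0 <- diag(c(0.01, 0.01, 0.05, 0.05))
  linear_gen_spec(A0, H0, W0, Q0, M = M, seed = seed)
}
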