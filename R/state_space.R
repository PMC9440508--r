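#' Assemble least-squares training matrices
#'
#' Lays the windowed training data out as the matrices used by the
#' least-squares system identification: `R` (d x M states), its first and
#' last `M - 1` columns `R1` and `R2`, and `Z` (channels x M measurements).
#' When several disjoint segments are supplied (e.g. training data split
#' around a validation block, or pooled subjects), `R` and `Z` concatenate
#' all segments while `R1`/`R2` pair consecutive windows only within each
#' segment, so no transition is fabricated across a gap.
#'
#' @param w A [windowed_session()] or a list of them (segments).
#' @param state_labels Ordered subset of the session's state labels defining
#'   the filter state (d = 1, 2 or 3).
#' @param channels Optional subset of EMG channels to use (default: all
#'   channels present).
#' @return List with `R`, `R1`, `R2`, `Z`, counts `M` and `n_pairs`, and the
#'   labels used.
#' @export
build_training_matrices <- function(w, state_labels, channels = NULL) {
  segs <- if (inherits(w, "windowed_session")) list(w) else w
  if (!length(segs)) stop_emgk("emgk_validation_error", "no training segments")
  labs <- segs[[1]]$state_labels
  if (!all(state_labels %in% labs)) {
    stop_emgk("emgk_validation_error", "unknown state label(s): %s",
              paste(setdiff(state_labels, labs), collapse = ", "))
  }
  if (is.null(channels)) channels <- segs[[1]]$channels
  if (!all(channels %in% segs[[1]]$channels)) {
    stop_emgk("emgk_validation_error", "unknown channel(s): %s",
              paste(setdiff(channels, segs[[1]]$channels), collapse = ", "))
  }
  d <- length(state_labels)
  Rs <- lapply(segs, function(s) t(s$states[, state_labels, drop = FALSE]))
  Zs <- lapply(segs, function(s) t(s$measurements[, channels, drop = FALSE]))
  R <- do.call(cbind, Rs)
  Z <- do.call(cbind, Zs)
  R1 <- do.call(cbind, lapply(Rs, function(r) r[, -ncol(r), drop = FALSE]))
  R2 <- do.call(cbind, lapply(Rs, function(r) r[, -1, drop = FALSE]))
  if (ncol(R) < d + 2) {
    stop_emgk("emgk_validation_error",
              "need at least d + 2 = %d windows, got %d", d + 2, ncol(R))
  }
  list(R = R, R1 = R1, R2 = R2, Z = Z,
       M = ncol(R), n_pairs = ncol(R1),
       state_labels = state_labels, channels = channels)
}

# Solve X = B A^T (A A^T)^{-1}, i.e. the least-squares map from A-rows to
# B-rows, with a pseudo-inverse fallback for rank-deficient Gram matrices.
ls_map <- function(B, A, what = "matrix") {
  G <- tcrossprod(A)
  C <- tcrossprod(B, A)
  out <- tryCatch({
    if (rcond(G) < 1e-12) stop("ill-conditioned")
    t(solve(G, t(C)))
  }, error = function(e) {
    warn_emgk("emgk_conditioning_warning",
              "Gram matrix singular or ill-conditioned while estimating %s; using pseudo-inverse",
              what)
    C %*% MASS::ginv(G)
  })
  unname(out)
}

#' Estimate the state transition matrix
#'
#' Least-squares fit of the linear dynamics `r[n+1] = A r[n]`:
#' `A = R2 R1' (R1 R1')^-1`. Falls back to a Moore-Penrose pseudo-inverse
#' with a conditioning warning when `R1 R1'` is (near) singular, which is
#' reachable in practice after long rest periods.
#'
#' @param tm Training matrices from [build_training_matrices()].
#' @return The d x d transition matrix `A`.
#' @export
estimate_transition <- function(tm) {
  ls_map(tm$R2, tm$R1, what = "transition matrix A")
}

#' Estimate the observation matrix
#'
#' Least-squares fit of the measurement model `z[n] = H r[n]`:
#' `H = Z R' (R R')^-1`, mapping the kinematic state to the EMG envelopes.
#'
#' @param tm Training matrices from [build_training_matrices()].
#' @return The channels x d observation matrix `H`.
#' @export
estimate_observation <- function(tm) {
  ls_map(tm$Z, tm$R, what = "observation matrix H")
}

# Symmetrize and floor eigenvalues so downstream solves see a true PSD matrix.
make_psd <- function(S, floor = 1e-12) {
  S <- unname((S + t(S)) / 2)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor) {
    S <- e$vectors %*% diag(pmax(e$values, floor), nrow = length(e$values)) %*%
      t(e$vectors)
    S <- (S + t(S)) / 2
  }
  S
}

#' Estimate the noise covariances
#'
#' Residual covariances of the fitted model: process noise
#' `W = (R2 - A R1)(R2 - A R1)' / (M - 1)` and measurement noise
#' `Q = (Z - H R)(Z - H R)' / M`. Both are symmetrized and eigenvalue-floored
#' at `1e-12` so the filter can always invert the innovation covariance.
#'
#' @param tm Training matrices from [build_training_matrices()].
#' @param A,H Matrices estimated from the same `tm`.
#' @return List with elements `W` (d x d) and `Q` (channels x channels).
#' @export
estimate_noise <- function(tm, A, H) {
  Ew <- tm$R2 - A %*% tm$R1
  Eq <- tm$Z - H %*% tm$R
  W <- tcrossprod(Ew) / tm$n_pairs
  Q <- tcrossprod(Eq) / tm$M
  list(W = make_psd(W), Q = make_psd(Q))
}

#' Fit a Kalman decoding model
#'
#' Identifies the full time-invariant quadruple (A, H, W, Q) from windowed
#' training data by least squares and residual covariances.
#'
#' @param w A [windowed_session()] or list of segments.
#' @param state_labels Ordered subset of state labels (the filter state).
#' @param channels Optional EMG channel subset.
#' @return An object of class `kalman_model` with fields `A`, `H`, `W`, `Q`,
#'   `state_labels`, `channels`, `n_train`.
#' @export
fit_kalman_model <- function(w, state_labels, channels = NULL) {
  tm <- build_training_matrices(w, state_labels, channels)
  A <- estimate_transition(tm)
  H <- estimate_observation(tm)
  nz <- estimate_noise(tm, A, H)
  structure(
    list(A = A, H = H, W = nz$W, Q = nz$Q,
         state_labels = tm$state_labels, channels = tm$channels,
         n_train = tm$M),
    class = "kalman_model"
  )
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model> d=%d states=[%s] channels=%d n_train=%d\n",
              length(x$state_labels), paste(x$state_labels, collapse = ","),
              length(x$channels), x$n_train))
  invisible(x)
}

#' Serialize a Kalman model to JSON
#'
#' @param model A `kalman_model`.
#' @param path Optional path; if given the JSON is written there.
#' @return JSON string (invisibly if written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    state_labels = model$state_labels,
    channels = model$channels,
    n_train = model$n_train,
    A = model$A, H = model$H, W = model$W, Q = model$Q,
    package_version = as.character(utils::packageVersion("emgkalman"))
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a Kalman model from JSON
#'
#' @param json A JSON string or path to a JSON file written by
#'   [model_to_json()].
#' @return A `kalman_model`.
#' @export
model_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  structure(
    list(A = as.matrix(doc$A), H = as.matrix(doc$H),
         W = as.matrix(doc$W), Q = as.matrix(doc$Q),
         state_labels = doc$state_labels, channels = doc$channels,
         n_train = doc$n_train),
    class = "kalman_model"
  )
}
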