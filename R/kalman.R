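#' Initial filter state
#'
#' The recursion starts from an all-ones state estimate and an identity
#' posterior covariance ("set to one" for a covariance is read as unit
#' diagonal; an all-ones matrix would be singular).
#'
#' @param model A `kalman_model`.
#' @param r0 Optional initial state vector (length d); default all ones.
#' @return An object of class `filter_state` with `r_post` and `P_post`.
#' @export
kalman_init <- function(model, r0 = NULL) {
  d <- length(model$state_labels)
  if (is.null(r0)) r0 <- rep(1, d)
  if (length(r0) != d) {
    stop_emgk("emgk_validation_error", "r0 must have length %d", d)
  }
  structure(
    list(r_prior = NULL, r_post = as.numeric(r0),
         P_prior = NULL, P_post = diag(d), K = NULL),
    class = "filter_state"
  )
}

#' Kalman time update
#'
#' Propagates the posterior through the dynamics:
#' `r_prior = A r_post` and `P_prior = A P_post A' + W`.
#'
#' @param prev A `filter_state` with `r_post`/`P_post` set.
#' @param model A `kalman_model`.
#' @return The `filter_state` with `r_prior`/`P_prior` filled in.
#' @export
kalman_time_update <- function(prev, model) {
  prev$r_prior <- as.numeric(model$A %*% prev$r_post)
  P <- model$A %*% prev$P_post %*% t(model$A) + model$W
  prev$P_prior <- (P + t(P)) / 2
  prev
}

#' Kalman measurement update
#'
#' Corrects the prediction with the measured EMG vector:
#' `K = P_prior H' (H P_prior H' + Q)^-1`,
#' `r_post = r_prior + K (z - H r_prior)`,
#' `P_post = (I - K H) P_prior`. The innovation covariance is solved as a
#' symmetric system (eigenvalue-floored at `1e-12`), never explicitly
#' inverted, so repeated runs on the same input are bit-stable.
#'
#' @param pred A `filter_state` after [kalman_time_update()].
#' @param z Measurement vector (one EMG value per model channel).
#' @param model A `kalman_model`.
#' @param window_index Optional index used in error messages.
#' @return The updated `filter_state`.
#' @export
kalman_measurement_update <- function(pred, z, model, window_index = NA) {
  H <- model$H
  d <- ncol(H)
  if (length(z) != nrow(H)) {
    stop_emgk("emgk_validation_error",
              "measurement has %d channels, model expects %d",
              length(z), nrow(H))
  }
  PHt <- pred$P_prior %*% t(H)
  S <- H %*% PHt + model$Q
  S <- (S + t(S)) / 2
  K <- tryCatch(
    t(solve(S, t(PHt))),
    error = function(e) {
      S2 <- make_psd(S)
      tryCatch(t(solve(S2, t(PHt))), error = function(e2) {
        stop_emgk("emgk_numeric_error",
                  "singular innovation covariance at window %s",
                  as.character(window_index))
      })
    }
  )
  innov <- as.numeric(z) - as.numeric(H %*% pred$r_prior)
  pred$r_post <- pred$r_prior + as.numeric(K %*% innov)
  P <- (diag(d) - K %*% H) %*% pred$P_prior
  pred$P_post <- (P + t(P)) / 2
  pred$K <- K
  pred
}

#' Decode a measurement sequence
#'
#' Runs the full Kalman recursion -- time update then measurement update per
#' 100-ms window -- over a sequence of EMG measurement vectors, producing one
#' decoded kinematic state per window. Supply `init` (e.g. the `final_state`
#' attribute of a previous call) to continue a stream; streaming in chunks is
#' exactly equivalent to one batch call.
#'
#' @param measurements M x channels matrix of EMG envelope values.
#' @param model A `kalman_model`.
#' @param init Optional `filter_state` to start from; default [kalman_init()].
#' @return M x d matrix of decoded states (columns named by the model's
#'   state labels), with the terminal `filter_state` attached as attribute
#'   `"final_state"`.
#' @export
decode_sequence <- function(measurements, model, init = NULL) {
  measurements <- as.matrix(measurements)
  d <- length(model$state_labels)
  if (!is.null(colnames(measurements)) &&
      all(model$channels %in% colnames(measurements))) {
    measurements <- measurements[, model$channels, drop = FALSE]
  } else if (ncol(measurements) != nrow(model$H) && nrow(measurements) > 0) {
    stop_emgk("emgk_validation_error",
              "measurements have %d channels, model expects %d",
              ncol(measurements), nrow(model$H))
  }
  m <- nrow(measurements)
  state <- if (is.null(init)) kalman_init(model) else init
  out <- matrix(NA_real_, nrow = m, ncol = d,
                dimnames = list(NULL, model$state_labels))
  for (n in seq_len(m)) {
    state <- kalman_time_update(state, model)
    state <- kalman_measurement_update(state, measurements[n, ], model,
                                       window_index = n)
    out[n, ] <- state$r_post
  }
  attr(out, "final_state") <- state
  out
}
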