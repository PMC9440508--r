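scalar_model <- function(a, h, w, q) {
  structure(
    list(A = matrix(a), H = matrix(h), W = matrix(w), Q = matrix(q),
         state_labels = "theta", channels = "biceps", n_train = 0L),
    class = "kalman_model"
  )
}

# closed-form steady-state posterior variance of the scalar filter:
# prior variance S solves h^2 S^2 + (q - a^2 q - w h^2) S - w q = 0,
# and P_post = S q / (h^2 S + q).
steady_state_post <- function(a, h, w, q) {
  b <- q * (1 - a^2) - w * h^2
  S <- (-b + sqrt(b^2 + 4 * h^2 * w * q)) / (2 * h^2)
  S * q / (h^2 * S + q)
}

test_that("time update applies the dynamics and inflates covariance", {
  m <- scalar_model(2, 1, 0, 1)
  st <- kalman_init(m, r0 = 3)
  up <- kalman_time_update(st, m)
  expect_equal(up$r_prior, 6)

  m2 <- scalar_model(1, 1, 1, 1)
  st2 <- kalman_init(m2)
  st2$P_post <- matrix(0.5)
  expect_equal(kalman_time_update(st2, m2)$P_prior, matrix(1.5))

  # identity dynamics with no process noise change nothing
  d2 <- structure(
    list(A = diag(2), H = matrix(rnorm(8), 4, 2), W = diag(2) * 0,
         Q = diag(4), state_labels = c("theta", "x"),
         channels = emg_channels(), n_train = 0L),
    class = "kalman_model"
  )
  st3 <- kalman_init(d2, r0 = c(2, -1))
  up3 <- kalman_time_update(st3, d2)
  expect_equal(up3$r_prior, c(2, -1))
  expect_equal(up3$P_prior, st3$P_post)
})

test_that("measurement update interpolates between prior and data", {
  # enormous measurement noise: gain ~ 0, estimate stays at the prior
  m <- scalar_model(1, 1, 1, 1e12)
  st <- kalman_time_update(kalman_init(m, r0 = 5), m)
  up <- kalman_measurement_update(st, z = 100, m)
  expect_equal(up$r_post, st$r_prior, tolerance = 1e-6)
  expect_lt(abs(up$K[1]), 1e-6)

  # zero measurement noise with square invertible H: exact data match
  set.seed(9)
  H <- diag(4) + matrix(rnorm(16, sd = 0.1), 4, 4)
  m4 <- structure(
    list(A = diag(4) * 0.9, H = H, W = diag(4) * 0.1,
         Q = diag(4) * 0, state_labels = c("theta", "x", "y", "extra"),
         channels = emg_channels(), n_train = 0L),
    class = "kalman_model"
  )
  st4 <- kalman_time_update(kalman_init(m4), m4)
  z <- c(1, 2, 3, 4)
  up4 <- kalman_measurement_update(st4, z, m4)
  expect_equal(as.numeric(H %*% up4$r_post), z, tolerance = 1e-6)
})

test_that("posterior covariance never exceeds the prior in PSD order", {
  set.seed(13)
  spec <- default_linear_spec(M = 50, seed = 13)
  sim <- generate_linear_session(spec)
  model <- fit_kalman_model(sim$session, c("theta", "x"))
  st <- kalman_init(model)
  for (n in 1:50) {
    st <- kalman_time_update(st, model)
    st <- kalman_measurement_update(st, sim$session$measurements[n, ], model)
    gap <- st$P_prior - st$P_post
    expect_gte(min(eigen((gap + t(gap)) / 2, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("scalar covariance converges to the closed-form Riccati root", {
  # canonical case a = h = w = q = 1: golden-ratio limit
  m <- scalar_model(1, 1, 1, 1)
  st <- kalman_init(m)
  for (i in 1:1000) {
    st <- kalman_time_update(st, m)
    st <- kalman_measurement_update(st, z = 0, m)
  }
  expect_equal(st$P_post[1, 1], (-1 + sqrt(5)) / 2, tolerance = 1e-9)

  for (a in c(-1, -0.5, 0.3, 0.9, 1)) {
    for (h in c(0.5, 2)) {
      for (w in c(0.1, 1)) {
        for (q in c(0.2, 2)) {
          m <- scalar_model(a, h, w, q)
          st <- kalman_init(m)
          for (i in 1:1000) {
            st <- kalman_time_update(st, m)
            st <- kalman_measurement_update(st, z = 0, m)
          }
          expect_equal(st$P_post[1, 1], steady_state_post(a, h, w, q),
                       tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("decoding matched synthetic data approaches the oracle filter", {
  spec <- default_linear_spec(M = 2000, seed = 31)
  sim <- generate_linear_session(spec)
  true_model <- structure(
    list(A = spec$A0, H = spec$H0, W = spec$W0, Q = spec$Q0,
         state_labels = c("theta", "x"), channels = emg_channels(),
         n_train = 0L),
    class = "kalman_model"
  )
  est_model <- fit_kalman_model(sim$session, c("theta", "x"))
  dec_true <- decode_sequence(sim$session$measurements, true_model)
  dec_est <- decode_sequence(sim$session$measurements, est_model)
  for (p in c("theta", "x")) {
    cc_true <- pearson_cc(dec_true[, p], sim$states[, p])
    cc_est <- pearson_cc(dec_est[, p], sim$states[, p])
    expect_gte(cc_est, 0.9)
    expect_lte(abs(cc_true - cc_est), 0.05)
  }
})

test_that("streaming in chunks equals one batch decode", {
  spec <- default_linear_spec(M = 300, seed = 17)
  sim <- generate_linear_session(spec)
  model <- fit_kalman_model(sim$session, c("theta", "x"))
  z <- sim$session$measurements
  batch <- decode_sequence(z, model)
  c1 <- decode_sequence(z[1:120, ], model)
  c2 <- decode_sequence(z[121:300, ], model,
                        init = attr(c1, "final_state"))
  chained <- rbind(c1, c2)
  expect_identical(unname(batch[, ]), unname(chained[, ]))
})

test_that("a single window with huge noise returns the propagated prior", {
  d2 <- structure(
    list(A = matrix(c(0.5, 0, 0.25, 0.5), 2, 2),
         H = matrix(1, 4, 2), W = diag(2) * 0.01, Q = diag(4) * 1e12,
         state_labels = c("theta", "x"), channels = emg_channels(),
         n_train = 0L),
    class = "kalman_model"
  )
  out <- decode_sequence(matrix(5, 1, 4, dimnames = list(NULL, emg_channels())),
                         d2)
  expect_equal(as.numeric(out), as.numeric(d2$A %*% c(1, 1)), tolerance = 1e-6)
})
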