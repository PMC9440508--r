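test_that("training matrices have the documented shapes and orderings", {
  w <- exact_windowed(diag(3) * 0.9, c(1, 2, 3), M = 5)
  tm <- build_training_matrices(w, c("theta", "x"))
  expect_equal(dim(tm$R), c(2, 5))
  expect_equal(dim(tm$R1), c(2, 4))
  expect_equal(dim(tm$R2), c(2, 4))
  expect_equal(dim(tm$Z), c(4, 5))
  expect_equal(tm$R1, tm$R[, 1:4])
  expect_equal(tm$R2, tm$R[, 2:5])
  expect_equal(nrow(build_training_matrices(w, "theta")$R), 1)
  expect_equal(nrow(build_training_matrices(w, c("theta", "x", "y"))$R), 3)
  expect_error(build_training_matrices(w, "nope"),
               class = "emgk_validation_error")
})

test_that("segment pooling never pairs windows across a gap", {
  w1 <- exact_windowed(diag(1) * 2, 1, M = 4)  # states 1,2,4,8
  w2 <- exact_windowed(diag(1) * 2, 16, M = 3) # states 16,32,64
  tm <- build_training_matrices(list(w1, w2), "theta")
  expect_equal(tm$M, 7)
  expect_equal(tm$n_pairs, 5)
  expect_equal(as.numeric(tm$R1), c(1, 2, 4, 16, 32))
  expect_equal(as.numeric(tm$R2), c(2, 4, 8, 32, 64))
})

test_that("transition estimate reproduces exact dynamics", {
  # doubling sequence 1,2,4,8 -> a = 2 exactly
  w <- exact_windowed(matrix(2), 1, M = 4)
  tm <- build_training_matrices(w, "theta")
  expect_equal(estimate_transition(tm), matrix(2), tolerance = 1e-12)

  # constant sequence -> identity
  r <- matrix(rep(c(3, -1), each = 6), ncol = 2)
  z <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, emg_channels()))
  wc <- windowed_session(r, z, state_labels = c("theta", "x"))
  tmc <- build_training_matrices(wc, c("theta", "x"))
  A <- suppressWarnings(estimate_transition(tmc))
  expect_equal(A %*% c(3, -1), matrix(c(3, -1)), tolerance = 1e-9)
})

test_that("observation estimate recovers exact linear maps", {
  set.seed(11)
  r <- matrix(rnorm(40), 2, 20)
  H_true <- rbind(2 * diag(2), matrix(0, 2, 2))
  z <- t(H_true %*% r)
  colnames(z) <- emg_channels()
  w <- windowed_session(t(r), z, state_labels = c("theta", "x"))
  tm <- build_training_matrices(w, c("theta", "x"))
  expect_equal(estimate_observation(tm), H_true, tolerance = 1e-10)

  zz <- z * 0
  w0 <- windowed_session(t(r), zz, state_labels = c("theta", "x"))
  tm0 <- build_training_matrices(w0, c("theta", "x"))
  expect_equal(estimate_observation(tm0), matrix(0, 4, 2), tolerance = 1e-12)
})

test_that("estimates agree with an independent least-squares solver", {
  set.seed(21)
  for (i in 1:5) {
    r <- matrix(rnorm(2 * 50), 2, 50)
    z <- matrix(rnorm(4 * 50), 4, 50)
    w <- windowed_session(t(r), t(z), state_labels = c("theta", "x"),
                          channels = emg_channels())
    tm <- build_training_matrices(w, c("theta", "x"))
    # oracle: qr-based multi-response regression without intercept
    A_or <- unname(t(qr.solve(t(tm$R1), t(tm$R2))))
    H_or <- unname(t(qr.solve(t(tm$R), t(tm$Z))))
    expect_equal(estimate_transition(tm), A_or, tolerance = 1e-10)
    expect_equal(estimate_observation(tm), H_or, tolerance = 1e-10)
  }
})

test_that("noise estimates vanish on noiseless systems and are PSD repaired", {
  A <- matrix(c(0.9, 0.1, 0, 0.8), 2, 2)
  w <- exact_windowed(A, c(1, -2), M = 30)
  tm <- build_training_matrices(w, c("theta", "x"))
  Ah <- estimate_transition(tm)
  Hh <- estimate_observation(tm)
  nz <- estimate_noise(tm, Ah, Hh)
  expect_lt(max(abs(nz$W)), 1e-10)
  expect_lt(max(abs(nz$Q)), 1e-10)
  # PSD with floored eigenvalues even in the degenerate case
  expect_gte(min(eigen(nz$W, symmetric = TRUE)$values), 0)
  expect_gte(min(eigen(nz$Q, symmetric = TRUE)$values), 0)
  expect_equal(nz$W, t(nz$W))
  expect_equal(nz$Q, t(nz$Q))
})

test_that("parameter recovery from simulated data is consistent", {
  spec <- default_linear_spec(M = 20000, seed = 101)
  sim <- generate_linear_session(spec)
  fit <- fit_kalman_model(sim$session, c("theta", "x"))
  expect_lt(norm(fit$A - spec$A0, "F"), 0.05)
  expect_lt(norm(fit$H - spec$H0, "F"), 0.05)
  rel_err <- function(est, truth) {
    abs(diag(est) - diag(truth)) / diag(truth)
  }
  expect_lt(max(rel_err(fit$W, spec$W0)), 0.10)
  expect_lt(max(rel_err(fit$Q, spec$Q0)), 0.10)
})

test_that("estimator error shrinks with sample size (median over seeds)", {
  err_at <- function(M) {
    sapply(1:8, function(seed) {
      spec <- default_linear_spec(M = M, seed = seed)
      sim <- generate_linear_session(spec)
      fit <- fit_kalman_model(sim$session, c("theta", "x"))
      c(A = norm(fit$A - spec$A0, "F"), H = norm(fit$H - spec$H0, "F"),
        W = norm(fit$W - spec$W0, "F"), Q = norm(fit$Q - spec$Q0, "F"))
    })
  }
  small <- apply(err_at(1000), 1, median)
  large <- apply(err_at(10000), 1, median)
  expect_true(all(large < small))
})

test_that("models serialize to JSON and back", {
  spec <- default_linear_spec(M = 500, seed = 4)
  fit <- fit_kalman_model(generate_linear_session(spec)$session,
                          c("theta", "x"))
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(fit, path)
  back <- model_from_json(path)
  expect_equal(back$A, fit$A, tolerance = 1e-12)
  expect_equal(back$H, fit$H, tolerance = 1e-12)
  expect_equal(back$W, fit$W, tolerance = 1e-12)
  expect_equal(back$Q, fit$Q, tolerance = 1e-12)
  expect_equal(back$state_labels, fit$state_labels)
})
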