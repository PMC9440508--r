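test_that("validation block size and determinism follow the configuration", {
  sim <- generate_linear_session(selection_fixture_spec(M = 1000, seed = 2))
  sel <- select_combinations(sim$session, validation_fraction = 0.2, seed = 7)
  expect_equal(sel$validation_block$length, 200)
  sel2 <- select_combinations(sim$session, validation_fraction = 0.2, seed = 7)
  expect_identical(sel$per_parameter_winner, sel2$per_parameter_winner)
  expect_identical(sel$validation_scores, sel2$validation_scores)
  sel3 <- select_combinations(sim$session, validation_fraction = 0.2, seed = 8)
  expect_false(identical(sel3$validation_block, sel$validation_block))

  expect_error(select_combinations(sim$session, validation_fraction = 0.01,
                                   seed = 1),
               class = "emgk_validation_error")
  expect_error(select_combinations(sim$session, validation_fraction = 0.7,
                                   seed = 1),
               class = "emgk_parameter_error")
})

test_that("each winner is one of the two pairs containing its parameter", {
  for (seed in 1:3) {
    sim <- generate_linear_session(default_linear_spec(M = 600, seed = seed))
    w3 <- windowed_session(
      cbind(sim$session$states,
            y = as.numeric(sim$session$states[, "x"]) * 0.5 +
              rnorm(600, sd = 0.2)),
      sim$session$measurements, state_labels = kin_params()
    )
    sel <- select_combinations(w3, seed = seed)
    for (p in kin_params()) {
      expect_true(p %in% sel$candidate_pairs[[sel$per_parameter_winner[[p]]]])
    }
  }
})

test_that("the constructed fixture selects (theta, x) for theta", {
  wins <- 0
  for (seed in 1:10) {
    sim <- generate_linear_session(selection_fixture_spec(M = 3000, seed = seed))
    sel <- select_combinations(sim$session, seed = seed)
    if (sel$per_parameter_winner$theta == "theta_x") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("selection matches an exhaustive pair-evaluation oracle", {
  sim <- generate_linear_session(selection_fixture_spec(M = 2000, seed = 5))
  sel <- select_combinations(sim$session, seed = 5)
  # oracle: refit and re-decode every pair on the same validation block
  blk <- sel$validation_block
  m <- sim$session$n_windows
  vidx <- seq(blk$start, blk$start + blk$length - 1)
  take <- function(ix) windowed_session(
    sim$session$states[ix, , drop = FALSE],
    sim$session$measurements[ix, , drop = FALSE],
    state_labels = kin_params()
  )
  train_segs <- Filter(function(s) !is.null(s), list(
    if (blk$start > 2) take(seq_len(blk$start - 1)) else NULL,
    if (blk$start + blk$length + 1 <= m) take(seq(blk$start + blk$length, m)) else NULL
  ))
  val <- take(vidx)
  for (pn in names(candidate_pairs())) {
    pair <- candidate_pairs()[[pn]]
    model <- fit_kalman_model(train_segs, pair)
    dec <- decode_sequence(val$measurements, model)
    for (p in pair) {
      got <- sel$validation_scores$cc[sel$validation_scores$pair == pn &
                                        sel$validation_scores$parameter == p]
      expect_equal(got, pearson_cc(val$states[, p], dec[, p]),
                   tolerance = 1e-10)
    }
  }
  # winner per parameter is the argmax over its two containing pairs
  for (p in kin_params()) {
    sc <- sel$validation_scores[sel$validation_scores$parameter == p, ]
    expect_equal(sel$per_parameter_winner[[p]], sc$pair[which.max(sc$cc)])
  }
})

test_that("the fitted decoder counts one model per distinct winning pair", {
  sim <- generate_linear_session(selection_fixture_spec(M = 2000, seed = 3))
  sel <- select_combinations(sim$session, seed = 3)
  sel$per_parameter_winner <- list(theta = "theta_x", x = "theta_x",
                                   y = "x_y")
  dec <- fit_multi_decoder(sim$session, sel)
  expect_length(dec$models, 2)

  sel$per_parameter_winner <- list(theta = "theta_y", x = "x_y",
                                   y = "theta_y")
  dec2 <- fit_multi_decoder(sim$session, sel)
  expect_length(dec2$models, 2)

  sel$per_parameter_winner <- list(theta = "theta_x", x = "x_y",
                                   y = "theta_y")
  expect_warning(dec3 <- fit_multi_decoder(sim$session, sel),
                 class = "emgk_selection_warning")
  expect_length(dec3$models, 3)
})

test_that("multi decoding assembles columns from the winning filters", {
  sim <- generate_linear_session(selection_fixture_spec(M = 2000, seed = 9))
  sel <- select_combinations(sim$session, seed = 9)
  dec <- fit_multi_decoder(sim$session, sel)
  out <- decode_kinematics(dec, sim$session$measurements)
  expect_equal(colnames(out), kin_params())
  expect_equal(nrow(out), 2000)
  for (p in kin_params()) {
    ref <- decode_sequence(sim$session$measurements,
                           dec$models[[dec$assignment[[p]]]])
    expect_identical(unname(out[, p]), unname(ref[, p]))
  }
  # empty input decodes to an empty matrix
  e <- decode_kinematics(dec, matrix(numeric(0), 0, 4))
  expect_equal(dim(e), c(0, 3))

  # a decoder whose filters do not cover every parameter errors out
  broken <- dec
  broken$assignment <- broken$assignment[c("theta", "x")]
  expect_error(decode_kinematics(broken, sim$session$measurements),
               class = "emgk_validation_error")
})

test_that("single and three-filter baselines have documented shapes", {
  sim <- generate_linear_session(selection_fixture_spec(M = 1500, seed = 6))
  single <- fit_single_decoder(sim$session)
  expect_equal(dim(single$model$A), c(3, 3))
  expect_equal(dim(single$model$H), c(4, 3))
  out_s <- decode_kinematics(single, sim$session$measurements)
  for (p in kin_params()) {
    expect_gt(pearson_cc(out_s[, p], sim$states[, p]), 0)
  }

  three <- fit_three_decoder(sim$session)
  expect_length(three$models, 3)
  for (p in kin_params()) {
    expect_equal(dim(three$models[[p]]$A), c(1, 1))
    expect_equal(dim(three$models[[p]]$H), c(4, 1))
  }
  out_t <- decode_kinematics(three, sim$session$measurements)
  expect_equal(colnames(out_t), kin_params())
})

test_that("independent states make the extra pair state uninformative", {
  # states evolve and are observed independently: pair filters and scalar
  # filters then agree closely per parameter
  A0 <- diag(c(0.9, 0.92, 0.88))
  H0 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.5, 0, 0))
  spec <- linear_gen_spec(A0, H0, diag(c(0.05, 0.05, 0.05)),
                          diag(4) * 0.1, M = 4000, seed = 14)
  sim <- generate_linear_session(spec)
  three <- fit_three_decoder(sim$session)
  out_t <- decode_kinematics(three, sim$session$measurements)
  for (pn in names(candidate_pairs())) {
    pair <- candidate_pairs()[[pn]]
    model <- fit_kalman_model(sim$session, pair)
    dec <- decode_sequence(sim$session$measurements, model)
    for (p in pair) {
      cc_pair <- pearson_cc(dec[, p], sim$states[, p])
      cc_three <- pearson_cc(out_t[, p], sim$states[, p])
      expect_lt(abs(cc_pair - cc_three), 0.05)
    }
  }
})

test_that("decoder bundles serialize to JSON", {
  sim <- generate_linear_session(selection_fixture_spec(M = 1500, seed = 2))
  dec <- fit_multi_decoder(sim$session, select_combinations(sim$session, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  decoder_to_json(dec, path)
  doc <- jsonlite::fromJSON(path)
  expect_named(doc$assignment, kin_params(), ignore.order = TRUE)
  expect_true(all(names(doc$models) %in% names(candidate_pairs())))
})
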