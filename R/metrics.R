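#' Pearson correlation coefficient
#'
#' The product-moment correlation between a decoded and an actual kinematic
#' trace, the primary decoding performance measure.
#'
#' @param a,b Numeric vectors of equal length >= 2, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b)) {
    stop_emgk("emgk_validation_error", "length mismatch: %d vs %d",
              length(a), length(b))
  }
  if (length(a) < 2) stop_emgk("emgk_validation_error", "need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_emgk("emgk_degenerate_error",
              "correlation undefined for a constant signal")
  }
  stats::cor(a, b)
}

#' Root-mean-square error
#'
#' @param a,b Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((a - b)^2))`, non-negative.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stop_emgk("emgk_validation_error", "length mismatch: %d vs %d",
              length(a), length(b))
  }
  sqrt(mean((a - b)^2))
}

#' Range-normalized root-mean-square error
#'
#' RMSE divided by the range of the *actual* signal `a`, making errors
#' comparable across parameters with different units and excursions.
#'
#' @param a Actual signal (defines the normalizing range).
#' @param b Decoded signal.
#' @return `rmse(a, b) / (max(a) - min(a))`.
#' @export
nrmse <- function(a, b) {
  r <- max(a) - min(a)
  if (r == 0) {
    stop_emgk("emgk_degenerate_error",
              "NRMSE undefined: actual signal is constant")
  }
  rmse(a, b) / r
}

#' Score decoded kinematics against the actual ones
#'
#' Computes CC, RMSE and NRMSE per kinematic parameter for matched actual /
#' decoded matrices, in the tidy layout used by the evaluation reports.
#'
#' @param actual,decoded Matrices with one column per parameter (matching
#'   column names) and one row per window.
#' @param parameters Which parameters to score (default: shared columns).
#' @param subject_id,fold_id Optional provenance carried into the report.
#' @return `data.frame` with columns `subject`, `fold`, `parameter`, `cc`,
#'   `rmse`, `nrmse`, `n`.
#' @export
score_decoding <- function(actual, decoded,
                           parameters = intersect(colnames(actual),
                                                  colnames(decoded)),
                           subject_id = NA_character_, fold_id = NA_integer_) {
  actual <- as.matrix(actual)
  decoded <- as.matrix(decoded)
  rows <- lapply(parameters, function(p) {
    a <- actual[, p]
    b <- decoded[, p]
    cc <- tryCatch(pearson_cc(a, b), emgk_degenerate_error = function(e) NA_real_)
    nr <- tryCatch(nrmse(a, b), emgk_degenerate_error = function(e) NA_real_)
    data.frame(subject = subject_id, fold = fold_id, parameter = p,
               cc = cc, rmse = rmse(a, b), nrmse = nr, n = length(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
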