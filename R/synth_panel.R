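#' Simulate a fold-change panel for the shape-response regression
#'
#' Emulates a screen of cell-line x perturbation conditions: each row
#' carries the treated/control fold change of neighbor fraction (NF),
#' ruffliness and the nuclear/cytoplasmic area ratio, and a response
#' fold change of the NF-kB ratio generated as
#' \deqn{\Delta tf = c_0 + c_1 \Delta NF + c_2 \Delta ruff +
#'   c_3 \Delta A_{nuc}/A_{cyto} + \epsilon .}
#' Predictor fold changes are lognormal around 1 (a no-change condition
#' maps to 1).
#'
#' @param coefficients Numeric length 4: intercept, NF, ruffliness,
#'   area-ratio coefficients.
#' @param n_conditions Number of conditions (rows), >= 5.
#' @param noise_sd Gaussian SD of the response noise (>= 0).
#' @param seed Integer seed.
#' @param predictor_sdlog SD of the predictors on the log scale.
#' @return data.frame with columns \code{condition_id}, \code{d_nf},
#'   \code{d_ruffliness}, \code{d_anucacyto}, \code{d_tfratio}.
#' @export
simulate_fold_change_panel <- function(coefficients, n_conditions = 176L,
                                       noise_sd = 0.05, seed = 1L,
                                       predictor_sdlog = 0.15) {
  stopifnot(length(coefficients) == 4L)
  if (n_conditions < 5L) stop("n_conditions must be >= 5")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    d_nf <- stats::rlnorm(n_conditions, 0, predictor_sdlog)
    d_ruff <- stats::rlnorm(n_conditions, 0, predictor_sdlog)
    d_ratio <- stats::rlnorm(n_conditions, 0, predictor_sdlog)
    eps <- if (noise_sd > 0) stats::rnorm(n_conditions, 0, noise_sd) else 0
    y <- coefficients[1] + coefficients[2] * d_nf +
      coefficients[3] * d_ruff + coefficients[4] * d_ratio + eps
    data.frame(condition_id = sprintf("cond_%03d", seq_len(n_conditions)),
               d_nf = d_nf, d_ruffliness = d_ruff, d_anucacyto = d_ratio,
               d_tfratio = y, stringsAsFactors = FALSE)
  })
}

#' Default coefficients of the synthetic fold-change panel
#'
#' Sign structure follows the screen's finding that the NF-kB ratio change
#' is negatively associated with neighbor fraction and the nuclear/
#' cytoplasmic area ratio and positively associated with ruffliness.
#'
#' @return Numeric length 4 (intercept, NF, ruffliness, area ratio).
#' @export
default_panel_coefficients <- function() c(1.0, -0.30, 0.25, -0.35)

#' Noise SD giving a target population R-squared
#'
#' For independent lognormal predictors with log-scale SD
#' \code{predictor_sdlog}, the signal variance is
#' \eqn{\sum_i c_i^2 Var(X_i)} and the noise SD solving
#' \eqn{R^2 = V_s / (V_s + \sigma^2)} is returned in closed form.
#'
#' @param coefficients As in \code{\link{simulate_fold_change_panel}}.
#' @param r2 Target population R-squared in (0, 1).
#' @param predictor_sdlog Predictor log-scale SD.
#' @return Noise SD (scalar).
#' @export
panel_noise_for_r2 <- function(coefficients, r2,
                               predictor_sdlog = 0.15) {
  stopifnot(r2 > 0, r2 < 1, length(coefficients) == 4L)
  s2 <- predictor_sdlog^2
  vx <- (exp(s2) - 1) * exp(s2)  # variance of lognormal(0, sdlog)
  vs <- sum(coefficients[2:4]^2) * vx
  sqrt(vs * (1 - r2) / r2)
}
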