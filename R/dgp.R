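#' Parameters of the copula data-generating process
#'
#' Defines the two marginal regression models and the dependence structure
#' used to simulate individual-participant data (IPD) with one continuous and
#' one binary outcome. The continuous outcome follows a normal linear model
#' and the binary outcome a Bernoulli/logit model; the two are linked at the
#' individual level through a Gaussian copula with correlation `rho`, and at
#' the study level through correlated random intercepts with correlation
#' `phi`.
#'
#' Defaults reproduce the reference simulation conditions: continuous-margin
#' coefficients (intercept, treatment, x1, x2) = (1, 1, 0.5, 0.5), logit
#' binary-margin coefficients (intercept, treatment, x3, x4) =
#' (-0.5, 0.1, 0.2, 0.2), unit residual variance for the continuous outcome
#' and unit random-intercept variances for both outcomes.
#'
#' @param beta_cont Coefficients of the continuous linear predictor:
#'   intercept, treatment, x1, x2.
#' @param beta_bin Coefficients of the binary logit predictor: intercept,
#'   treatment, x3, x4.
#' @param sigma1_sq Residual variance of the continuous outcome (> 0).
#' @param rho Individual-level copula correlation, in (-1, 1).
#' @param phi Study-level random-intercept correlation, in (-1, 1).
#' @param tau_sq Length-2 vector of random-intercept variances (> 0).
#' @return An object of class `dgp_params`.
#' @examples
#' dgp_params(rho = 0.2, phi = 0.1)
#' @export
dgp_params <- function(beta_cont = c(1, 1, 0.5, 0.5),
                       beta_bin = c(-0.5, 0.1, 0.2, 0.2),
                       sigma1_sq = 1,
                       rho = 0.2,
                       phi = 0.1,
                       tau_sq = c(1, 1)) {
  stopifnot(length(beta_cont) == 4, length(beta_bin) == 4, length(tau_sq) == 2)
  if (abs(rho) >= 1) abort("`rho` must satisfy |rho| < 1.")
  if (abs(phi) >= 1) abort("`phi` must satisfy |phi| < 1.")
  if (sigma1_sq <= 0) abort("`sigma1_sq` must be positive.")
  if (any(tau_sq <= 0)) abort("both components of `tau_sq` must be positive.")
  structure(
    list(beta_cont = beta_cont, beta_bin = beta_bin, sigma1_sq = sigma1_sq,
         rho = rho, phi = phi, tau_sq = tau_sq),
    class = "dgp_params"
  )
}

#' One cell of the simulation grid
#'
#' @param n_studies Number of studies (clusters).
#' @param n_per_study Participants per study.
#' @param rho Individual-level copula correlation.
#' @param phi Study-level random-intercept correlation.
#' @param missingness A [missingness_params()] object, or `NULL` for complete
#'   data.
#' @param seed Optional integer seed recorded with the scenario.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(20, 150, rho = 0.2, phi = 0.1)
#' @export
scenario_config <- function(n_studies, n_per_study, rho = 0.2, phi = 0.1,
                            missingness = NULL, seed = NULL) {
  if (n_studies < 1 || n_per_study < 1) {
    abort("`n_studies` and `n_per_study` must be positive integers.")
  }
  if (!is.null(missingness) && !inherits(missingness, "missingness_params")) {
    abort("`missingness` must be created by missingness_params().")
  }
  structure(
    list(n_studies = as.integer(n_studies),
         n_per_study = as.integer(n_per_study),
         rho = rho, phi = phi, missingness = missingness, seed = seed),
    class = "scenario_config"
  )
}

#' The paper-style scenario grid
#'
#' Returns the factorial grid of simulation conditions: study layout
#' \{(20, 150), (5, 600)\}, individual-level correlation rho in \{0.2, 0.7\},
#' study-level correlation phi in \{0.1, 0.3\} and missingness rate in
#' \{0.2, 0.5\}, for a given mechanism.
#'
#' @param mechanism One of `"covariate_only"`, `"outcome_dependent"`,
#'   `"systematic_binary"`.
#' @return A tibble with one row per scenario.
#' @export
scenario_grid <- function(mechanism = "covariate_only") {
  tidyr::expand_grid(
    layout = c("20x150", "5x600"),
    rho = c(0.2, 0.7),
    phi = c(0.1, 0.3),
    rate = c(0.2, 0.5)
  ) |>
    dplyr::mutate(
      n_studies = ifelse(.data$layout == "20x150", 20L, 5L),
      n_per_study = ifelse(.data$layout == "20x150", 150L, 600L),
      mechanism = mechanism
    )
}

#' Missingness mechanism parameters
#'
#' Encodes the logistic missingness models for the two outcomes,
#' logit P(R_k = 1) = theta0 + theta1 * x_k + theta2 * y_other, where `x_k`
#' is the missingness covariate of outcome k (x1 for the continuous outcome,
#' x3 for the binary outcome) and `y_other` is the other outcome (used only
#' by the outcome-dependent mechanism). `theta2` must be zero under the
#' covariate-only mechanism.
#'
#' @param mechanism `"covariate_only"`, `"outcome_dependent"` or
#'   `"systematic_binary"`.
#' @param target_rate Intended marginal missingness proportion per outcome
#'   (within the eligible half-sample for the outcome-dependent mechanism).
#' @param theta_cont,theta_bin Length-3 vectors (theta0, theta1, theta2) of
#'   the missingness model for the continuous and binary outcome.
#' @param n_systematic_studies For `"systematic_binary"` only: number of
#'   studies whose binary outcome is set entirely missing.
#' @return An object of class `missingness_params`.
#' @export
missingness_params <- function(mechanism = c("covariate_only",
                                             "outcome_dependent",
                                             "systematic_binary"),
                               target_rate,
                               theta_cont = c(0, 0, 0),
                               theta_bin = c(0, 0, 0),
                               n_systematic_studies = NULL) {
  mechanism <- match.arg(mechanism)
  if (target_rate <= 0 || target_rate >= 1) {
    abort("`target_rate` must lie strictly between 0 and 1.")
  }
  stopifnot(length(theta_cont) == 3, length(theta_bin) == 3)
  if (mechanism == "covariate_only" &&
      (theta_cont[3] != 0 || theta_bin[3] != 0)) {
    abort("theta2 must be 0 under the covariate-only mechanism.")
  }
  if (mechanism == "systematic_binary" && is.null(n_systematic_studies)) {
    abort("`n_systematic_studies` is required for the systematic mechanism.")
  }
  structure(
    list(mechanism = mechanism, target_rate = target_rate,
         theta_cont = theta_cont, theta_bin = theta_bin,
         n_systematic_studies = n_systematic_studies),
    class = "missingness_params"
  )
}

## exact 1:1 allocation within study (permuted block)
balanced_treatment <- function(n) {
  sample(rep(0:1, length.out = n))
}

#' Draw complete IPD from the copula model
#'
#' Simulates a complete two-level participant table. Per study, random
#' intercepts (u1, u2) are drawn from a bivariate normal with unit variances
#' (scaled by `tau_sq`) and correlation `phi`. Per participant, covariates
#' x1..x4 are i.i.d. standard normal; the marginal means are
#' mu = beta_cont' (1, t, x1, x2) + u1 and
#' logit(pi) = beta_bin' (1, t, x3, x4) + u2. A bivariate standard normal
#' pair with correlation `rho` is mapped through the normal CDF to uniforms
#' (w1, w2); then y_cont = mu + sigma1 * qnorm(w1) and y_bin = 1 if
#' w2 > 1 - pi, so that larger latent values map to y_bin = 1 and the sign
#' of `rho` carries over to a positive outcome association.
#'
#' @param config A [scenario_config()].
#' @param params A [dgp_params()]; its `rho`/`phi` are overridden by the
#'   scenario's values.
#' @param seed Integer seed (defaults to the scenario's seed).
#' @param keep_latent If `TRUE`, keep the underlying standard-normal pair as
#'   columns `.z1`, `.z2` (useful for checking copula fidelity).
#' @return A tibble with columns `study_id`, `treatment`, `x1`..`x4`,
#'   `y_cont`, `y_bin`, and observedness flags `r_cont`, `r_bin` (all `TRUE`
#'   for a complete table).
#' @examples
#' d <- draw_complete_ipd(scenario_config(5, 40), seed = 1)
#' dplyr::count(d, study_id, treatment)
#' @export
draw_complete_ipd <- function(config, params = dgp_params(),
                              seed = NULL, keep_latent = FALSE) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be created by scenario_config().")
  }
  if (!inherits(params, "dgp_params")) {
    abort("`params` must be created by dgp_params().")
  }
  params$rho <- config$rho %||% params$rho
  params$phi <- config$phi %||% params$phi
  if (abs(params$rho) >= 1) abort("|rho| must be < 1.")
  if (abs(params$phi) >= 1) abort("|phi| must be < 1.")
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  J <- config$n_studies
  npj <- config$n_per_study
  n <- J * npj
  study <- rep(seq_len(J), each = npj)

  ## study-level random intercepts: unit-variance bivariate normal with
  ## correlation phi, scaled to tau
  eu <- matrix(rnorm(2 * J), J, 2)
  u <- eu %*% chol(matrix(c(1, params$phi, params$phi, 1), 2))
  u[, 1] <- u[, 1] * sqrt(params$tau_sq[1])
  u[, 2] <- u[, 2] * sqrt(params$tau_sq[2])

  treatment <- as.integer(unlist(lapply(seq_len(J),
                                        function(j) balanced_treatment(npj))))
  X <- matrix(rnorm(4 * n), n, 4)
  mu <- params$beta_cont[1] + params$beta_cont[2] * treatment +
    params$beta_cont[3] * X[, 1] + params$beta_cont[4] * X[, 2] + u[study, 1]
  eta <- params$beta_bin[1] + params$beta_bin[2] * treatment +
    params$beta_bin[3] * X[, 3] + params$beta_bin[4] * X[, 4] + u[study, 2]
  pi <- plogis(eta)

  ## Gaussian copula: correlated standard-normal pair -> uniforms -> margins
  ez <- matrix(rnorm(2 * n), n, 2)
  zz <- ez %*% chol(matrix(c(1, params$rho, params$rho, 1), 2))
  w1 <- pnorm(zz[, 1])
  w2 <- pnorm(zz[, 2])
  y_cont <- mu + sqrt(params$sigma1_sq) * qnorm(w1)
  y_bin <- as.integer(w2 > 1 - pi)

  out <- tibble(
    study_id = as.integer(study),
    treatment = treatment,
    x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], x4 = X[, 4],
    y_cont = y_cont,
    y_bin = y_bin,
    r_cont = TRUE,
    r_bin = TRUE
  )
  if (keep_latent) {
    out$.z1 <- zz[, 1]
    out$.z2 <- zz[, 2]
  }
  out
}

## shared validation for participant tables
check_ipd <- function(data, require_complete = FALSE) {
  needed <- c("study_id", "treatment", "x1", "x2", "x3", "x4",
              "y_cont", "y_bin")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("input is not an IPD table; missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (require_complete && (anyNA(data$y_cont) || anyNA(data$y_bin))) {
    abort("a complete table (no missing outcomes) is required here.")
  }
  invisible(data)
}

## keep r_cont / r_bin flags in sync with NA patterns
sync_r_flags <- function(data) {
  data$r_cont <- !is.na(data$y_cont)
  data$r_bin <- !is.na(data$y_bin)
  data
}
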