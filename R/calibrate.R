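#' Calibrate missingness-model coefficients
#'
#' The simulation design specifies targets for the missingness models rather
#' than coefficients: a marginal missingness proportion (20% or 50%) and a
#' correlation of about 0.3 between the missingness indicator R_k and its
#' covariate x_k. This function recovers (theta0, theta1) by stochastic
#' root-finding: a large table is simulated once under a fixed oracle seed,
#' and nested bisection matches the empirical rate (inner, on theta0) and the
#' empirical indicator-covariate correlation (outer, on theta1) on that
#' table. The correlation is the Pearson correlation of the 0/1 indicator
#' with the covariate, computed in expectation over the Bernoulli draw
#' (cov(R, x) = cov(p(x), x), var(R) = p(1-p)).
#'
#' Under the outcome-dependent mechanism, theta2 is held at its configured
#' value while (theta0, theta1) are calibrated with the outcome term active.
#' When `theta2` is `NULL` it is set by an a-priori equal-association rule:
#' the per-standard-deviation log-odds effect of the other outcome equals the
#' covariate's (theta2 = theta1_cov / sd(y_other)), where theta1_cov is the
#' covariate-only solution.
#'
#' @param target_rate Desired marginal missingness proportion (0, 1).
#' @param target_corr Desired corr(R_k, x_k); 0.3 in the reference scenarios.
#' @param params [dgp_params()] describing the outcome model.
#' @param mechanism `"covariate_only"` or `"outcome_dependent"`.
#' @param theta2 Length-2 vector (continuous-outcome model coefficient on
#'   y_bin, binary-outcome model coefficient on y_cont), or `NULL` for the
#'   equal-association default. Ignored under `"covariate_only"`.
#' @param n_sim Rows of the calibration table.
#' @param oracle_seed Fixed seed of the calibration table.
#' @param max_iter Bisection iteration cap per solve.
#' @return A [missingness_params()] object with calibrated coefficients.
#' @examples
#' \donttest{
#' mp <- calibrate_theta(0.2, 0.3, n_sim = 5e4)
#' mp$theta_cont
#' }
#' @export
calibrate_theta <- function(target_rate, target_corr = 0.3,
                            params = dgp_params(),
                            mechanism = c("covariate_only",
                                          "outcome_dependent"),
                            theta2 = NULL,
                            n_sim = 2e5, oracle_seed = 20260928L,
                            max_iter = 30) {
  mechanism <- match.arg(mechanism)
  if (target_rate <= 0 || target_rate >= 1) {
    abort("`target_rate` must lie strictly between 0 and 1.")
  }

  ## one large reference table under a fixed oracle seed
  J <- 20L
  npj <- as.integer(ceiling(n_sim / J))
  big <- draw_complete_ipd(
    scenario_config(J, npj, rho = params$rho, phi = params$phi),
    params, seed = oracle_seed
  )

  solve_theta <- function(x, extra) {
    ## calibrate (theta0, theta1) for one outcome given its covariate x and
    ## the fixed extra linear-predictor term (theta2 * y_other or 0)
    rate_at <- function(th0, th1) mean(plogis(th0 + th1 * x + extra))
    corr_at <- function(th0, th1) {
      p <- plogis(th0 + th1 * x + extra)
      pbar <- mean(p)
      cov(p, x) / sqrt(pbar * (1 - pbar) * var(x))
    }
    th0_for <- function(th1) {
      lo <- -15; hi <- 15
      for (k in seq_len(max_iter)) {
        mid <- (lo + hi) / 2
        if (rate_at(mid, th1) < target_rate) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    if (target_corr == 0) {
      th1 <- 0
    } else {
      lo <- 0; hi <- 8
      if (corr_at(th0_for(hi), hi) < target_corr) {
        abort(paste0("target correlation ", target_corr,
                     " is unreachable for this mechanism/rate."))
      }
      for (k in seq_len(max_iter)) {
        th1 <- (lo + hi) / 2
        if (corr_at(th0_for(th1), th1) < target_corr) lo <- th1 else hi <- th1
      }
      th1 <- (lo + hi) / 2
    }
    c(th0_for(th1), th1)
  }

  if (mechanism == "covariate_only") {
    tc <- solve_theta(big$x1, 0)
    tb <- solve_theta(big$x3, 0)
    out <- missingness_params("covariate_only", target_rate,
                              theta_cont = c(tc, 0), theta_bin = c(tb, 0))
  } else {
    if (is.null(theta2)) {
      ## equal-association default: per-SD effect of the other outcome
      ## matches the covariate's per-SD effect
      t1c <- solve_theta(big$x1, 0)[2]
      t1b <- solve_theta(big$x3, 0)[2]
      theta2 <- c(t1c / sd(big$y_bin), t1b / sd(big$y_cont))
    }
    tc <- solve_theta(big$x1, theta2[1] * big$y_bin)
    tb <- solve_theta(big$x3, theta2[2] * big$y_cont)
    out <- missingness_params("outcome_dependent", target_rate,
                              theta_cont = c(tc, theta2[1]),
                              theta_bin = c(tb, theta2[2]))
  }

  ## verify on the calibration table
  pc <- with(big, plogis(out$theta_cont[1] + out$theta_cont[2] * x1 +
                           out$theta_cont[3] * y_bin))
  pb <- with(big, plogis(out$theta_bin[1] + out$theta_bin[2] * x3 +
                           out$theta_bin[3] * y_cont))
  if (abs(mean(pc) - target_rate) > 0.01 || abs(mean(pb) - target_rate) > 0.01) {
    abort("calibration failed to reach the target rate within 0.01.")
  }
  out
}

#' Default (cached) missingness parameters for the reference scenarios
#'
#' Returns pre-calibrated coefficients for the scenario grid, read from the
#' versioned fixtures file shipped with the package, avoiding the
#' large-sample calibration at run time.
#'
#' @param mechanism Missingness mechanism.
#' @param target_rate 0.2 or 0.5.
#' @param n_studies Needed for `"systematic_binary"` to size the number of
#'   fully missing studies (round(target_rate * n_studies)).
#' @return A [missingness_params()] object.
#' @export
default_missingness <- function(mechanism = c("covariate_only",
                                              "outcome_dependent",
                                              "systematic_binary"),
                                target_rate, n_studies = NULL) {
  mechanism <- match.arg(mechanism)
  cache_path <- system.file("extdata", "theta_defaults.json",
                            package = "ipdmix")
  cache <- jsonlite::read_json(cache_path, simplifyVector = TRUE)
  if (mechanism == "systematic_binary") {
    if (is.null(n_studies)) {
      abort("`n_studies` is required for the systematic mechanism.")
    }
    ## sporadic 20% for the continuous outcome, whole studies for the binary
    key <- "covariate_only_0.2"
    entry <- cache[[key]]
    return(missingness_params(
      "systematic_binary", target_rate,
      theta_cont = entry$theta_cont,
      theta_bin = c(0, 0, 0),
      n_systematic_studies = as.integer(round(target_rate * n_studies))
    ))
  }
  key <- paste0(mechanism, "_", format(target_rate))
  entry <- cache[[key]]
  if (is.null(entry)) {
    abort(paste0("no cached calibration for '", key,
                 "'; run calibrate_theta() directly."))
  }
  missingness_params(mechanism, target_rate,
                     theta_cont = entry$theta_cont,
                     theta_bin = entry$theta_bin)
}
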