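#' Fit the substantive bivariate random-intercept model
#'
#' Fits the analysis model — a normal linear margin for `y_cont` and a
#' probit margin for `y_bin`, with study random intercepts and correlated
#' individual-level residuals — to a complete (or completed) table by
#' running the joint Gibbs sampler with no missing-data steps active. The
#' posterior mean of the two treatment effects serves as the point estimate
#' and the posterior covariance as its covariance matrix, the pairing used
#' by Rubin's rules downstream.
#'
#' @param data A complete IPD tibble (no missing outcome entries).
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param keep_draws Keep the full posterior draws in the returned object.
#' @return An object of class `substantive_fit` with elements `theta_hat`
#'   (continuous and probit-scale binary treatment effects), `V_hat` (2x2
#'   posterior covariance) and convergence diagnostics.
#' @export
fit_substantive <- function(data, priors = prior_spec(),
                            mcmc = mcmc_config(n_iter = 2000, n_burn = 1000,
                                               n_chains = 1),
                            keep_draws = FALSE) {
  check_ipd(data, require_complete = TRUE)
  if (length(unique(data$study_id)) < 2) {
    abort("at least 2 studies are needed to identify the random intercepts.")
  }
  if (length(unique(data$treatment)) < 2) {
    abort("treatment does not vary; treatment effects are unidentifiable.")
  }
  fit <- fit_joint(data, priors = priors, mcmc = mcmc)
  te <- treatment_effects(fit)
  structure(
    list(theta_hat = te$theta, V_hat = te$V,
         sign_violations = fit$sign_violations,
         max_rhat = if (mcmc$n_chains >= 2) max(gelman_rubin(fit)$rhat)
                    else NA_real_,
         n = nrow(data), n_studies = length(unique(data$study_id)),
         draws = if (keep_draws) fit$draws else NULL),
    class = "substantive_fit"
  )
}

#' @export
print.substantive_fit <- function(x, ...) {
  cat("Substantive bivariate random-intercept fit\n")
  cat(sprintf("  n = %d in %d studies\n", x$n, x$n_studies))
  cat(sprintf("  treatment effects: cont %.3f (SE %.3f), bin (probit) %.3f (SE %.3f)\n",
              x$theta_hat[1], sqrt(x$V_hat[1, 1]),
              x$theta_hat[2], sqrt(x$V_hat[2, 2])))
  invisible(x)
}

#' @export
tidy.substantive_fit <- function(x, ...) {
  tibble(
    term = c("treatment_cont", "treatment_bin_probit"),
    estimate = unname(x$theta_hat),
    std.error = sqrt(diag(x$V_hat))
  )
}

#' Complete-case filter
#'
#' Keeps only participants with both outcomes observed; studies that lose
#' all rows (as happens with systematically missing outcomes) are dropped
#' entirely, with a message reporting how many.
#'
#' @param data An IPD tibble.
#' @return The filtered tibble, with attribute `dropped_studies`.
#' @export
complete_case_filter <- function(data) {
  check_ipd(data)
  keep <- !is.na(data$y_cont) & !is.na(data$y_bin)
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no complete cases remain: every participant has a missing outcome.")
  }
  dropped <- setdiff(unique(data$study_id), unique(out$study_id))
  if (length(dropped) > 0) {
    message(length(dropped),
            " stud", ifelse(length(dropped) == 1, "y", "ies"),
            " lost all rows and were discarded from the complete-case set.")
  }
  attr(out, "dropped_studies") <- dropped
  out
}

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' Combines `M` completed-data estimates of the 2-vector of treatment
#' effects: the pooled estimate is the mean of the point estimates, the
#' within-imputation covariance is the mean of the per-imputation
#' covariances, the between-imputation covariance is the sample covariance
#' of the point estimates, and the total covariance is
#' `T = W + (1 + 1/M) B`.
#'
#' @param estimates A list of `substantive_fit` objects (or of lists with
#'   elements `theta_hat` and `V_hat`).
#' @return An object of class `pooled_estimate`.
#' @examples
#' e <- list(list(theta_hat = c(1, .05), V_hat = diag(2) * .01),
#'           list(theta_hat = c(1.1, .07), V_hat = diag(2) * .01))
#' rubin_pool(e)
#' @export
rubin_pool <- function(estimates) {
  M <- length(estimates)
  if (M < 2) abort("Rubin's rules need M >= 2 estimates.")
  thetas <- t(vapply(estimates, function(e) unname(e$theta_hat),
                     numeric(2)))
  Ws <- lapply(estimates, function(e) unname(e$V_hat))
  if (!all(vapply(Ws, function(w) all(dim(w) == c(2, 2)), TRUE))) {
    abort("all estimates must carry a 2x2 covariance.")
  }
  theta_bar <- colMeans(thetas)
  W_bar <- Reduce(`+`, Ws) / M
  B <- stats::cov(thetas)
  T_total <- W_bar + (1 + 1 / M) * B
  structure(
    list(theta_bar = setNames(theta_bar, c("cont", "bin")),
         W_bar = W_bar, B = B, T_total = T_total, M = M),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over M = %d imputations\n", x$M))
  cat(sprintf("  cont %.3f (SE %.3f), bin (probit) %.3f (SE %.3f)\n",
              x$theta_bar[1], sqrt(x$T_total[1, 1]),
              x$theta_bar[2], sqrt(x$T_total[2, 2])))
  invisible(x)
}

#' @export
tidy.pooled_estimate <- function(x, ...) {
  tibble(
    term = c("treatment_cont", "treatment_bin_probit"),
    estimate = unname(x$theta_bar),
    std.error = sqrt(diag(x$T_total)),
    within = sqrt(diag(x$W_bar)),
    between = sqrt(diag(x$B))
  )
}

#' @export
glance.pooled_estimate <- function(x, ...) {
  k <- 2
  r <- (1 + 1 / x$M) * sum(diag(x$B %*% solve(x$W_bar))) / k
  tibble(m = x$M, avg_rel_increase = r)
}

#' Simultaneous confidence-region containment for a pooled estimate
#'
#' Tests whether the true effect vector lies inside the elliptical
#' simultaneous region
#' (truth - theta_bar)' T^{-1} (truth - theta_bar) <= q, with q the level
#' quantile of chi^2_2 by default, or of the small-sample F reference of
#' Rubin's multivariate pooling when `method = "rubin"`.
#'
#' @param pooled A `pooled_estimate`, or a `substantive_fit`/list with
#'   `theta_hat` and `V_hat` (single complete-data analysis).
#' @param truth Length-2 true effect vector.
#' @param level Confidence level.
#' @param method Reference distribution.
#' @return `TRUE` if contained.
#' @export
simultaneous_region_contains <- function(pooled, truth, level = 0.95,
                                         method = c("chisq", "rubin")) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  k <- 2
  if (inherits(pooled, "pooled_estimate")) {
    theta <- pooled$theta_bar
    V <- pooled$T_total
    if (method == "rubin") {
      M <- pooled$M
      r <- (1 + 1 / M) * sum(diag(pooled$B %*% solve(pooled$W_bar))) / k
      t_df <- k * (M - 1)
      w_df <- if (t_df > 4) {
        4 + (t_df - 4) * (1 + (1 - 2 / t_df) / r)^2
      } else {
        t_df * (1 + 1 / k) * (1 + 1 / r)^2 / 2
      }
      q <- k * qf(level, k, w_df)
      return(ellipse_contains(theta, V, truth, level, q = q))
    }
  } else {
    theta <- pooled$theta_hat
    V <- pooled$V_hat
  }
  ellipse_contains(theta, V, truth, level)
}
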