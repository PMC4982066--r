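#' Prior specification for the joint hierarchical model
#'
#' Priors are vague or weakly informative throughout. Regression
#' coefficients get independent normal(0, `beta_sd`^2) priors. The two
#' covariance matrices get conjugate inverse-Wishart working priors used by
#' the parameter-expanded update of the constrained individual-level
#' covariance; with `nu = 3` and an identity scale in two dimensions the
#' induced marginal prior on each correlation (rho, phi) is uniform on
#' (-1, 1).
#'
#' @param beta_sd Prior standard deviation of every regression coefficient.
#' @param nu_e,Se Inverse-Wishart degrees of freedom and scale for the
#'   individual-level covariance.
#' @param nu_u,Su Inverse-Wishart degrees of freedom and scale for the
#'   study-level covariance.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 10, nu_e = 3, Se = diag(2),
                       nu_u = 3, Su = diag(2)) {
  stopifnot(beta_sd > 0, nu_e > 1, nu_u > 1,
            all(dim(Se) == c(2, 2)), all(dim(Su) == c(2, 2)))
  structure(list(beta_sd = beta_sd, nu_e = nu_e, Se = Se,
                 nu_u = nu_u, Su = Su),
            class = "prior_spec")
}

#' MCMC run configuration
#'
#' The default is a reduced desk-scale run (5000 iterations, first half
#' burn-in, 2 chains); the reference full-length analysis uses 50 000
#' iterations per chain.
#'
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations (default: half of `n_iter`).
#' @param n_chains Number of chains.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain c uses a sub-seed derived from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000, n_burn = NULL, n_chains = 2,
                        thin = 1, seed = NULL) {
  n_burn <- n_burn %||% (n_iter %/% 2)
  if (n_iter < n_burn) abort("`n_iter` must be at least `n_burn`.")
  if (n_chains < 1 || thin < 1) abort("`n_chains` and `thin` must be >= 1.")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_config")
}

joint_param_names <- function(covariates) {
  c(paste0("beta1_", c("0", "trt", covariates)),
    paste0("beta2_", c("0", "trt", covariates)),
    "sigma1_sq", "sigma2_sq", "rho", "tau1_sq", "tau2_sq", "phi")
}

#' Fit the latent-normal joint hierarchical model by Gibbs sampling
#'
#' Estimates the bivariate random-intercept model with a normal continuous
#' margin and a probit binary margin (via a latent normal variable z, with
#' y_bin = 1 exactly when z > 0) and correlated residuals, by a blocked
#' Gibbs sampler. Missing outcome entries and all latent z values are
#' treated as unknowns and updated inside the sampler, so incomplete tables
#' (including studies whose binary outcome is entirely missing) are handled
#' in a single stage without separate imputation. The identification
#' constraint var(e2) = 1 holds exactly at every retained draw through a
#' parameter-expanded covariance update.
#'
#' @param data An IPD tibble; `NA` marks missing outcomes.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param covariates Covariate columns entering both margins.
#' @return An object of class `joint_fit` with a tibble of retained draws
#'   (`.chain`, `.iteration`, one column per monitored parameter).
#' @examples
#' d <- draw_complete_ipd(scenario_config(4, 50), seed = 1)
#' fit <- fit_joint(d, mcmc = mcmc_config(300, 150, n_chains = 1, seed = 1))
#' tidy(fit)
#' @export
fit_joint <- function(data, priors = prior_spec(), mcmc = mcmc_config(),
                      covariates = c("x1", "x2", "x3", "x4")) {
  check_ipd(data)
  studies <- sort(unique(data$study_id))
  if (length(studies) < 2) abort("at least 2 studies are required.")
  if (all(is.na(data$y_cont)) || all(is.na(data$y_bin))) {
    abort("each outcome needs at least one observed value overall.")
  }

  X <- cbind(1, data$treatment,
             as.matrix(data[, covariates, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    abort("the design matrix is rank deficient (e.g. constant treatment).")
  }
  study0 <- match(data$study_id, studies) - 1L
  miss1 <- as.integer(is.na(data$y_cont))
  miss2 <- as.integer(is.na(data$y_bin))
  y1 <- ifelse(miss1 == 1, 0, data$y_cont)
  y2 <- as.integer(ifelse(miss2 == 1, 0L, data$y_bin))

  seed <- mcmc$seed %||% sample.int(.Machine$integer.max, 1)
  nm <- joint_param_names(covariates)
  chains <- vector("list", mcmc$n_chains)
  violations <- 0
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed((seed + 104729 * (ch - 1)) %% 2147483647)
    res <- gibbs_joint_cpp(y1, y2, X, study0, length(studies),
                           miss1, miss2,
                           mcmc$n_iter, mcmc$n_burn, mcmc$thin,
                           1 / priors$beta_sd^2,
                           priors$nu_e, priors$Se, priors$nu_u, priors$Su)
    d <- as_tibble(as.data.frame(res$draws))
    names(d) <- nm
    d <- dplyr::mutate(d, .chain = ch, .iteration = dplyr::row_number(),
                       .before = 1)
    chains[[ch]] <- d
    violations <- violations + res$sign_violations
  }

  structure(
    list(draws = dplyr::bind_rows(chains),
         parameters = nm,
         n = nrow(data), n_studies = length(studies),
         covariates = covariates,
         sign_violations = violations,
         mcmc = mcmc, priors = priors),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("Latent-normal joint hierarchical model (Gibbs)\n")
  cat(sprintf("  %d participants in %d studies; %d chains x %d retained draws\n",
              x$n, x$n_studies, x$mcmc$n_chains,
              nrow(x$draws) / x$mcmc$n_chains))
  s <- tidy(x)
  print(as.data.frame(s[s$parameter %in%
                          c("beta1_trt", "beta2_trt", "sigma1_sq",
                            "rho", "tau1_sq", "tau2_sq", "phi"), ]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Posterior summaries of a joint model fit
#'
#' @param x A `joint_fit`.
#' @param ... Unused.
#' @return A tibble with posterior mean, SD and central 95% interval per
#'   monitored parameter (plus split-chain Rhat when at least two chains
#'   were run).
#' @export
tidy.joint_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(x$draws, -c(".chain", ".iteration"),
                              names_to = "parameter")
  out <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = sd(.data$value),
      conf.low = quantile(.data$value, 0.025),
      conf.high = quantile(.data$value, 0.975),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, x$parameters))
  if (x$mcmc$n_chains >= 2) {
    out <- dplyr::left_join(out, gelman_rubin(x), by = "parameter")
  }
  out
}

#' @export
glance.joint_fit <- function(x, ...) {
  tibble(
    n = x$n, n_studies = x$n_studies,
    n_chains = x$mcmc$n_chains,
    n_draws = nrow(x$draws),
    max_rhat = if (x$mcmc$n_chains >= 2) max(gelman_rubin(x)$rhat) else NA_real_,
    sign_violations = x$sign_violations
  )
}

#' Trace plot of monitored parameters
#'
#' @param object A `joint_fit`.
#' @param parameters Which parameters to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_fit <- function(object,
                               parameters = c("beta1_trt", "beta2_trt",
                                              "rho", "phi"), ...) {
  long <- object$draws |>
    dplyr::select(dplyr::all_of(c(".chain", ".iteration", parameters))) |>
    tidyr::pivot_longer(-c(".chain", ".iteration"), names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$.iteration, .data$value,
                                     colour = factor(.data$.chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL, colour = "chain")
}

## pooled posterior mean/covariance of the two treatment effects
#' Posterior treatment effects of a joint fit
#'
#' @param fit A `joint_fit`.
#' @return A list with `theta` (posterior means of the continuous and
#'   probit-scale binary treatment effects) and `V` (their 2x2 posterior
#'   covariance), pooled across chains.
#' @export
treatment_effects <- function(fit) {
  stopifnot(inherits(fit, "joint_fit"))
  m <- as.matrix(fit$draws[, c("beta1_trt", "beta2_trt")])
  list(theta = setNames(colMeans(m), c("cont", "bin")),
       V = stats::cov(m))
}
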