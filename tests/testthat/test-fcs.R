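test_that("steps are identity on complete data and validate their inputs", {
  d <- tiny_ipd(5, 60, seed = 101)
  expect_identical(impute_continuous_step(d), d)
  expect_identical(impute_binary_step(d), d)
  iset <- run_chained_equations(d, imputation_config(m = 3, seed = 1))
  expect_identical(iset$imputations[[1]], d)
  expect_identical(iset$imputations[[3]], d)

  d2 <- d
  d2$y_cont <- NA_real_
  expect_error(impute_continuous_step(d2), "no observed")
  expect_error(run_chained_equations(d2), "observed data")
})

test_that("collinear imputation predictors are reported by name", {
  d <- tiny_ipd(5, 60, seed = 102)
  d$x2 <- d$x1
  d$y_cont[1:10] <- NA
  expect_error(impute_continuous_step(d), "x2")
})

test_that("observed entries are immutable and imputations vary", {
  d <- tiny_ipd(8, 80, seed = 103)
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 104)
  iset <- run_chained_equations(
    di, imputation_config(m = 4, n_cycles = 4, variant = "fcs2", seed = 2))
  obs_c <- !is.na(di$y_cont)
  obs_b <- !is.na(di$y_bin)
  for (imp in iset$imputations) {
    expect_false(anyNA(imp$y_cont) || anyNA(imp$y_bin))
    expect_identical(imp$y_cont[obs_c], di$y_cont[obs_c])
    expect_identical(imp$y_bin[obs_b], di$y_bin[obs_b])
  }
  ## between-imputation variability is positive where data were missing
  y1 <- iset$imputations[[1]]$y_cont[!obs_c]
  y2 <- iset$imputations[[2]]$y_cont[!obs_c]
  expect_gt(mean((y1 - y2)^2), 0)
})

test_that("single-level continuous step matches the conjugate predictive", {
  ## one study, tau fixed at 0: the imputation distribution must equal the
  ## closed-form Bayesian predictive (scaled t) from the conjugate
  ## normal-inverse-chi-square formulas
  set.seed(105)
  n_obs <- 60
  d <- tibble::tibble(
    study_id = 1L, treatment = rep(0:1, length.out = n_obs + 1),
    x1 = rnorm(n_obs + 1), x2 = rnorm(n_obs + 1),
    x3 = rnorm(n_obs + 1), x4 = rnorm(n_obs + 1),
    y_bin = rbinom(n_obs + 1, 1, 0.5),
    r_cont = TRUE, r_bin = TRUE
  )
  d$y_cont <- 1 + d$treatment + 0.5 * d$x1 + rnorm(n_obs + 1)
  d$y_cont[n_obs + 1] <- NA # one row to impute, fixed target covariates

  preds <- c("treatment", "x1", "x2", "x3", "x4")
  draws <- vapply(seq_len(3000), function(i) {
    imp <- impute_continuous_step(d, preds)
    imp$y_cont[n_obs + 1]
  }, 0)

  ## oracle: y* = x*'bhat + sqrt(s2 (1 + h)) * t_{n-p}, computed directly
  X <- cbind(1, as.matrix(d[seq_len(n_obs), preds]))
  y <- d$y_cont[seq_len(n_obs)]
  XtXi <- solve(crossprod(X))
  bhat <- drop(XtXi %*% crossprod(X, y))
  rss <- sum((y - X %*% bhat)^2)
  p <- ncol(X)
  xstar <- c(1, as.numeric(d[n_obs + 1, preds]))
  h <- drop(t(xstar) %*% XtXi %*% xstar)
  set.seed(106)
  oracle <- drop(xstar %*% bhat) +
    sqrt(rss / (n_obs - p) * (1 + h)) * stats::rt(3000, df = n_obs - p)

  ks <- stats::ks.test(draws, oracle)
  expect_gt(ks$p.value, 0.01)
})

test_that("systematically missing studies are imputed at a sane prevalence", {
  d <- tiny_ipd(20, 150, seed = 107)
  mp <- default_missingness("systematic_binary", 0.2, n_studies = 20)
  ds <- impose_systematic(d, mp, seed = 108)
  masked <- unique(ds$study_id[is.na(ds$y_bin)])
  iset <- run_chained_equations(
    ds, imputation_config(m = 8, n_cycles = 3, variant = "fcs1", seed = 3))
  imputed <- unlist(lapply(iset$imputations, function(imp) {
    imp$y_bin[imp$study_id %in% masked]
  }))
  expect_false(anyNA(imputed))
  ## oracle: marginal prevalence by direct Monte-Carlo integration
  set.seed(109)
  n_or <- 2e5
  t_or <- rep(0:1, n_or / 2)
  oracle <- mean(plogis(-0.5 + 0.1 * t_or + 0.2 * rnorm(n_or) +
                          0.2 * rnorm(n_or) + rnorm(n_or)))
  expect_lt(abs(mean(imputed) - oracle), 0.06)
})

test_that("the other-outcome coefficient is detected under strong correlation", {
  d <- tiny_ipd(8, 120, rho = 0.7, seed = 110,
                params = dgp_params(rho = 0.7, phi = 0.1))
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 111)
  iset <- run_chained_equations(
    di, imputation_config(m = 3, n_cycles = 5, variant = "fcs2", seed = 4))
  expect_gt(mean(iset$trace$alpha2, na.rm = TRUE), 0.2)
  expect_gt(mean(iset$trace$alpha1, na.rm = TRUE), 0.05)
  ## fcs1 never uses the other outcome
  iset1 <- run_chained_equations(
    di, imputation_config(m = 2, n_cycles = 2, variant = "fcs1", seed = 5))
  expect_true(all(is.na(iset1$trace$alpha1)))
  expect_true(all(is.na(iset1$trace$alpha2)))
})

test_that("update order barely matters for the pooled estimate", {
  d <- tiny_ipd(8, 100, seed = 112)
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 113)
  pool_for <- function(ord) {
    iset <- run_chained_equations(
      di, imputation_config(m = 5, n_cycles = 5, variant = "fcs2", seed = 6,
                            order = ord))
    fits <- lapply(iset$imputations, fit_substantive,
                   mcmc = quick_mcmc(500, 200, seed = 7))
    rubin_pool(fits)
  }
  p1 <- pool_for("continuous_first")
  p2 <- pool_for("binary_first")
  se <- sqrt(diag(p1$T_total))
  expect_lt(max(abs(p1$theta_bar - p2$theta_bar) / se), 1.5)
})
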