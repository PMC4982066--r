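test_that("input validation catches degenerate designs", {
  d <- tiny_ipd(4, 30, seed = 71)
  expect_error(fit_joint(d[d$study_id == 1, ]), "2 studies")
  d2 <- d
  d2$y_cont <- NA_real_
  expect_error(fit_joint(d2), "observed value")
  d3 <- d
  d3$treatment <- 0L
  expect_error(fit_joint(d3), "rank deficient")
})

test_that("sampling is deterministic given the seed", {
  d <- tiny_ipd(4, 40, seed = 72)
  f1 <- fit_joint(d, mcmc = quick_mcmc(200, 100, seed = 5))
  f2 <- fit_joint(d, mcmc = quick_mcmc(200, 100, seed = 5))
  expect_identical(f1$draws, f2$draws)
})

test_that("the identification constraint and latent signs hold at every draw", {
  d <- tiny_ipd(8, 40, seed = 73)
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 74)
  f <- fit_joint(di, mcmc = quick_mcmc(800, 200, seed = 6))
  expect_true(all(f$draws$sigma2_sq == 1))
  expect_identical(f$sign_violations, 0)
  expect_true(all(is.finite(as.matrix(
    dplyr::select(f$draws, -".chain", -".iteration")))))
})

test_that("continuous-margin posterior mean matches a closed-form GLS oracle", {
  d <- tiny_ipd(10, 60, rho = 0, seed = 75)
  f <- fit_joint(d, mcmc = quick_mcmc(1500, 500, seed = 7))
  post <- colMeans(f$draws[, paste0("beta1_", c("0", "trt", "x1", "x2",
                                                "x3", "x4"))])

  ## independent oracle: closed-form GLS at the true variance components
  ## (sigma^2 = 1, tau1^2 = 1), V = I + tau^2 11' blockwise per study
  X <- cbind(1, d$treatment, d$x1, d$x2, d$x3, d$x4)
  A <- matrix(0, ncol(X), ncol(X))
  bvec <- numeric(ncol(X))
  for (j in unique(d$study_id)) {
    idx <- d$study_id == j
    Vj <- diag(sum(idx)) + 1
    Vinv <- solve(Vj)
    A <- A + t(X[idx, ]) %*% Vinv %*% X[idx, ]
    bvec <- bvec + t(X[idx, ]) %*% Vinv %*% d$y_cont[idx]
  }
  gls <- drop(solve(A, bvec))
  ## compare slopes: the intercept's posterior depends materially on the
  ## random-intercept variance uncertainty at J = 10, the slopes do not
  expect_lt(max(abs(unname(post)[-1] - gls[-1])), 0.05)
})

test_that("independence is recovered when the data carry none", {
  d <- tiny_ipd(10, 100, rho = 0, phi = 0, seed = 76,
                params = dgp_params(rho = 0, phi = 0))
  f <- fit_joint(d, mcmc = quick_mcmc(1000, 300, seed = 8))
  expect_lt(abs(mean(f$draws$rho)), 0.1)
})

test_that("the sampler handles systematically missing binary studies", {
  d <- tiny_ipd(8, 60, seed = 77)
  mp <- default_missingness("systematic_binary", 0.25, n_studies = 8)
  ds <- impose_systematic(d, mp, seed = 78)
  f <- fit_joint(ds, mcmc = quick_mcmc(500, 200, seed = 9))
  te <- treatment_effects(f)
  expect_true(all(is.finite(te$theta)) && all(is.finite(te$V)))
})

test_that("split-chain PSRF behaves like a scale-reduction factor", {
  expect_error(gelman_rubin(tibble::tibble(.chain = 1, x = rnorm(10))),
               "2 chains")
  ## chains drawn from one distribution by an independent generator
  set.seed(81)
  calm <- tibble::tibble(.chain = rep(1:2, each = 5000),
                         .iteration = rep(1:5000, 2),
                         x = rnorm(10000))
  expect_lt(gelman_rubin(calm)$rhat, 1.1)
  ## chains with means 10 SDs apart must be flagged
  split <- calm
  split$x <- split$x + ifelse(split$.chain == 1, 0, 10)
  expect_gt(gelman_rubin(split)$rhat, 2)
  ## a healthy short joint-model run stays below 1.1 on the effects
  d <- tiny_ipd(6, 50, seed = 82)
  f <- fit_joint(d, mcmc = mcmc_config(800, 400, n_chains = 2, seed = 10))
  gr <- gelman_rubin(f, parameters = c("beta1_trt", "sigma1_sq"))
  expect_true(all(gr$rhat < 1.2))
})

test_that("the elliptical credible region is calibrated", {
  ## truth at the posterior mean is always contained; a 10-SD offset never is
  set.seed(83)
  draws <- cbind(rnorm(2000), rnorm(2000, sd = 2))
  m <- colMeans(draws)
  expect_true(joint_region_contains(draws, m, level = 0.001))
  expect_false(joint_region_contains(draws, m + c(10, 0), level = 0.95))
  expect_error(joint_region_contains(cbind(rep(1, 50), rnorm(50)), c(0, 0)),
               "degenerate")

  ## simulation oracle: when the spread of the region's centre around the
  ## truth matches the spread of the draws (a calibrated posterior), the
  ## containment frequency approximates the nominal level
  set.seed(84)
  sds <- c(1, 0.5)
  hits <- vapply(seq_len(2000), function(i) {
    centre <- c(1, 0.06) + rnorm(2) * sds
    dr <- cbind(rnorm(400, centre[1], sds[1]), rnorm(400, centre[2], sds[2]))
    joint_region_contains(dr, c(1, 0.06), level = 0.9)
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.9), 0.025)
})
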