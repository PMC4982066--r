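test_that("tables have the right shape and exact treatment balance", {
  d <- draw_complete_ipd(scenario_config(20, 150, rho = 0.2, phi = 0.1),
                         seed = 1)
  expect_equal(nrow(d), 3000)
  expect_equal(sum(d$treatment), 1500)
  balance <- dplyr::count(d, study_id, treatment)
  expect_true(all(balance$n == 75))
  expect_true(all(d$y_bin %in% 0:1))
  expect_true(all(d$r_cont) && all(d$r_bin))
})

test_that("invalid parameters and configs are rejected", {
  expect_error(dgp_params(rho = 1), "rho")
  expect_error(dgp_params(phi = -1.2), "phi")
  expect_error(dgp_params(sigma1_sq = 0), "sigma1_sq")
  expect_error(dgp_params(tau_sq = c(1, -1)), "tau_sq")
  expect_error(scenario_config(0, 100), "positive")
  expect_error(draw_complete_ipd(scenario_config(5, 100, rho = 1.5)), "rho")
})

test_that("identical seed and config give bit-identical tables", {
  cfg <- scenario_config(8, 40, rho = 0.5, phi = 0.3)
  expect_identical(draw_complete_ipd(cfg, seed = 7),
                   draw_complete_ipd(cfg, seed = 7))
})

test_that("zero copula and study correlation give independent outcomes", {
  p0 <- dgp_params(beta_cont = c(1, 0, 0.5, 0.5),
                   beta_bin = c(-0.5, 0, 0.2, 0.2),
                   rho = 0, phi = 0)
  d <- draw_complete_ipd(scenario_config(10, 10000, rho = 0, phi = 0),
                         p0, seed = 3)
  ## demean within study so the study intercepts (whose handful of draws
  ## dominate the Monte-Carlo error otherwise) drop out
  mu <- 1 + 0.5 * d$x1 + 0.5 * d$x2
  resid <- d$y_cont - mu
  resid <- resid - stats::ave(resid, d$study_id)
  ybc <- d$y_bin - stats::ave(d$y_bin, d$study_id)
  expect_lt(abs(cor(resid, ybc)), 0.012)
})

test_that("control-arm prevalence matches a Monte-Carlo integration oracle", {
  ## many studies, so the random-intercept average is close to its integral
  d <- draw_complete_ipd(scenario_config(500, 1000), seed = 11)
  observed <- mean(d$y_bin[d$treatment == 0])

  ## independent oracle: direct MC average of expit(-0.5 + .2 X3 + .2 X4 + u2)
  ## over the stated distributions, with its own RNG stream
  set.seed(991)
  n_or <- 4e5
  oracle <- mean(plogis(-0.5 + 0.2 * rnorm(n_or) + 0.2 * rnorm(n_or) +
                          rnorm(n_or)))
  ## Monte-Carlo error is driven by the 500 study intercepts (~0.009)
  expect_lt(abs(observed - oracle), 0.03)
})

test_that("the copula reproduces the latent correlation and the margins", {
  params <- dgp_params(rho = 0.7, phi = 0.1)
  d <- draw_complete_ipd(scenario_config(10, 10000, rho = 0.7, phi = 0),
                         params, seed = 5, keep_latent = TRUE)
  ## latent pair correlation
  expect_lt(abs(cor(d$.z1, d$.z2) - 0.7), 0.02)
  ## the continuous margin is an exact transform of the first latent
  ## coordinate; reconstruct it from y_cont and the known mean structure
  mu <- with(d, 1 + treatment + 0.5 * x1 + 0.5 * x2)
  z1_rec <- (d$y_cont - mu) # phi = 0 still leaves u1 per study; partial out
  expect_gt(cor(z1_rec, d$.z1), 0.70)
  expect_gt(summary(lm(z1_rec ~ d$.z1 + factor(d$study_id)))$r.squared, 0.999)

  ## marginal moments of y_cont per arm: mean 1 + t, variance
  ## sigma1^2 + tau1^2 + 0.25 + 0.25 = 2.5; Monte-Carlo error is dominated
  ## by the study intercepts (SD 1/sqrt(J))
  d2 <- draw_complete_ipd(scenario_config(2000, 100), seed = 6)
  for (t in 0:1) {
    y <- d2$y_cont[d2$treatment == t]
    expect_lt(abs(mean(y) - (1 + t)), 0.07)
    expect_lt(abs(var(y) - 2.5), 0.15)
  }
})
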