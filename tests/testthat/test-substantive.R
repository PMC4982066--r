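test_that("complete-case filtering keeps exactly the doubly-observed rows", {
  d <- tiny_ipd(5, 20, seed = 121)
  expect_identical(nrow(complete_case_filter(d)), nrow(d))

  ## known pattern on a 100-row fixture: exhaustive count oracle
  d2 <- d
  d2$y_cont[1:30] <- NA
  d2$y_bin[21:50] <- NA
  cc <- complete_case_filter(d2)
  expect_identical(nrow(cc), 50L)
  expect_true(all(!is.na(cc$y_cont) & !is.na(cc$y_bin)))

  ## systematically missing studies disappear altogether, with a message
  d3 <- tiny_ipd(20, 30, seed = 122)
  mp <- default_missingness("systematic_binary", 0.2, n_studies = 20)
  ds <- impose_systematic(d3, mp, seed = 123)
  expect_message(cc3 <- complete_case_filter(ds), "discarded")
  masked <- unique(ds$study_id[is.na(ds$y_bin)])
  expect_length(intersect(unique(cc3$study_id), masked), 0)
  expect_setequal(attr(cc3, "dropped_studies"), masked)

  d4 <- d
  d4$y_cont <- NA_real_
  expect_error(complete_case_filter(d4), "complete cases")
})

test_that("Rubin pooling follows the closed-form rules", {
  ## hand-specified M = 3 oracle
  est <- list(
    list(theta_hat = c(1, 0), V_hat = diag(2)),
    list(theta_hat = c(2, 1), V_hat = diag(2)),
    list(theta_hat = c(3, 2), V_hat = diag(2))
  )
  p <- rubin_pool(est)
  expect_equal(unname(p$theta_bar), c(2, 1))
  expect_equal(p$W_bar, diag(2))
  expect_equal(p$B, matrix(1, 2, 2))
  expect_equal(p$T_total, diag(2) + (1 + 1 / 3) * matrix(1, 2, 2))

  ## identical estimates: no between-imputation variance
  same <- rubin_pool(est[c(1, 1)])
  expect_equal(same$B, matrix(0, 2, 2))
  expect_equal(same$T_total, same$W_bar)

  expect_error(rubin_pool(est[1]), "M >= 2")
})

test_that("total variance dominates within variance on a real run", {
  d <- tiny_ipd(6, 80, seed = 124)
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 125)
  iset <- run_chained_equations(
    di, imputation_config(m = 5, n_cycles = 3, variant = "fcs1", seed = 8))
  fits <- lapply(iset$imputations, fit_substantive,
                 mcmc = quick_mcmc(400, 150, seed = 9))
  p <- rubin_pool(fits)
  ## T - W = (1 + 1/M) B exactly, and is positive semi-definite
  expect_equal(p$T_total - p$W_bar, (1 + 1 / p$M) * p$B)
  expect_true(all(eigen(p$T_total - p$W_bar)$values > -1e-12))
  expect_gt(sum(diag(p$B)), 0)
})

test_that("simultaneous regions contain their centre and reject far points", {
  p <- rubin_pool(list(
    list(theta_hat = c(1, 0.05), V_hat = diag(2) * 0.01),
    list(theta_hat = c(1.1, 0.07), V_hat = diag(2) * 0.01)
  ))
  expect_true(simultaneous_region_contains(p, p$theta_bar))
  expect_false(simultaneous_region_contains(
    list(theta_hat = c(0, 0), V_hat = diag(2)), c(10, 0)))
  expect_true(simultaneous_region_contains(p, p$theta_bar,
                                           method = "rubin"))
  bad <- p
  bad$T_total <- matrix(0, 2, 2)
  expect_error(simultaneous_region_contains(bad, c(0, 0)), "degenerate")
})

test_that("substantive fitting validates its inputs", {
  d <- tiny_ipd(4, 30, seed = 126)
  d$y_cont[1] <- NA
  expect_error(fit_substantive(d), "complete")
  d2 <- tiny_ipd(4, 30, seed = 127)
  d2$treatment <- 1L
  expect_error(fit_substantive(d2), "unidentifiable")
  expect_error(fit_substantive(tiny_ipd(4, 30, seed = 128)[1:30, ]),
               "2 studies")
})

test_that("the probit treatment effect is about 0.6 times the logit one", {
  d <- tiny_ipd(10, 2000, seed = 129)
  f <- fit_substantive(d, mcmc = quick_mcmc(900, 300, seed = 11))
  logit_fit <- stats::glm(y_bin ~ treatment + x3 + x4 + factor(study_id),
                          family = stats::binomial(), data = d)
  bridge <- 0.6 * coef(logit_fit)[["treatment"]]
  expect_lt(abs(f$theta_hat[2] - bridge), 0.03)
})
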