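test_that("covariate-only masking matches its probabilities and flags", {
  d <- tiny_ipd(10, 1000, seed = 51)
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 52)
  expect_lt(abs(mean(is.na(di$y_cont)) - 0.2), 0.02)
  expect_lt(abs(mean(is.na(di$y_bin)) - 0.2), 0.02)
  expect_identical(di$r_cont, !is.na(di$y_cont))
  expect_identical(di$r_bin, !is.na(di$y_bin))
  ## observed entries are untouched
  expect_identical(di$y_cont[!is.na(di$y_cont)],
                   d$y_cont[!is.na(di$y_cont)])
})

test_that("an effectively -Inf intercept leaves the table untouched", {
  d <- tiny_ipd(5, 100, seed = 53)
  mp <- missingness_params("covariate_only", target_rate = 0.2,
                           theta_cont = c(-50, 0, 0),
                           theta_bin = c(-50, 0, 0))
  di <- impose_sporadic_mar(d, mp, seed = 54)
  expect_identical(di, d)
})

test_that("outcome-dependent masking is MAR by construction", {
  d <- tiny_ipd(10, 500, seed = 55)
  mp <- default_missingness("outcome_dependent", 0.5)
  di <- impose_sporadic_mar(d, mp, seed = 56)
  ## exhaustive scan: the split-sample construction never masks both
  ## outcomes of one participant, so the probability of each missing entry
  ## depended only on quantities still observed in that row
  expect_identical(sum(is.na(di$y_cont) & is.na(di$y_bin)), 0L)
  expect_gt(sum(is.na(di$y_cont)), 0)
  expect_gt(sum(is.na(di$y_bin)), 0)
})

test_that("mechanism routing is enforced", {
  d <- tiny_ipd(5, 40, seed = 57)
  mp_sys <- missingness_params("systematic_binary", 0.2,
                               n_systematic_studies = 1)
  expect_error(impose_sporadic_mar(d, mp_sys), "impose_systematic")
  expect_error(impose_systematic(d, mp_cov20()), "systematic_binary")
  expect_error(missingness_params("covariate_only", 0.2,
                                  theta_cont = c(0, 1, 1)), "theta2")
  di <- impose_sporadic_mar(d, mp_cov20(), seed = 58)
  expect_error(impose_sporadic_mar(di, mp_cov20()), "complete")
})

test_that("systematic masking hits whole studies and the overall rate", {
  d <- tiny_ipd(20, 150, seed = 59)
  for (rate in c(0.2, 0.5)) {
    mp <- default_missingness("systematic_binary", rate, n_studies = 20)
    expect_identical(mp$n_systematic_studies, as.integer(20 * rate))
    ds <- impose_systematic(d, mp, seed = 60)
    masked <- unique(ds$study_id[is.na(ds$y_bin)])
    expect_length(masked, 20 * rate)
    ## within selected studies nothing observed, elsewhere fully observed
    expect_true(all(is.na(ds$y_bin[ds$study_id %in% masked])))
    expect_false(anyNA(ds$y_bin[!ds$study_id %in% masked]))
    expect_lt(abs(mean(is.na(ds$y_bin)) - rate), 1e-9)
  }
  mp_bad <- missingness_params("systematic_binary", 0.99,
                               n_systematic_studies = 20)
  expect_error(impose_systematic(d, mp_bad), "at least one study")
})

test_that("masking is deterministic given the seed", {
  d <- tiny_ipd(6, 200, seed = 61)
  expect_identical(impose_sporadic_mar(d, mp_cov20(), seed = 62),
                   impose_sporadic_mar(d, mp_cov20(), seed = 62))
})
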