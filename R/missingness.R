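#' Impose sporadic missing-at-random outcomes
#'
#' Applies the logistic missingness models to a complete table. Under the
#' covariate-only mechanism each outcome k is set missing independently with
#' probability expit(theta0 + theta1 * x_k). Under the outcome-dependent
#' mechanism the table is first randomly split into two halves: in half A
#' only `y_cont` can be missing (probability depending on x1 and the
#' observed `y_bin`), in half B only `y_bin` can be missing (probability
#' depending on x3 and the observed `y_cont`). The split guarantees that the
#' missingness probability of every entry depends only on quantities that
#' remain observed in that row, so the mechanism is missing-at-random by
#' construction, and no row loses both outcomes.
#'
#' @param data A complete IPD tibble (see [draw_complete_ipd()]).
#' @param mp A [missingness_params()] with mechanism `"covariate_only"` or
#'   `"outcome_dependent"`.
#' @param seed Optional integer seed.
#' @return The table with `NA` in masked outcome entries and `r_cont`,
#'   `r_bin` updated.
#' @export
impose_sporadic_mar <- function(data, mp, seed = NULL) {
  check_ipd(data, require_complete = TRUE)
  if (!inherits(mp, "missingness_params")) {
    abort("`mp` must be created by missingness_params().")
  }
  if (mp$mechanism == "systematic_binary") {
    abort("systematic mechanisms must go through impose_systematic().")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)

  if (mp$mechanism == "covariate_only") {
    p_cont <- plogis(mp$theta_cont[1] + mp$theta_cont[2] * data$x1)
    p_bin <- plogis(mp$theta_bin[1] + mp$theta_bin[2] * data$x3)
    m_cont <- runif(n) < p_cont
    m_bin <- runif(n) < p_bin
  } else {
    half <- sample(rep(c(1L, 2L), length.out = n))
    p_cont <- plogis(mp$theta_cont[1] + mp$theta_cont[2] * data$x1 +
                       mp$theta_cont[3] * data$y_bin)
    p_bin <- plogis(mp$theta_bin[1] + mp$theta_bin[2] * data$x3 +
                      mp$theta_bin[3] * data$y_cont)
    m_cont <- half == 1L & runif(n) < p_cont
    m_bin <- half == 2L & runif(n) < p_bin
  }

  data$y_cont[m_cont] <- NA_real_
  data$y_bin[m_bin] <- NA_integer_
  sync_r_flags(data)
}

#' Impose systematically missing binary outcomes
#'
#' First applies sporadic covariate-only missingness to the continuous
#' outcome (at the rate encoded in `mp$theta_cont`, 20% in the reference
#' scenarios), then sets `y_bin` missing for every participant of
#' `n_systematic_studies` randomly chosen studies, emulating trials that did
#' not collect the outcome at all.
#'
#' @inheritParams impose_sporadic_mar
#' @param mp A [missingness_params()] with mechanism `"systematic_binary"`.
#' @return The masked table.
#' @export
impose_systematic <- function(data, mp, seed = NULL) {
  check_ipd(data, require_complete = TRUE)
  if (!inherits(mp, "missingness_params") ||
      mp$mechanism != "systematic_binary") {
    abort("`mp` must be a missingness_params() with mechanism 'systematic_binary'.")
  }
  studies <- unique(data$study_id)
  if (mp$n_systematic_studies >= length(studies)) {
    abort("at least one study must observe the binary outcome.")
  }
  if (!is.null(seed)) set.seed(seed)

  p_cont <- plogis(mp$theta_cont[1] + mp$theta_cont[2] * data$x1)
  data$y_cont[runif(nrow(data)) < p_cont] <- NA_real_

  drop <- sample(studies, mp$n_systematic_studies)
  data$y_bin[data$study_id %in% drop] <- NA_integer_
  sync_r_flags(data)
}
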