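#' Gelman-Rubin convergence diagnostic
#'
#' Computes the split-chain potential scale reduction factor (PSRF) per
#' monitored parameter: each chain is split in half, and Rhat is the square
#' root of the ratio of the pooled-variance estimate to the mean
#' within-chain variance. Values below 1.1 are conventionally taken as
#' convergence.
#'
#' @param x A `joint_fit`, or a data frame of draws with a `.chain` column.
#' @param parameters Optional subset of parameter names.
#' @return A tibble with columns `parameter` and `rhat`.
#' @export
gelman_rubin <- function(x, parameters = NULL) {
  draws <- if (inherits(x, "joint_fit")) x$draws else as_tibble(x)
  if (!".chain" %in% names(draws)) {
    abort("draws must carry a `.chain` column.")
  }
  if (length(unique(draws$.chain)) < 2) {
    abort("at least 2 chains are required for the Gelman-Rubin diagnostic.")
  }
  params <- parameters %||%
    setdiff(names(draws), c(".chain", ".iteration"))

  split_rhat <- function(v, chain) {
    pieces <- unlist(lapply(split(v, chain), function(vc) {
      h <- length(vc) %/% 2
      list(vc[seq_len(h)], vc[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(pieces)
    n <- length(pieces[[1]])
    means <- vapply(pieces, mean, 0)
    vars <- vapply(pieces, var, 0)
    W <- mean(vars)
    B_over_n <- var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }

  tibble(
    parameter = params,
    rhat = vapply(params, function(p) {
      split_rhat(draws[[p]], draws$.chain)
    }, 0)
  )
}

## shared elliptical containment check on a (mean, covariance) pair
ellipse_contains <- function(theta, V, truth, level, q = NULL) {
  if (!all(is.finite(V)) || det(V) <= 0 ||
      any(diag(V) <= .Machine$double.eps)) {
    abort("degenerate covariance: the region is not defined.")
  }
  d <- truth - theta
  stat <- drop(t(d) %*% solve(V, d))
  stat <= (q %||% qchisq(level, df = length(theta)))
}

#' Joint credible-region containment for a full-Bayes fit
#'
#' Forms an elliptical empirical credible region for the 2-vector of
#' treatment effects from the pooled posterior draws (posterior mean m and
#' covariance S) and reports whether
#' (truth - m)' S^{-1} (truth - m) <= chi^2_2(level).
#'
#' @param fit A `joint_fit`, or a 2-column matrix of posterior draws of the
#'   treatment effects.
#' @param truth Length-2 vector of true effects (continuous, probit binary).
#' @param level Credible level in (0, 1).
#' @return `TRUE` if the truth lies inside the region.
#' @export
joint_region_contains <- function(fit, truth, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  if (inherits(fit, "joint_fit")) {
    te <- treatment_effects(fit)
    theta <- te$theta; V <- te$V
  } else {
    m <- as.matrix(fit)
    if (ncol(m) != 2) abort("expected a 2-column matrix of draws.")
    theta <- colMeans(m); V <- stats::cov(m)
  }
  ellipse_contains(theta, V, truth, level)
}
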