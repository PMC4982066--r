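## coerce replicate estimates to an n x 2 matrix
as_estimate_matrix <- function(estimates) {
  if (is.matrix(estimates)) {
    m <- estimates
  } else if (is.data.frame(estimates)) {
    m <- as.matrix(estimates)
  } else if (is.list(estimates)) {
    m <- do.call(rbind, lapply(estimates, as.numeric))
  } else {
    m <- matrix(estimates, nrow = 1)
  }
  if (ncol(m) != 2) abort("expected 2-vector estimates (one per outcome).")
  m
}

#' Percent bias of replicate estimates
#'
#' Absolute relative bias of the mean estimate per outcome:
#' 100 * |mean(est) - truth| / |truth|. The signed version is attached as
#' attribute `signed` for diagnostics.
#'
#' @param estimates Replicate estimates: an n x 2 matrix, data frame, or
#'   list of 2-vectors (continuous effect, probit-scale binary effect).
#' @param truth Length-2 true values (must be nonzero).
#' @return Length-2 named vector of percentages.
#' @examples
#' percent_bias(rbind(c(1.071, 0.06)), c(1, 0.06))
#' @export
percent_bias <- function(estimates, truth) {
  m <- as_estimate_matrix(estimates)
  if (any(truth == 0)) abort("percent bias is undefined for zero truth.")
  signed <- 100 * (colMeans(m) - truth) / abs(truth)
  out <- setNames(abs(signed), c("cont", "bin"))
  attr(out, "signed") <- setNames(signed, c("cont", "bin"))
  out
}

#' Root mean squared error of replicate estimates
#'
#' @inheritParams percent_bias
#' @return Length-2 named vector: sqrt(mean((est - truth)^2)) per outcome.
#' @export
rmse <- function(estimates, truth) {
  m <- as_estimate_matrix(estimates)
  if (nrow(m) < 2) abort("rmse needs at least 2 replicate estimates.")
  setNames(sqrt(colMeans(sweep(m, 2, truth)^2)), c("cont", "bin"))
}

#' Joint coverage from containment flags
#'
#' @param flags Logical vector: per replicate, whether the joint region
#'   contained the truth.
#' @return The coverage proportion, with the binomial Monte-Carlo standard
#'   error as attribute `mc_se` and the replicate count as attribute `n`.
#' @export
joint_coverage <- function(flags) {
  flags <- as.logical(flags)
  if (length(flags) == 0 || anyNA(flags)) {
    abort("`flags` must be a non-empty logical vector without NA.")
  }
  p <- mean(flags)
  structure(p, mc_se = sqrt(p * (1 - p) / length(flags)),
            n = length(flags))
}
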