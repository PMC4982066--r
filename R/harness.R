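#' Per-replicate seed derivation
#'
#' Counter-based splitting rule: replicate r of master seed s uses
#' (s + 1000003 * r) mod 2147483647, so results are reproducible for a
#' fixed seed assignment regardless of execution order or parallelism.
#'
#' @param master Master integer seed.
#' @param r Replicate index (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(master, r) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(r)) %% 2147483647)
}

## default fitting settings for replicate-scale runs: single chain, short
## warmup; the posterior at n = 3000 is tight and stabilises quickly
harness_mcmc_defaults <- function() {
  list(
    direct = mcmc_config(n_iter = 1200, n_burn = 400, n_chains = 1),
    completed = mcmc_config(n_iter = 700, n_burn = 250, n_chains = 1)
  )
}

#' Run one simulation scenario
#'
#' Executes the full replicate loop for one cell of the simulation grid:
#' per replicate, a complete table is drawn, the full-data analysis is
#' recorded, the scenario's missingness mechanism is imposed, and each
#' requested method is applied — complete-case analysis (`"cca"`),
#' chained-equations multiple imputation without and with the other outcome
#' in the imputation model (`"fcs1"`, `"fcs2"`; Rubin-pooled), and the
#' one-stage full-Bayes joint model on the incomplete data (`"joint"`).
#' Each method yields the 2-vector of treatment effects and a flag for
#' whether its 95% joint (credible or simultaneous) elliptical region
#' contains the truth. Metrics aggregate over replicates.
#'
#' @param config A [scenario_config()]; its `missingness` element defines
#'   the mechanism (may be `NULL` when only `"full_data"` is run).
#' @param n_reps Number of replicates.
#' @param methods Subset of `c("full_data", "cca", "fcs1", "fcs2",
#'   "joint")`.
#' @param params A [dgp_params()].
#' @param truth True treatment effects (continuous scale, probit scale).
#' @param seed Master seed; replicate sub-seeds are derived by
#'   [replicate_seed()].
#' @param m Imputations per FCS method.
#' @param n_cycles Chained-equation cycles.
#' @param mcmc_direct MCMC settings for full-data/CCA/joint fits.
#' @param mcmc_completed MCMC settings for per-imputation substantive fits.
#' @param level Nominal joint coverage level.
#' @param verbose Print a progress line every 25 replicates.
#' @return An object of class `scenario_result` with elements `metrics`
#'   (long tibble: method, outcome, metric, value, mc_se), `replicates`
#'   (one row per replicate x method) and the settings used. Replicates
#'   that fail are logged and skipped; the run errors if more than 1% fail.
#' @export
run_scenario <- function(config, n_reps, methods = c("full_data", "cca",
                                                     "fcs1", "fcs2",
                                                     "joint"),
                         params = dgp_params(),
                         truth = c(1, 0.06),
                         seed = 1L,
                         m = 10, n_cycles = 10,
                         mcmc_direct = NULL, mcmc_completed = NULL,
                         level = 0.95, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  bad <- setdiff(methods, c("full_data", "cca", "fcs1", "fcs2", "joint"))
  if (length(bad) > 0) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  }
  defaults <- harness_mcmc_defaults()
  mcmc_direct <- mcmc_direct %||% defaults$direct
  mcmc_completed <- mcmc_completed %||% defaults$completed
  needs_missing <- length(setdiff(methods, "full_data")) > 0
  if (needs_missing && is.null(config$missingness)) {
    abort("`config$missingness` is required for methods other than 'full_data'.")
  }

  if (length(methods) == 0) {
    return(structure(list(metrics = tibble(), replicates = tibble(),
                          config = config, n_reps = 0L, errors = 0L),
                     class = "scenario_result"))
  }

  one_method <- function(method, complete, incomplete, rep_seed) {
    if (method == "full_data") {
      f <- fit_substantive(complete, mcmc = mcmc_direct)
      theta <- f$theta_hat
      contained <- simultaneous_region_contains(f, truth, level)
    } else if (method == "cca") {
      f <- suppressMessages(
        fit_substantive(complete_case_filter(incomplete),
                        mcmc = mcmc_direct))
      theta <- f$theta_hat
      contained <- simultaneous_region_contains(f, truth, level)
    } else if (method %in% c("fcs1", "fcs2")) {
      variant <- ifelse(method == "fcs1", "fcs1", "fcs2")
      iset <- run_chained_equations(
        incomplete,
        imputation_config(m = m, n_cycles = n_cycles, variant = variant,
                          seed = rep_seed))
      fits <- lapply(iset$imputations, fit_substantive,
                     mcmc = mcmc_completed)
      pooled <- rubin_pool(fits)
      theta <- pooled$theta_bar
      contained <- simultaneous_region_contains(pooled, truth, level)
    } else { # joint
      f <- fit_joint(incomplete, mcmc = mcmc_direct)
      te <- treatment_effects(f)
      theta <- te$theta
      contained <- joint_region_contains(f, truth, level)
    }
    tibble(method = method,
           theta_cont = unname(theta[1]), theta_bin = unname(theta[2]),
           contained = contained)
  }

  rows <- list()
  n_err <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- replicate_seed(seed, r)
    res <- tryCatch({
      set.seed(rep_seed)
      complete <- draw_complete_ipd(config, params, seed = rep_seed)
      incomplete <- NULL
      if (needs_missing) {
        mp <- config$missingness
        incomplete <- if (mp$mechanism == "systematic_binary") {
          impose_systematic(complete, mp)
        } else {
          impose_sporadic_mar(complete, mp)
        }
      }
      ## method fits consume the replicate RNG stream sequentially; the
      ## chained-equations seed is re-derived so fcs1/fcs2 see the same data
      dplyr::bind_rows(lapply(methods, one_method,
                              complete = complete,
                              incomplete = incomplete,
                              rep_seed = rep_seed)) |>
        dplyr::mutate(replicate = r, seed = rep_seed)
    }, error = function(e) {
      warn(paste0("replicate ", r, " failed: ", conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_err <- n_err + 1L else rows[[length(rows) + 1]] <- res
    if (verbose && r %% 25 == 0) {
      message("  replicate ", r, "/", n_reps)
    }
  }
  if (n_err > max(1, 0.01 * n_reps)) {
    abort(paste0("scenario failed: ", n_err, " of ", n_reps,
                 " replicates errored."))
  }
  replicates <- dplyr::bind_rows(rows)

  metrics <- replicates |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      est <- cbind(d$theta_cont, d$theta_bin)
      pb <- percent_bias(est, truth)
      pbs <- attr(pb, "signed")
      rm <- rmse(est, truth)
      cov <- joint_coverage(d$contained)
      n <- nrow(d)
      dplyr::bind_rows(
        tibble(outcome = c("cont", "bin"), metric = "percent_bias",
               value = unname(pb), signed = unname(pbs),
               mc_se = 100 * apply(est, 2, sd) / sqrt(n) / abs(truth)),
        tibble(outcome = c("cont", "bin"), metric = "rmse",
               value = unname(rm), signed = NA_real_,
               mc_se = unname(rm) / sqrt(2 * n)),
        tibble(outcome = "joint", metric = "coverage",
               value = as.numeric(cov), signed = NA_real_,
               mc_se = attr(cov, "mc_se"))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_replicates = n_reps - n_err)

  structure(
    list(metrics = metrics, replicates = replicates, config = config,
         truth = truth, n_reps = n_reps, errors = n_err,
         seed = seed, level = level),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario result: %d studies x %d, rho = %.2f, phi = %.2f, %d replicates (%d errors)\n",
              x$config$n_studies, x$config$n_per_study, x$config$rho,
              x$config$phi, x$n_reps, x$errors))
  print(report_table(x), n = Inf)
  invisible(x)
}

#' Results-table layout of a scenario result
#'
#' One row per method with percent bias and rMSE per outcome and the joint
#' coverage, mirroring the usual presentation of simulation studies of this
#' design.
#'
#' @param result A `scenario_result`.
#' @return A wide tibble.
#' @export
report_table <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  m <- result$metrics
  wide <- m |>
    dplyr::mutate(col = dplyr::case_when(
      .data$metric == "percent_bias" & .data$outcome == "cont" ~ "bias_cont",
      .data$metric == "percent_bias" & .data$outcome == "bin" ~ "bias_bin",
      .data$metric == "rmse" & .data$outcome == "cont" ~ "rmse_cont",
      .data$metric == "rmse" & .data$outcome == "bin" ~ "rmse_bin",
      TRUE ~ "coverage"
    )) |>
    dplyr::select("method", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  method_order <- c("full_data", "cca", "fcs1", "fcs2", "joint")
  wide[order(match(wide$method, method_order)), ]
}

#' Plot scenario metrics by method
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object: one panel per metric/outcome, methods on the
#'   x-axis, with the nominal coverage level marked.
#' @export
autoplot.scenario_result <- function(object, ...) {
  m <- object$metrics |>
    dplyr::mutate(panel = paste(.data$metric, .data$outcome))
  ggplot2::ggplot(m, ggplot2::aes(.data$method, .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$mc_se,
                                        ymax = .data$value + .data$mc_se),
                           width = 0.2) +
    ggplot2::geom_hline(
      data = data.frame(panel = "coverage joint", y = object$level),
      ggplot2::aes(yintercept = .data$y), linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
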