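#' Write an IPD table to CSV
#'
#' Writes the participant table with header columns `study_id`, `treatment`,
#' `x1`..`x4`, `y_cont`, `y_bin`, using empty fields for missing outcome
#' values. When `meta` is supplied, a sidecar `<path>.meta.json` records it
#' (e.g. the RNG seed and scenario settings).
#'
#' @param data An IPD tibble.
#' @param path Output CSV path.
#' @param meta Optional named list written to the sidecar metadata file.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(data, path, meta = NULL) {
  check_ipd(data)
  out <- data[, c("study_id", "treatment", "x1", "x2", "x3", "x4",
                  "y_cont", "y_bin")]
  readr::write_csv(out, path, na = "")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read an IPD table from CSV
#'
#' @param path CSV path produced by [write_ipd()] (empty fields are read as
#'   missing outcomes).
#' @return An IPD tibble with `r_cont`/`r_bin` observedness flags.
#' @export
read_ipd <- function(path) {
  d <- readr::read_csv(path, na = "", show_col_types = FALSE,
                       col_types = readr::cols(
                         study_id = readr::col_integer(),
                         treatment = readr::col_integer(),
                         y_bin = readr::col_integer(),
                         .default = readr::col_double()
                       ))
  sync_r_flags(check_ipd(as_tibble(d)))
}

#' Read a scenario configuration from YAML
#'
#' Expected keys: `n_studies`, `n_per_study`, `rho`, `phi`, `seed`
#' (optional) and an optional `missingness` block with `mechanism`,
#' `target_rate`, `theta_cont`, `theta_bin`, `n_systematic_studies`.
#'
#' @param path YAML file path.
#' @return A [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mp <- NULL
  if (!is.null(y$missingness)) {
    mp <- missingness_params(
      mechanism = y$missingness$mechanism,
      target_rate = y$missingness$target_rate,
      theta_cont = unlist(y$missingness$theta_cont %||% c(0, 0, 0)),
      theta_bin = unlist(y$missingness$theta_bin %||% c(0, 0, 0)),
      n_systematic_studies = y$missingness$n_systematic_studies
    )
  }
  scenario_config(y$n_studies, y$n_per_study, rho = y$rho, phi = y$phi,
                  missingness = mp, seed = y$seed)
}

#' Write a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  y <- list(n_studies = config$n_studies, n_per_study = config$n_per_study,
            rho = config$rho, phi = config$phi, seed = config$seed)
  if (!is.null(config$missingness)) {
    mp <- config$missingness
    y$missingness <- list(mechanism = mp$mechanism,
                          target_rate = mp$target_rate,
                          theta_cont = mp$theta_cont,
                          theta_bin = mp$theta_bin,
                          n_systematic_studies = mp$n_systematic_studies)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export posterior draws to CSV
#'
#' One column per monitored parameter plus chain and iteration columns, for
#' inspection with standard MCMC tooling.
#'
#' @param fit A `joint_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "joint_fit"))
  readr::write_csv(fit$draws, path)
  invisible(path)
}
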