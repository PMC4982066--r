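# small fixtures and shared settings, built in code at test time

tiny_ipd <- function(n_studies = 6, n_per_study = 50, rho = 0.2, phi = 0.1,
                     seed = 1, params = dgp_params(rho = rho, phi = phi)) {
  draw_complete_ipd(scenario_config(n_studies, n_per_study,
                                    rho = rho, phi = phi),
                    params, seed = seed)
}

quick_mcmc <- function(n_iter = 600, n_burn = 200, n_chains = 1, seed = 1) {
  mcmc_config(n_iter, n_burn, n_chains = n_chains, seed = seed)
}

# fixed 20% covariate-only thetas (cached calibration)
mp_cov20 <- function() default_missingness("covariate_only", 0.2)
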