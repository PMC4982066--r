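# ipdmix

Joint models and multilevel multiple imputation for incomplete mixed
outcomes in individual-participant-data (IPD) meta-analysis.

## The problem

IPD meta-analyses of randomised trials typically want treatment effects on
several correlated endpoints — here one continuous outcome
*y*<sub>1,*ij*</sub> and one binary outcome *y*<sub>2,*ij*</sub> per
participant *i* in study *j* — and those endpoints are incomplete:
sporadically missing within trials, or systematically missing when a trial
never collected an outcome. `ipdmix` implements, for biostatisticians
working with such data, two principled analysis routes plus the
complete-case baseline, and a copula-based simulation framework for
measuring their bias, rMSE and joint coverage.

**The latent-normal joint hierarchical model.** Representing the binary
outcome through a latent normal *z*<sub>*ij*</sub> (probit link,
*y*<sub>2</sub> = 1 ⇔ *z* > 0):

    y1_ij = β10 + β11 t_ij + β12' x_ij + u1_j + e1_ij
    z_ij  = β20 + β21 t_ij + β22' x_ij + u2_j + e2_ij
    (e1, e2)' ~ N(0, Ω_e),   (u1_j, u2_j)' ~ N(0, Ω_u),   Ω_e[2,2] = 1

with individual-level correlation ρ and study-level correlation φ between
outcomes. A blocked Gibbs sampler (C++ core) treats missing outcomes and
all latents as unknowns, so incomplete tables — including whole studies
without the binary outcome — are analysed in a single stage. The
identification constraint Ω<sub>e</sub>[2,2] = 1 is enforced exactly at
every retained draw by a parameter-expanded covariance update.

**Chained-equations multiple imputation.** Random-intercept linear and
logistic imputation models, iterated (default 10 imputations × 10 cycles),
in two variants: FCS1 excludes and FCS2 includes the other outcome in each
imputation model. Completed datasets are analysed with the substantive
bivariate model and pooled by Rubin's rules
(T = W̄ + (1 + 1/M)·B), with elliptical simultaneous confidence regions for
the pair of treatment effects.

## Worked example

Simulate one reference scenario (20 trials × 150 participants, ρ = 0.2,
φ = 0.1), mask 20% of each outcome under covariate-dependent MAR, and
analyse with both routes:

```r
library(ipdmix)

cfg <- scenario_config(20, 150, rho = 0.2, phi = 0.1,
                       missingness = default_missingness("covariate_only", 0.2))
ipd        <- draw_complete_ipd(cfg, seed = 42)
incomplete <- impose_sporadic_mar(ipd, cfg$missingness, seed = 43)

fit <- fit_joint(incomplete, mcmc = mcmc_config(5000, 2500, n_chains = 2, seed = 44))
fit
#> Latent-normal joint hierarchical model (Gibbs)
#>   3000 participants in 20 studies; 2 chains x 2500 retained draws
#>  parameter estimate std.error conf.low conf.high rhat
#>  beta1_trt   0.9387    0.0411   0.8590     1.019    1
#>  beta2_trt   0.0206    0.0572  -0.0929     0.133    1
#>  sigma1_sq   1.0361    0.0296   0.9786     1.097    1
#>        rho   0.1858    0.0313   0.1251     0.249    1
#>    tau1_sq   1.7391    0.6125   0.9253     3.255    1
#>    tau2_sq   0.5601    0.1950   0.2902     1.042    1
#>        phi   0.4733    0.1733   0.0796     0.758    1
joint_region_contains(fit, truth = c(1, 0.06))
#> [1] TRUE
```

`beta1_trt` is the treatment effect on the continuous outcome (truth 1 in
this simulation) and `beta2_trt` the probit-scale effect on the binary
outcome (truth 0.06 = 0.6 × the logit coefficient 0.1); both posterior
means sit within two posterior SDs of the truth, the residual correlation
ρ is recovered near its generating value 0.2, and the 95% joint credible
ellipse contains the true pair. The imputation route gives the same
picture:

```r
iset   <- run_chained_equations(incomplete,
                                imputation_config(m = 10, variant = "fcs2", seed = 45))
pooled <- rubin_pool(lapply(iset$imputations, fit_substantive))
tidy(pooled)
#> # A tibble: 2 × 5
#>   term                 estimate std.error within between
#> 1 treatment_cont         0.939     0.0406 0.0373  0.0152
#> 2 treatment_bin_probit   0.0236    0.0616 0.0501  0.0341
```

The `between` column is the between-imputation SD — the part of the
uncertainty attributable to the missing data.

Simulation experiments over many replicates run through `run_scenario()`,
which reports percent bias, rMSE and joint 95% coverage per method
(`report_table()`, `autoplot()`). A thin command-line front end
(`exec/ipdmix`) exposes `simulate`, `fit`, `run-grid` and `report`
subcommands for shell pipelines.

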