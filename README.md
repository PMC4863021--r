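# droughtscale

Bayesian hierarchical beta regression in which the *timescale* of a
standardized drought index is itself an estimated parameter.

## The problem

Drought indices like the SPEI (standardized anomaly of precipitation minus
potential evapotranspiration) and the SPI (precipitation alone) are computed
over a user-chosen aggregation window — 3 months, a year, a decade — and
ecological responses can integrate climate over any of these. Instead of
fixing the window by intuition or stepwise selection, `droughtscale` places
the timescale on a discrete grid (1–120 months for SPEI, 1–3 for SPI),
precomputes the index at every candidate, and samples the timescale by MCMC
jointly with the rest of a hierarchical beta regression. The motivating
application is wetland hydrology: the fraction of a prairie pothole basin
covered with water, observed from historical (pre-1970) and contemporary
(post-2003) aerial imagery, where one wants to know whether the climatic
memory of wetlands has shortened between eras.

## The model

For wetland *i* in year *j*,

    y_ij ~ Beta(mu_ij * phi_ij, (1 - mu_ij) * phi_ij)
    logit(mu_ij) = X_ij * beta + gamma_i + delta_ij
    log(phi_ij)  = beta_phi + eps_i + zeta_ij

with X = (1, era, SPEI, SPI, SPEI·era, SPEI·SPI, SPEI·SPI·era). The SPEI
column uses an era-specific estimated timescale (t_hist for historical
rows, t_cont for contemporary rows), SPI a single shared timescale. Random
effects are normal with gamma-prior precisions; timescales carry a uniform
prior on their grid. The sampler is Gibbs for the normal-linear hierarchy,
random-walk Metropolis for the per-observation latents and for the discrete
timescales, plus an interweaving re-update of the precisions that keeps
short chains out of the variance-component funnel. See the methods vignette
(`vignettes/timescale-estimation.Rmd`) for the full account.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly.

```r
library(droughtscale)

# 1. a monthly climate record (5 sites, 1895-2011) and the index bank:
#    SPEI at timescales 1..120, SPI at 1..3, per site-month
clim <- simulate_climate(n_sites = 5, years = c(1895, 2011), seed = 42)
bank <- build_index_bank(clim)

# 2. wetland-year observations drawn from the generative model at known
#    parameters (printed magnitudes echo a field study of 147 ND wetlands)
truth <- ts_truth()   # beta_spei = 0.68, t_hist = 84, t_cont = 64, ...
sim <- simulate_observations(truth, bank, n_wetlands = 100,
                             years_per_era = 10, seed = 3)

# 3. fit: 3 chains x (5000 burn-in + 5000 iterations), thinned to 500 draws
ctrl <- ts_control(chains = 3, burnin = 5000, iter = 5000, thin = 10,
                   adapt = TRUE)
fit <- timescale_betareg(sim$data, control = ctrl, seed = 11)
summary(fit)
```

```
Posterior summary (chains pooled)
         parameter    mean      se   q2.5    q97.5  rhat
             beta0  -0.571   0.055 -0.679   -0.462 0.999
          beta_era   0.551   0.077  0.400    0.703 1.000
         beta_spei   0.693   0.052  0.590    0.795 1.002
          beta_spi   0.030   0.037 -0.041    0.104 0.999
     beta_spei_era  -0.374   0.069 -0.509   -0.242 1.004
     beta_spei_spi   0.115   0.050  0.018    0.217 1.001
 beta_spei_spi_era  -0.205   0.096 -0.392   -0.014 1.000
           log_phi   3.251   0.320  2.533    3.842 1.041
         tau_gamma  48.521 160.179  9.277  243.527 1.005
         tau_delta   0.521   0.031  0.467    0.588 1.001
           tau_eps   0.211   0.056  0.124    0.339 1.027
          tau_zeta 335.750 542.081  8.770 1954.132 1.000
       t_spei_hist  80.733   2.713 76.000   84.000 0.999
       t_spei_cont  70.158  12.730 53.000  109.000 1.000
             t_spi   1.577   0.831  1.000    3.000 1.001
```

The generating values sit inside the 95% intervals for every parameter
except the observation-level dispersion precision `tau_zeta` (truth 0.51):
its split from the beta dispersion is only weakly identified and for this
dataset the posterior collapses the dispersion residual — see the
"Known limitations" section of the methods vignette. The point of the
package works: the posterior over the historical SPEI timescale
concentrates near the true 84 months and the contemporary one near 64
(posterior means 80.7 and 70.2), recovered from data in which the
timescale was never observed, and the SPEI effect 0.68, era effect 0.65
and intercept −0.62 are all recovered. `predictive_r2(fit, "marginal")`
and `... "conditional"` give 0.014 and 0.019 here — low because the
generating wetland heterogeneity is tiny relative to the observation-level
logit noise, and conditional exceeds marginal by the share the wetland
effects explain.

Downstream products:

```r
predictive_r2(fit, "marginal")     # fit using fixed effects only
predictive_r2(fit, "conditional")  # ... plus estimated wetland effects

# posterior-weighted SPEI (timescale uncertainty propagated), era contrast
w <- weighted_index(bank, fit$draws[, "t_spei_hist"])
compare_index_by_group(w, regions = c(S1 = "west", S2 = "west", S3 = "east",
                                      S4 = "east", S5 = "east"))

# population-level proportion-filled trajectory for one site, both eras
pred <- predict(fit, w[w$site_id == "S1", ], era = 0)
plot(fit, which = "timescale")     # posterior over t vs the uniform prior
```

A thin command-line interface over the same functions lives at
`inst/cli/droughtscale.R` with subcommands `simulate`, `compute-indices`,
`fit`, `summarize`, `predict`.

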