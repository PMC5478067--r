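# zipnmix

Bayesian hierarchical community abundance modelling for repeated count
surveys of birds in restored urban green spaces — and for any
multi-species point-count design with imperfect detection where species
fall into a small number of response guilds.

## The problem and the model

Managers of urban green spaces revegetate mowed grass and control
invasive weeds in remnant forest, hoping to benefit birds — especially
the *urban sensitive* species that decline most under urbanization, as
opposed to *urban adaptable* and *urban exploitative* species. Raw
counts confound abundance with detectability, and most species are too
rarely detected to model alone.

`zipnmix` fits a zero-inflated Poisson N-mixture model jointly across
the community. For species *i*, site *j*, visit *k*:

    w_ij ~ Bernoulli(psi_i)                      # inclusion
    N_ij ~ Poisson(w_ij * lambda_ij)             # latent abundance
    y_ijk ~ Binomial(N_ij, p_ijk)                # observed count

    log(lambda_ij) = u1_i TRT_j + u2_i (1-TRT_j) + o1_i ORI_j + o2_i (1-ORI_j)
                     + a1_i area_j + a2_i area_j TRT_j
                     + a3_i TRT_j ORI_j + a4_i TRT_j (1-ORI_j)

    logit(p_ijk) = v1_i + b1_i DATE_jk + b2_i DATE_jk^2
                        + b3_i TSR_jk + b4_i TSR_jk^2

`TRT` marks treated sites (revegetated or weed-controlled), `ORI`
forest versus grass origin, so `a3`/`a4` are the weed-control and
revegetation effects on log abundance. Every species coefficient is
drawn from hyperparameters of its urban class, e.g.
`a3_i ~ Normal(mu_a3_sensitive, sigma_a3_sensitive)`, estimated jointly
by a Metropolis-within-Gibbs sampler with full data augmentation of
`(w, N)`. Derived per-draw quantities give per-site class richness
(`N_ij >= 1`), stratum mean richness, and the *richness benefit* of a
treatment (treated minus untreated stratum mean). Everything is
reported as posterior mode, 95% highest density interval, and the
proportion of the posterior above zero.

A synthetic-data generator reproduces the motivating blocked design (19
blocks × 4 site types, 3 morning visits, 74 species in classes
29/21/24) with full latent truth, so the pipeline is verified by
parameter recovery. See `vignettes/community-zip-nmixture.Rmd` for the
model's assumptions, the sampler's special moves (exact draws along the
predictor's likelihood-invariant ridges, non-centered interweaving, a
collapsed variance-allocation move), and known identifiability limits.

## Worked example

```r
library(zipnmix)

design <- generate_design(design_spec(n_blocks = 19), seed = 1)
params <- draw_species_params(default_class_hyperparams(),
                              default_roster(10, 10, 10), seed = 2)
truth  <- simulate_counts(design, params, seed = 3)
print(truth)

fit <- fit_model(truth, config = mcmc_config(n_chains = 3, n_iter = 4000,
                                             n_burnin = 1000, thin = 5,
                                             seed = 4))
print(fit)

rich <- richness_draws(fit)
b <- richness_benefit(rich, design, "sensitive", "grass")  # revegetation
summarize_draws(list(BRichness_sensitive_grass = b))
```

which prints (abridged):

```
truth_bundle: 30 species x 76 sites x 3 visits (seed 3)
  occupied species-sites: 1181/2280; total count 3985
zipnmix_fit: 3 chains x 4000 iterations (burn-in 1000, thin 5)
  30 species, 76 sites, 3 visits; N truncated at 860
  max split R-hat over hyperparameters: 1.203
                  parameter hdi_lower      mode hdi_upper prop_above_0
1 BRichness_sensitive_grass 0.3157895 0.6812236 0.9473684            1
```

The benefit row reads: revegetating mowed grass adds about 0.7 urban
sensitive species per site (mode), 95% HDI roughly (0.3, 0.9), with
posterior probability ~1.00 that the effect is positive — matching the
generating hyperparameters, whose revegetation effect for the sensitive
class is positive (`mu_a4 = 0.4`). (A 3 × 4000 fit is demonstration
size: an R-hat of 1.2 on the slowest spread hyperparameter calls for
the default 3 × 10,000 run.)

The `analysis/` scripts run the same pipeline at full scale and leave
their tables under `results/`: `01_simulate.R` (reference 74-species
survey + truth), `02_fit.R`, `03_summarize.R` (hyperparameter and
richness-benefit tables), `04_diagnostics.R` (R-hat, acceptance rates,
recovery scoring).

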