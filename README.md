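# tvddm

Bayesian estimation and comparison of two evidence-accumulation models
of two-choice perceptual decisions: the standard drift-diffusion model
(DDM) and a time-varying drift-rate variant (TV-DDM) in which a
perceptual-integration stage modulates evidence accumulation.  The
package is aimed at researchers who want to test whether gradual
perceptual integration — rather than an instantaneously available
percept — better explains choice and response-time (RT) data from noisy
discrimination tasks, and whether experimental manipulations (e.g.
stimulus noise) selectively influence the parameters they are supposed
to influence.

## The models

The DDM accumulates evidence $x$ from start point $A/2$ between
absorbing boundaries $0$ and $A$:

$$\Delta x_t = v\,dt + \sigma\,\Delta W_t$$

with drift rate $v$, diffusion coefficient $\sigma = 0.1$, non-decision
time $t_{er}$, and conventional between-trial variability parameters
$s_z$, $s_v$, $s_{ter}$ (six free parameters).

The TV-DDM replaces the instantaneous drift onset with a growth
function $\theta(t) = P(n, \beta t)$ (regularized lower incomplete
gamma; $n$ cascaded linear filters with rate $\beta$):

$$\Delta x_t = v\,\theta(t)\,dt + \sqrt{\sigma^2\theta(t) +
\sigma_2^2}\,\Delta W_t$$

where $\sigma_2$ is premature-sampling noise present before the percept
has formed (seven free parameters).

Inference is fully simulation-based: likelihoods are approximated by
kernel density estimation over simulated defective RT distributions
(probability density approximation, with adaptive per-point
bandwidths), posteriors are sampled by two-stage differential-evolution
MCMC with truncated-normal priors and a purification step for the noisy
likelihood, convergence is checked with split R-hat, and models are
compared through Bayes factors whose marginal likelihoods come from
thermodynamic integration (plus DIC/BPIC).  Distributional measures
(CDF quantiles, conditional accuracy functions), posterior credible
bands, a repeated-measures ANOVA on posterior-mean estimates and a
posterior-overlap indicator complete the analysis pipeline.  A
synthetic-data generator emulates the 2 × 4 factorial noise designs
this methodology targets, so the whole pipeline is testable without
human data.

See the methods vignette (`vignettes/tvddm-methods.Rmd`) for the
numerical choices and their rationale.

## Worked example

Simulate one participant-condition cell from the DDM, fit it with a
reduced sampler budget, and summarize:

```r
library(tvddm)

truth <- ddm_params(A = 0.17, ter = 0.26, v = 0.25,
                    sz = 0.05, sv = 0.07, ster = 0.28)
trials <- simulate_ddm(truth, 256, seed = 7)
dat <- clean_rts(trials[trials$response != "timeout",
                        c("response", "rt")])$table

fit <- fit_dm(dat, "ddm",
              control = sampler_control(n_chains = 12,
                                        stage1_iters = 60,
                                        stage2_iters = 600,
                                        burn_in = 200),
              n_sim = 500, seed = 1)
fit
```

```
DDM fit by two-stage DE-MCMC (PDA likelihood, n_sim = 500)
  data: 256 trials; chains: 12; generations: 600 (burn-in 200)
  max split R-hat: 1.137 (criterion 1.1)
  EAP estimates:
     A    ter      v     sz     sv   ster 
0.2030 0.2859 0.3551 0.0903 0.1271 0.2161 
```

The posterior means land near the generating values (`A` 0.17,
`ter` 0.26, `v` 0.25) given only 256 trials; the weakly identified
variability parameters are drawn toward their priors, and at this
reduced budget the split R-hat statistic sits slightly above the 1.1
criterion — at the reference budget (30 chains, 3000 generations) it
falls below it.  `summary(fit)`
adds posterior SDs and 95% credible intervals, `plot(fit)` shows traces
and marginals, and `simulate(fit)` draws posterior-predictive trials.

Model comparison on the same cell:

```r
ml_ddm <- tide_log_ml(dat, "ddm", eap_init = coef(fit),
                      n_temps = 6, n_gens = 250, burn_in = 80,
                      n_sim = 500, seed = 11)
fit_tv <- fit_dm(dat, "tvddm",
                 control = sampler_control(n_chains = 12,
                                           stage1_iters = 60,
                                           stage2_iters = 150,
                                           burn_in = 50),
                 n_sim = 500, seed = 2)
ml_tv <- tide_log_ml(dat, "tvddm", eap_init = coef(fit_tv),
                     n_temps = 6, n_gens = 250, burn_in = 80,
                     n_sim = 500, seed = 12)
bayes_factor(ml_ddm, ml_tv)
```

```
BF(M1 vs M2) = 2.337 (log BF 0.849): anecdotal M1 evidence
```

Data generated by the plain DDM favour it, though at 256 trials and
this reduced integration budget the evidence is only anecdotal —
larger cells and the reference budget sharpen the discrimination.
`run_study()` drives the same pipeline end to end over a whole
synthetic study (generation, cleaning, screening, per-cell fits,
convergence gating, Bayes-factor evidence counts, posterior-overlap
indicator).

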