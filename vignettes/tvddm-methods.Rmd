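---
title: "Methods: simulation, likelihood approximation and Bayesian inference for the DDM and TV-DDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, likelihood approximation and Bayesian inference for the DDM and TV-DDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **tvddm**, the
numerical and design choices behind the implementation, and what the
package's synthetic-data tests do and do not establish about real data.

## The two models

**Standard DDM.** Evidence $x$ accumulates from a start point $z$
between absorbing boundaries at $0$ and $A$ according to
$\Delta x_t = v\,dt + \sigma\,\Delta W_t$, with drift rate $v$,
diffusion coefficient $\sigma$ and Wiener noise $W$.  Hitting the upper
boundary produces the correct response, the lower an error; observed
response time adds a non-decision time $t_{er}$.  Between-trial
variability follows the conventional scheme: start point uniform on
$A/2 \pm s_z/2$, drift normal with SD $s_v$, non-decision time uniform
on $t_{er} \pm s_{ter}/2$ — six free parameters.

**TV-DDM.** The standard model assumes evidence accumulation operates
on a fully formed percept from the first millisecond.  The time-varying
variant instead modulates accumulation by a perceptual-integration
stage: $\Delta x_t = v\,\theta(t)\,dt +
\sqrt{\sigma^2\theta(t) + \sigma_2^2}\,\Delta W_t$, where
$\theta(t) = P(n, \beta t)$ is the regularized lower incomplete gamma
function — the output of $n$ cascaded linear filters with rate $\beta$
— rising from 0 to 1, and $\sigma_2$ is a constant premature-sampling
noise present before the representation has formed.  The TV-DDM has no
start-point or non-decision-time variability; with drift variability
$s_v$ it has seven free parameters.

The printed rendering of the diffusion term in our source for the
TV-DDM is typographically ambiguous; we implement the infinitesimal SD
$\sqrt{\sigma^2\theta(t) + \sigma_2^2}$, the natural reading in which
stimulus-driven diffusion grows with the representation while premature
sampling stays constant.  $\theta$ is evaluated on the decision-stage
clock (time since stimulus onset, excluding $t_{er}$), and no pre-onset
accumulation interval is modelled.

## Forward simulation

Both models are integrated by Euler's method in seconds with
`dt = 0.001`, `sigma = 0.1` and a 10 s decision-time cap.  Timed-out
trials are re-simulated up to 10 times and then recorded as timeouts;
this keeps defective densities proper at extreme parameter values while
leaving ordinary parameter regions untouched (timeouts are essentially
impossible there).  Gaussian increments come from a ziggurat sampler
over a xoroshiro128+ stream seeded per trial with splitmix64, so trial
$i$ is reproducible independent of the number of trials requested and
results are identical across platforms for a given seed.

A note on discretization: an Euler scheme overshoots absorbing
boundaries, biasing absorption probabilities by $O(\sqrt{dt})$.  The
package's tests compare simulated choice probabilities against the
closed form with the standard continuity correction (each boundary
widened by $0.5826\,\sigma\sqrt{dt}$), which removes this bias to
Monte-Carlo accuracy at `dt = 0.001`.

## Likelihood: probability density approximation

Neither model has a tractable likelihood once between-trial variability
(or the growth function) is present, so the likelihood is estimated by
simulation: `n_sim` trials (default 1000) are drawn at the candidate
parameters, a Gaussian-kernel KDE is built per response category, each
category weighted by its choice proportion (a *defective* density;
timeouts absorb mass), and the data are scored under it with a density
floor of $10^{-10}$ per observation.  Categories with fewer than two
simulated trials evaluate to the floor.

The default bandwidths are *adaptive* (Abramson square-root law: a
Silverman-rule pilot density is estimated on a 128-point grid, and each
kernel centre gets bandwidth $h_0 (\hat f/g)^{-1/2}$, clamped at
$10 h_0$, with $g$ the geometric-mean pilot).  The reference
methodology likewise relies on an adaptive KDE, and here the adaptivity
is load-bearing rather than an efficiency device: with a fixed
bandwidth, the log-likelihood of a several-hundred-trial cell is
dominated by a handful of extreme-RT observations whose kernel density
flickers between a finite value and the floor across simulation
replicates, and the resulting noise makes the pseudo-marginal sampler
unusably sticky.  Wide kernels in sparse tails remove this flicker at a
small, smooth cost in tail bias.  Fixed Silverman and Sheather-Jones
rules remain configuration options, as is an off-by-default log-RT
transform.  An analytic Wiener first-passage density
(small-time/large-time series) is included for the variability-free DDM
as a test oracle only.

Even so the estimator is *noisy*: repeated evaluations at the same
parameters differ, with an SD that grows with the number of data points
and shrinks with `n_sim`.  The sampler is designed around this noise
rather than pretending it away.

## Two-stage DE-MCMC

Fitting proceeds per participant and condition.  Priors are truncated
normals (lower bound 0) with location equal to scale; defaults are
`default_priors()`.

**Stage 1** is a current-to-best differential-evolution search:
proposals $x_i + \gamma_1(x_{best}-x_i) + \gamma_2(x_{r1}-x_{r2}) + U(-b,b)$
with $\gamma_1=\gamma_2=0.5$ and $b = 10^{-4}$ of each prior scale,
accepted greedily on the noisy log posterior.  Greedy acceptance on a
noisy objective is an extreme-value trap — the incumbent's stored value
drifts upward on lucky draws — so the purification idea is applied here
too: with probability 0.3 a chain's stored log-likelihood is
re-evaluated with a fresh simulation before each comparison.  Without
this the search parks at whichever point received the luckiest
likelihood estimate.

**Handoff.** An optimizer's final population is collapsed onto the
mode, and differential-evolution proposals are scale-adaptive: from a
degenerate population they cannot expand.  Stage-2 chains therefore
start from the stage-1 solution re-dispersed with per-parameter scales
probed from the local posterior curvature (the axis displacement at
which the averaged log posterior drops by about two nats, i.e. roughly
two posterior SDs for a locally Gaussian target).  Dispersed starts are
also a precondition for the split-$\hat R$ diagnostic to mean anything.
For the TV-DDM the handoff additionally multiplies each chain's
evidence-scale parameters ($A$, $v$, $\sigma_2$, $s_v$) by a common
log-normal factor (`scale_jitter`): the premature-sampling noise
re-introduces partial freedom in the evidence scale that fixing
$\sigma$ normally removes, and a population spanning that soft ridge
lets difference-vector proposals traverse it.

**Stage 2** is DE-MCMC proper: proposals
$x_i + \gamma(x_{r1}-x_{r2}) + U(-b,b)$ with
$\gamma = 2.38/\sqrt{2d}$ (10% of proposals use $\gamma = 1$ for mode
jumping), Metropolis acceptance against the chain's stored noisy log
likelihood, and a purification step: with probability 0.3 per chain per
generation the stored value is refreshed before proposing, which
prevents chains from sticking at overestimated likelihoods.  The
reference budget is 30 chains, 1000 stage-1 and 3000 stage-2
generations with 500 burn-in (30 × 3000 = 90,000 generated draws;
30 × 2500 retained).

**Convergence and summaries.** `split_rhat()` implements the standard
split potential-scale-reduction factor (each chain halved, criterion
1.1).  Point estimates are posterior means (EAPs) with central 95%
credible intervals.  A caveat established by the package's own
acceptance run: at severely reduced budgets (hundreds rather than
thousands of retained generations) the pseudo-marginal stickiness of
the noisy likelihood keeps the statistic above the 1.1 criterion even
when point estimates are already adequate; the same sampler falls
below the criterion once a few thousand generations are retained.
Users fitting real data should use the full reference budget.

## Model comparison

Marginal likelihoods are computed by thermodynamic integration over
power posteriors $p(\theta)\,L(\theta)^{t}$: one DE chain per
temperature (default 30), sharing difference vectors across
temperatures but never swapping states, initialized at the EAPs of a
completed fit.  Difference-vector donors are restricted to chains at
neighbouring temperatures (window of about a fifth of the schedule):
the power-posterior scale varies by an order of magnitude along the
path, and scale-matched differences keep the extreme-temperature
chains moving.  The temperature schedule is the fifth-power rule
$t_k = (k/(K-1))^5$, concentrating temperatures near zero where the
expected log likelihood changes fastest.  With the simulation-based
likelihood the chains are purified exactly as in the base sampler
(probability 0.3 per chain per generation) — here it matters doubly,
because the stored values are not only the Metropolis targets but the
integrand itself, and retained noise spikes bias the marginal
likelihood upward.

The quadrature depends on the likelihood type.  For deterministic
plug-in likelihoods the integral uses the variance-corrected
trapezoidal rule (each segment's trapezoid minus $\Delta t^2/12$ times
the change in the within-temperature log-likelihood variance), which
cancels the leading discretization error — on a 10-temperature schedule
that error alone is a few tenths of a nat.  For the simulation-based
likelihood the plain trapezoid is used instead: there the
within-temperature variance is dominated by estimator noise (enormous
at low temperatures, where chains roam the prior), and the correction
term would amplify it by orders of magnitude.  These choices are stated
because the source method fixes only the number of temperatures.

Bayes factors are interpreted on the Jeffreys scale with the standard
bounds (1–3 anecdotal, 3–10 moderate, 10–30 strong, 30–100 very
strong, above 100 decisive, and reciprocals for the other model); the
printed table in our source garbles two adjacent categories, so the
standard bounds are used and documented here.  DIC and BPIC accompany
the Bayes factor; with a PDA likelihood each draw's deviance is
averaged over repeated likelihood evaluations (default 20) so that
estimator noise does not masquerade as effective parameters.

## Distributional measures and the overlap indicator

RT distributions are summarized by 17 quantiles (10% to 90% in 5%
steps; type-7 linear interpolation, stated because the source does not
specify an estimator) and conditional accuracy functions over five
RT-quantile bands whose centres are 10/30/50/70/90% (the source names
levels, not edges; correct and error trials are pooled before
binning).  Model-based measures simulate 2000 trials per condition at
the EAPs; credible bands re-simulate the measures for posterior draws
(1000 by default), averaging across participants per draw, with the
simulation seed derived from the drawn parameters so a degenerate
posterior yields exactly zero-width bands.

Condition effects on EAPs use a one-way repeated-measures ANOVA
(uncorrected degrees of freedom, matching the source's reporting).  The
*posterior overlap indicator* guards those ANOVAs against posterior
uncertainty: in each of 1000 replicates, 10 posterior draws per
participant × condition are averaged and the ANOVA repeated; an effect
is confirmed if at least 95% of replicates reject.  Ten draws rather
than the full posterior is deliberate — averaging many draws collapses
each cell to its EAP and the indicator becomes as liberal as the
original ANOVA.

## Synthetic data generator

`generate_dataset()` emulates the behavioral structure the analysis
assumes: a 2 × 4 repeated-measures design (two stimulus identities ×
noise levels 10/40/70/80%), 32–64 trials per participant per noise
level, RT cleaning at 150 ms/3000 ms (strict bounds, counts reported)
and below-chance participant screening.  The default ground truth
encodes the qualitative pattern of interest — drift decreasing and
boundary increasing with noise, non-decision time constant — with
values chosen so group error rates rise from a few percent to roughly
25–30%, matching the accuracy range reported for noisy
dot-discrimination tasks (about 70–100%) while keeping every condition
off ceiling; near-ceiling cells leave drift and boundary barely
identifiable and would make any recovery study vacuous.  Participants
differ by a 10% relative normal jitter on every parameter
(truncated-by-redraw); this is a declared convention, not an inference
target — the analysis has no group-level model.  The generator does not
emulate contaminant/guessing processes, sequential effects, or the
psychophysical mapping from physical noise to drift, so passing tests
demonstrate pipeline correctness on model-faithful data, not robustness
to model violation.

## Problem sizes used by the tests

The test suite scales the pipeline to desk size as its own design
choice: recovery studies use 512 trials per fit with 10–12 chains and
200–600 retained generations at 300–500 simulated trials per
likelihood call; model-recovery Bayes factors use 6 temperatures × 250
generations; the convergence-gate run uses the configuration stated in
its test.  These budgets are adequate for the properties each test
asserts (orderings, coverage, signs of log Bayes factors) but are an
order of magnitude below the reference budget appropriate for real
data.

## Known limitations

- The PDA likelihood's noise makes short chains sticky; the convergence
  gate at the smallest budgets is the pipeline's weakest point (see
  above), and is exactly what the purification step mitigates but
  cannot eliminate.
- The TV-DDM at priors-centred parameters is only weakly identified on
  a few hundred trials: the premature-sampling noise opens a soft
  evidence-scale ridge, and additional trade-offs run through the
  non-decision time and growth rate.  Even long, well-converged runs
  can place a 95% credible bound just past a generating value
  (non-decision time is the usual casualty), so joint interval coverage
  of several parameters at once should not be expected to reach nominal
  rates at small per-cell trial counts.  Drift-rate *orderings* across
  conditions, and model discrimination, are robust much earlier.
- The growth function is a smooth incomplete-gamma form; data generated
  by qualitatively different integration dynamics (e.g. non-linear
  filtering) are outside its family, and the package makes no claim
  about them.
- Collapsing-boundary and urgency-gating variants are not implemented.
- Fits are independent per participant × condition; there is no
  hierarchical pooling.
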