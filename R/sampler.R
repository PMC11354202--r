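#' Sampler settings for the two-stage DE-MCMC
#'
#' Stage 1 is a current-to-best differential-evolution search (greedy
#' acceptance) whose final population seeds stage 2, the DE-MCMC proper
#' (Metropolis acceptance).  Defaults follow the reference configuration:
#' 30 chains, 1000 stage-1 generations, 3000 stage-2 generations of which
#' 500 are burn-in, and a purification probability of 0.3 (each chain's
#' stored noisy log-likelihood is re-evaluated with a fresh simulation
#' before proposing, preventing chains from sticking at likelihood values
#' that were overestimated by chance).
#'
#' @param n_chains number of chains; must be at least d + 2 where d is the
#'   parameter count.
#' @param stage1_iters stage-1 (search) generations.
#' @param stage2_iters stage-2 (posterior) generations.
#' @param burn_in stage-2 generations discarded, `< stage2_iters`.
#' @param purify_prob per-chain per-generation purification probability in
#'   `[0, 1]`.
#' @param gamma_de stage-2 DE scale; default `2.38 / sqrt(2 d)`.
#' @param gamma1,gamma2 stage-1 current-to-best coefficients.
#' @param mode_jump_prob fraction of stage-2 proposals using `gamma = 1`
#'   (mode jumping).
#' @param jitter_scale half-width of the uniform proposal jitter, as a
#'   fraction of each prior's scale.
#' @param redisperse start stage-2 chains from the stage-1 solution
#'   re-dispersed at posterior-curvature scales (default `TRUE`).  The
#'   greedy search collapses its population onto the mode, difference-
#'   vector proposals cannot expand a degenerate population, and the
#'   split R-hat diagnostic presupposes dispersed starts.
#' @param scale_jitter names of parameters that share an evidence-scale
#'   non-identifiability (they can be multiplied jointly by a constant
#'   with little effect on the predicted data).  At the stage-2 handoff
#'   each chain additionally multiplies these parameters by a common
#'   log-normal factor, so the population spans the scale ridge and
#'   difference-vector proposals can traverse it.  [fit_dm()] sets this
#'   to `A`, `v`, `sigma2`, `sv` for the TV-DDM (whose
#'   premature-sampling noise re-introduces partial scale freedom) and
#'   leaves it empty for the DDM.
#' @return An object of class `"sampler_control"`.
#' @export
sampler_control <- function(n_chains = 30, stage1_iters = 1000,
                            stage2_iters = 3000, burn_in = 500,
                            purify_prob = 0.3, gamma_de = NULL,
                            gamma1 = 0.5, gamma2 = 0.5,
                            mode_jump_prob = 0.1, jitter_scale = 1e-4,
                            redisperse = TRUE, scale_jitter = NULL) {
  stopifnot(n_chains >= 3, stage1_iters >= 1, stage2_iters >= 1,
            burn_in >= 0, burn_in < stage2_iters,
            purify_prob >= 0, purify_prob <= 1)
  structure(list(n_chains = as.integer(n_chains),
                 stage1_iters = as.integer(stage1_iters),
                 stage2_iters = as.integer(stage2_iters),
                 burn_in = as.integer(burn_in),
                 purify_prob = purify_prob, gamma_de = gamma_de,
                 gamma1 = gamma1, gamma2 = gamma2,
                 mode_jump_prob = mode_jump_prob,
                 jitter_scale = jitter_scale,
                 redisperse = isTRUE(redisperse),
                 scale_jitter = scale_jitter),
            class = "sampler_control")
}

# fresh 31-bit simulation seed from R's RNG stream
new_sim_seed <- function() sample.int(2147483647L, 1L)

# Per-parameter posterior scale around a mode estimate: for each parameter,
# the axis displacement at which the log posterior drops by about 2 nats
# (about two posterior SDs for a locally Gaussian target) is found by
# doubling from 2% of the prior scale.  Noisy log-likelihoods are averaged
# over a few evaluations.  Used to re-disperse stage-2 starting values.
probe_posterior_scale <- function(centre, loglik_fn, priors,
                                  target_drop = 2, n_avg = 3) {
  d <- length(priors)
  ps <- prior_scales(priors)
  lpost <- function(theta, reps = n_avg) {
    lp <- log_prior(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    lp + mean(vapply(seq_len(reps),
                     function(j) loglik_fn(theta, new_sim_seed()),
                     numeric(1)))
  }
  # the reference value is shared by every parameter's probe, so average
  # it well: an unlucky high draw would shrink all scales at once
  l0 <- lpost(centre, reps = 4 * n_avg)
  deltas <- 0.02 * 2^(0:6)
  sc <- numeric(d)
  for (j in seq_len(d)) {
    drop_at <- vapply(deltas, function(f) {
      up <- centre; up[j] <- up[j] + f * ps[j]
      dn <- centre; dn[j] <- dn[j] - f * ps[j]
      dr <- l0 - c(lpost(up), lpost(dn))
      dr <- dr[is.finite(dr)]
      if (!length(dr)) Inf else mean(dr)
    }, numeric(1))
    # smallest displacement whose drop, and every larger displacement's
    # drop, exceeds the target: single noisy flukes cannot shrink the
    # scale estimate
    hit <- rev(cumprod(rev(drop_at >= target_drop))) == 1
    k <- if (any(hit)) which(hit)[1] else length(deltas)
    sc[j] <- deltas[k] * ps[j] / 2
  }
  stats::setNames(pmin(sc, ps), names(priors))
}

prior_scales <- function(priors) {
  vapply(priors, function(p) p$sigma, numeric(1))
}

init_population <- function(loglik_fn, priors, n_chains, max_tries = 100) {
  d <- length(priors)
  pop <- matrix(NA_real_, n_chains, d,
                dimnames = list(NULL, names(priors)))
  lp <- ll <- rep(-Inf, n_chains)
  for (i in seq_len(n_chains)) {
    for (k in seq_len(max_tries)) {
      theta <- drop(sample_prior(priors, 1))
      lpi <- log_prior(theta, priors)
      if (!is.finite(lpi)) next
      lli <- loglik_fn(theta, new_sim_seed())
      if (is.finite(lli)) {
        pop[i, ] <- theta; lp[i] <- lpi; ll[i] <- lli
        break
      }
    }
  }
  if (all(!is.finite(lp + ll)))
    stop("prior/data mismatch: no chain initialized at finite posterior",
         call. = FALSE)
  list(pop = pop, log_prior = lp, log_lik = ll)
}

#' Stage-1 current-to-best differential-evolution search
#'
#' Optimizes the (noisy) unnormalized log posterior.  Each chain proposes
#' `x_i + gamma1 (x_best - x_i) + gamma2 (x_r1 - x_r2) + U(-b, b)` and
#' accepts greedily; the final population seeds [stage2_demcmc()].
#'
#' @param loglik_fn `function(theta, seed)` returning a scalar
#'   log-likelihood (`-Inf` allowed); `seed` is a fresh simulation seed
#'   for stochastic likelihoods and may be ignored by analytic ones.
#' @param priors a `"prior_set"` covering every parameter.
#' @param control a [sampler_control()].
#' @param seed integer seed for the sampler's RNG.
#' @return List with elements `pop` (chains x parameters matrix),
#'   `log_prior`, `log_lik` and `trace_best` (best log posterior per
#'   generation).
#' @export
stage1_search <- function(loglik_fn, priors, control = sampler_control(),
                          seed = 1L) {
  d <- length(priors)
  nc <- control$n_chains
  if (nc < d + 2) stop("n_chains must be at least d + 2", call. = FALSE)
  set.seed(seed)
  st <- init_population(loglik_fn, priors, nc)
  jit <- control$jitter_scale * prior_scales(priors)
  trace_best <- numeric(control$stage1_iters)
  history <- array(NA_real_, c(nc, control$stage1_iters, d),
                   dimnames = list(NULL, NULL, names(priors)))
  lpost <- st$log_prior + st$log_lik
  for (gen in seq_len(control$stage1_iters)) {
    best <- which.max(lpost)
    for (i in seq_len(nc)) {
      # purification: refresh the incumbent's noisy likelihood so greedy
      # search tracks the posterior rather than lucky overestimates
      if (control$purify_prob > 0 &&
          stats::runif(1) < control$purify_prob) {
        st$log_lik[i] <- loglik_fn(st$pop[i, ], new_sim_seed())
        lpost[i] <- st$log_prior[i] + st$log_lik[i]
      }
      r <- sample(seq_len(nc)[-i], 2)
      prop <- st$pop[i, ] +
        control$gamma1 * (st$pop[best, ] - st$pop[i, ]) +
        control$gamma2 * (st$pop[r[1], ] - st$pop[r[2], ]) +
        stats::runif(d, -jit, jit)
      lp <- log_prior(prop, priors)
      if (!is.finite(lp)) next
      ll <- loglik_fn(prop, new_sim_seed())
      if (lp + ll > lpost[i]) {
        st$pop[i, ] <- prop
        st$log_prior[i] <- lp
        st$log_lik[i] <- ll
        lpost[i] <- lp + ll
      }
    }
    trace_best[gen] <- max(lpost)
    history[, gen, ] <- st$pop
  }
  c(st, list(trace_best = trace_best, history = history))
}

#' Stage-2 DE-MCMC posterior sampling
#'
#' Population MCMC with difference-vector proposals
#' `x_i + gamma (x_r1 - x_r2) + U(-b, b)` (`r1 != r2 != i`) and Metropolis
#' acceptance on the (noisy) unnormalized posterior.  Before proposing,
#' each chain's stored log-likelihood is re-evaluated with a fresh
#' simulation seed with probability `purify_prob`.  All generations are
#' returned; `burn_in` marks the prefix conventionally discarded.
#'
#' @param init population from [stage1_search()] (or any list with
#'   elements `pop`, `log_prior`, `log_lik`).
#' @inheritParams stage1_search
#' @return An object of class `"dm_draws"`: samples array
#'   (chains x iterations x parameters), log-likelihood trace, burn-in
#'   index, acceptance rate and purification count.
#' @export
stage2_demcmc <- function(init, loglik_fn, priors,
                          control = sampler_control(), seed = 1L) {
  d <- length(priors)
  nc <- control$n_chains
  if (nc < d + 2) stop("n_chains must be at least d + 2", call. = FALSE)
  set.seed(seed)
  gam <- if (is.null(control$gamma_de)) 2.38 / sqrt(2 * d) else
    control$gamma_de
  jit <- control$jitter_scale * prior_scales(priors)
  ni <- control$stage2_iters
  pop <- init$pop
  lp <- init$log_prior
  ll <- init$log_lik
  if (isTRUE(control$redisperse)) {
    # The stage-1 greedy search collapses its population onto the mode;
    # DE proposals cannot expand a degenerate population, so stage-2
    # chains start from the stage-1 solution re-dispersed with
    # per-parameter scales probed from the local posterior curvature.
    best <- which.max(init$log_prior + init$log_lik)
    centre <- init$pop[best, ]
    sc <- probe_posterior_scale(centre, loglik_fn, priors)
    sj <- intersect(control$scale_jitter, names(priors))
    for (i in seq_len(nc)) {
      for (tr in 1:100) {
        cand <- centre + stats::rnorm(d, 0, sc)
        if (length(sj))
          cand[sj] <- cand[sj] * exp(stats::rnorm(1, 0, 0.35))
        lp_c <- log_prior(cand, priors)
        if (!is.finite(lp_c)) next
        ll_c <- loglik_fn(cand, new_sim_seed())
        if (is.finite(ll_c)) {
          pop[i, ] <- cand; lp[i] <- lp_c; ll[i] <- ll_c
          break
        }
      }
    }
  } else if (control$purify_prob > 0) {
    # purify every chain at the handoff: greedy search retains
    # upward-biased likelihood estimates that stall early mixing
    for (i in seq_len(nc)) ll[i] <- loglik_fn(pop[i, ], new_sim_seed())
  }
  samples <- array(NA_real_, c(nc, ni, d),
                   dimnames = list(NULL, NULL, names(priors)))
  ll_trace <- matrix(NA_real_, nc, ni)
  n_acc <- 0L
  n_purify <- 0L
  for (gen in seq_len(ni)) {
    for (i in seq_len(nc)) {
      if (control$purify_prob > 0 &&
          stats::runif(1) < control$purify_prob) {
        ll[i] <- loglik_fn(pop[i, ], new_sim_seed())
        n_purify <- n_purify + 1L
      }
      r <- sample(seq_len(nc)[-i], 2)
      g <- if (stats::runif(1) < control$mode_jump_prob) 1 else gam
      prop <- pop[i, ] + g * (pop[r[1], ] - pop[r[2], ]) +
        stats::runif(d, -jit, jit)
      lp_p <- log_prior(prop, priors)
      if (is.finite(lp_p)) {
        ll_p <- loglik_fn(prop, new_sim_seed())
        if (log(stats::runif(1)) < (lp_p + ll_p) - (lp[i] + ll[i])) {
          pop[i, ] <- prop; lp[i] <- lp_p; ll[i] <- ll_p
          n_acc <- n_acc + 1L
        }
      }
      samples[i, gen, ] <- pop[i, ]
      ll_trace[i, gen] <- ll[i]
    }
  }
  structure(list(samples = samples, log_lik = ll_trace,
                 burn_in = control$burn_in, par_names = names(priors),
                 n_generated = nc * ni,
                 n_retained = nc * (ni - control$burn_in),
                 acc_rate = n_acc / (nc * ni),
                 n_purify = n_purify),
            class = "dm_draws")
}

#' @export
print.dm_draws <- function(x, ...) {
  dm <- dim(x$samples)
  cat(sprintf(
    "DE-MCMC draws: %d chains x %d generations x %d parameters\n",
    dm[1], dm[2], dm[3]))
  cat(sprintf("  generated %d, retained %d (burn-in %d), acceptance %.2f\n",
              x$n_generated, x$n_retained, x$burn_in, x$acc_rate))
  invisible(x)
}

# retained draws as (chains * iters) x d matrix
retained_matrix <- function(draws) {
  keep <- (draws$burn_in + 1):dim(draws$samples)[2]
  m <- draws$samples[, keep, , drop = FALSE]
  dd <- dim(m)
  out <- matrix(aperm(m, c(2, 1, 3)), dd[1] * dd[2], dd[3])
  colnames(out) <- draws$par_names
  out
}

#' Split potential-scale-reduction convergence diagnostic
#'
#' Each retained chain is split in half and the standard
#' between-/within-variance potential scale reduction factor is computed
#' over the split halves, per parameter.  Values at or below 1.1 are
#' conventionally taken to indicate convergence.
#'
#' @param draws a [stage2_demcmc()] result, or a chains x iterations x
#'   parameters array.
#' @param burn_in burn-in to drop when `draws` is a plain array.
#' @return Named numeric vector, one statistic per parameter.
#' @export
split_rhat <- function(draws, burn_in = 0) {
  if (inherits(draws, "dm_draws")) {
    a <- draws$samples
    burn_in <- draws$burn_in
  } else a <- draws
  keep <- (burn_in + 1):dim(a)[2]
  if (length(keep) < 4)
    stop("need at least 4 post-burn-in iterations per chain", call. = FALSE)
  a <- a[, keep, , drop = FALSE]
  n_half <- floor(dim(a)[2] / 2)
  out <- numeric(dim(a)[3])
  names(out) <- dimnames(a)[[3]]
  for (p in seq_len(dim(a)[3])) {
    halves <- rbind(a[, seq_len(n_half), p, drop = TRUE],
                    a[, n_half + seq_len(n_half), p, drop = TRUE])
    m <- rowMeans(halves)
    v <- apply(halves, 1, stats::var)
    W <- mean(v)
    if (W == 0) stop("degenerate chains: zero within-chain variance",
                     call. = FALSE)
    B <- n_half * stats::var(m)
    out[p] <- sqrt(((n_half - 1) / n_half * W + B / n_half) / W)
  }
  out
}

#' Expected a posteriori estimates
#'
#' Mean of the retained (post-burn-in) draws, per parameter.
#'
#' @param draws a `"dm_draws"` object.
#' @return Named numeric vector of posterior means.
#' @seealso [credible_interval()]
#' @export
eap <- function(draws) {
  colMeans(retained_matrix(draws))
}

#' Central credible intervals
#'
#' @param draws a `"dm_draws"` object.
#' @param level interval mass (default 0.95).
#' @return Matrix with rows `lower`, `upper` and one column per parameter.
#' @export
credible_interval <- function(draws, level = 0.95) {
  m <- retained_matrix(draws)
  al <- (1 - level) / 2
  out <- apply(m, 2, stats::quantile, probs = c(al, 1 - al), names = FALSE)
  rownames(out) <- c("lower", "upper")
  out
}

#' Fit a diffusion model to one participant-condition cell by DE-MCMC
#'
#' The central fitting routine: two-stage differential-evolution MCMC
#' (search, then posterior sampling with purification) with the PDA
#' likelihood — each likelihood evaluation simulates `n_sim` trials from
#' the model and scores the data under a defective kernel density
#' estimate.  Fits are intended per participant and condition; they are
#' independent and reproducible given `seed`.
#'
#' @param data `data.frame` with columns `response`
#'   (`"upper"`/`"lower"`) and `rt` in seconds, already RT-cleaned.
#' @param model `"ddm"` or `"tvddm"`.
#' @param priors a `"prior_set"`; defaults to [default_priors()].
#' @param control a [sampler_control()].
#' @param cfg a [sim_config()].
#' @param n_sim simulated trials per likelihood evaluation.
#' @param floor density floor of the KDE likelihood.
#' @param seed integer seed; governs both sampler and simulation streams.
#' @return An object of class `"dmfit"` with components `draws`
#'   (a `"dm_draws"`), `rhat`, `eap`, `ci`, the configuration, and the
#'   data.  Methods: [print.dmfit()], [summary.dmfit()], [coef.dmfit()],
#'   [plot.dmfit()], [simulate.dmfit()].
#' @export
#' @examples
#' \donttest{
#' truth <- ddm_params(A = 0.17, ter = 0.26, v = 0.25)
#' dat <- simulate_ddm(truth, 200, seed = 7)
#' fit <- fit_dm(dat, "ddm",
#'               control = sampler_control(n_chains = 8, stage1_iters = 30,
#'                                         stage2_iters = 120, burn_in = 40),
#'               n_sim = 200, seed = 1)
#' coef(fit)
#' }
fit_dm <- function(data, model = c("ddm", "tvddm"),
                   priors = default_priors(model),
                   control = sampler_control(), cfg = sim_config(),
                   n_sim = 1000, floor = 1e-10, seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), nrow(data) > 0,
            all(c("response", "rt") %in% names(data)))
  if (model == "tvddm" && is.null(control$scale_jitter))
    control$scale_jitter <- c("A", "v", "sigma2", "sv")
  data_rt <- data$rt
  data_code <- response_code(data$response)
  loglik_fn <- function(theta, sim_seed) {
    if (!params_valid(theta, model)) return(-Inf)
    pda_loglik_fast(data_rt, data_code, theta, model, n_sim, cfg,
                    floor, sim_seed)
  }
  s1 <- stage1_search(loglik_fn, priors, control, seed = seed)
  draws <- stage2_demcmc(s1, loglik_fn, priors, control,
                         seed = seed + 1L)
  structure(list(model = model, draws = draws, priors = priors,
                 control = control, cfg = cfg, n_sim = n_sim,
                 floor = floor, data = data, stage1 = s1,
                 rhat = split_rhat(draws), eap = eap(draws),
                 ci = credible_interval(draws), seed = seed,
                 call = match.call()),
            class = "dmfit")
}
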