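# shared fixtures: canonical parameter sets, toy likelihoods and small
# prior sets used across the test files

ddm_ref <- function(...) {
  args <- utils::modifyList(
    list(A = 0.17, ter = 0.26, v = 0.25, sz = 0, sv = 0, ster = 0),
    list(...))
  do.call(ddm_params, args)
}

tvddm_ref <- function(...) {
  args <- utils::modifyList(
    list(A = 0.2, ter = 0.18, v = 0.3, beta = 25, n = 5,
         sigma2 = 0.1, sv = 0.25),
    list(...))
  do.call(tvddm_params, args)
}

# wide, effectively untruncated normal priors for conjugate toys
wide_priors <- function(mu, sigma) {
  pr <- lapply(seq_along(mu), function(i)
    trunc_normal_prior(mu[i], sigma[i], mu[i] - 50 * sigma[i],
                       mu[i] + 50 * sigma[i]))
  names(pr) <- paste0("p", seq_along(mu))
  structure(pr, class = "prior_set")
}

# deterministic normal log-likelihood factory: observations y with known
# observation SD, single location parameter p1
normal_loglik <- function(y, sd_obs) {
  force(y); force(sd_obs)
  function(theta, seed) sum(dnorm(y, theta[["p1"]], sd_obs, log = TRUE))
}

# analytic log marginal likelihood of the normal-normal toy by quadrature
# over the location parameter (independent oracle).  The integrand is a
# narrow peak at the posterior mode, so the limits are set from the
# posterior (everything outside contributes ~exp(-70) of the mass).
normal_log_ml_quad <- function(y, sd_obs, prior) {
  post <- normal_posterior(y, sd_obs, prior$mu, prior$sigma)
  lo <- max(prior$lower, post$mean - 12 * post$sd)
  hi <- min(prior$upper, post$mean + 12 * post$sd)
  peak <- sum(dnorm(y, post$mean, sd_obs, log = TRUE))
  f <- function(mu) {
    exp(vapply(mu, function(m)
      sum(dnorm(y, m, sd_obs, log = TRUE)) - peak +
        dnorm(m, prior$mu, prior$sigma, log = TRUE) -
        log(pnorm(prior$upper, prior$mu, prior$sigma) -
              pnorm(prior$lower, prior$mu, prior$sigma)),
      numeric(1)))
  }
  peak + log(integrate(f, lo, hi, rel.tol = 1e-10)$value)
}

# closed-form posterior of the normal-normal toy (prior treated as normal;
# truncation negligible at 50 sigma)
normal_posterior <- function(y, sd_obs, mu0, sd0) {
  n <- length(y)
  prec <- 1 / sd0^2 + n / sd_obs^2
  list(mean = (mu0 / sd0^2 + sum(y) / sd_obs^2) / prec,
       sd = sqrt(1 / prec))
}
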