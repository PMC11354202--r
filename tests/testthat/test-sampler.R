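# priors, two-stage DE-MCMC on analytic targets, diagnostics

test_that("truncated-normal log prior normalizes and bounds", {
  pr <- default_priors("ddm")
  theta <- prior_means(pr)
  expect_true(is.finite(log_prior(theta, pr)))
  theta["A"] <- -0.01
  expect_identical(log_prior(theta, pr), -Inf)
  # numerical normalization of one marginal over its support
  one <- trunc_normal_prior(0.26, 0.26, 0, Inf)
  f <- function(x) exp(vapply(x, function(xx)
    log_prior(c(p1 = xx), structure(list(p1 = one), class = "prior_set")),
    numeric(1)))
  expect_equal(integrate(f, 0, 10, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
})

test_that("stage-1 search finds the mode of a deterministic posterior", {
  pr <- wide_priors(c(0.3, -1), c(1, 2))
  mode_at <- c(0.8, 0.4)
  llf <- function(theta, seed)
    -0.5 * sum((c(theta[["p1"]], theta[["p2"]]) - mode_at)^2 / 0.05^2)
  ctl <- sampler_control(n_chains = 10, stage1_iters = 200,
                         stage2_iters = 10, burn_in = 2,
                         purify_prob = 0)
  s1 <- stage1_search(llf, pr, ctl, seed = 4)
  best <- which.max(s1$log_prior + s1$log_lik)
  lp_best <- s1$log_prior[best] + s1$log_lik[best]
  lp_mode <- log_prior(setNames(mode_at, c("p1", "p2")), pr) +
    llf(c(p1 = mode_at[1], p2 = mode_at[2]), 1)
  expect_lt(abs(lp_best - lp_mode), 1e-3)
  # greedy acceptance: best posterior is non-decreasing over generations
  expect_true(all(diff(s1$trace_best) >= 0))
  # seed determinism
  s1b <- stage1_search(llf, pr, ctl, seed = 4)
  expect_identical(s1$pop, s1b$pop)
})

test_that("stage 2 recovers the prior when the likelihood is flat", {
  pr <- structure(list(p1 = trunc_normal_prior(0.5, 0.2, 0, 1),
                       p2 = trunc_normal_prior(2, 1, 0, Inf)),
                  class = "prior_set")
  llf <- function(theta, seed) 0
  ctl <- sampler_control(n_chains = 12, stage1_iters = 1,
                         stage2_iters = 2000, burn_in = 200,
                         purify_prob = 0, redisperse = FALSE)
  set.seed(6)
  init <- list(pop = sample_prior(pr, 12),
               log_prior = rep(0, 12), log_lik = rep(0, 12))
  init$log_prior <- apply(init$pop, 1, log_prior, priors = pr)
  dr <- stage2_demcmc(init, llf, pr, ctl, seed = 6)
  m <- tvddm:::retained_matrix(dr)
  # analytic moments of the truncated normals
  tn_mom <- function(mu, s, a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    z <- pnorm(be) - pnorm(al)
    hd <- function(x) ifelse(is.finite(x), x * dnorm(x), 0)
    mean <- mu + s * (dnorm(al) - dnorm(be)) / z
    v <- s^2 * (1 + (hd(al) - hd(be)) / z -
                  ((dnorm(al) - dnorm(be)) / z)^2)
    c(mean, sqrt(v))
  }
  m1 <- tn_mom(0.5, 0.2, 0, 1)
  m2 <- tn_mom(2, 1, 0, Inf)
  # MC error assessed from between-chain spread of chain means
  ch_means <- apply(dr$samples[, 201:2000, "p1"], 1, mean)
  se1 <- sd(ch_means) / sqrt(length(ch_means))
  expect_lt(abs(mean(m[, "p1"]) - m1[1]), 4 * se1 + 0.01)
  expect_equal(sd(m[, "p1"]), m1[2], tolerance = 0.1)
  expect_equal(mean(m[, "p2"]), m2[1], tolerance = 0.1)
  expect_equal(sd(m[, "p2"]), m2[2], tolerance = 0.15)
  # every retained draw respects the truncation bounds
  expect_true(all(m[, "p1"] >= 0 & m[, "p1"] <= 1))
  expect_true(all(m[, "p2"] >= 0))
})

test_that("stage 2 matches the conjugate normal-normal posterior", {
  set.seed(12)
  y <- rnorm(25, 0.7, 0.5)
  pr <- wide_priors(0.2, 1)
  llf <- normal_loglik(y, 0.5)
  post <- normal_posterior(y, 0.5, 0.2, 1)
  ctl <- sampler_control(n_chains = 8, stage1_iters = 50,
                         stage2_iters = 2500, burn_in = 500,
                         purify_prob = 0, redisperse = FALSE)
  s1 <- stage1_search(llf, pr, ctl, seed = 9)
  dr <- stage2_demcmc(s1, llf, pr, ctl, seed = 10)
  m <- tvddm:::retained_matrix(dr)[, 1]
  ch_means <- apply(dr$samples[, 501:2500, 1], 1, mean)
  se <- sd(ch_means) / sqrt(length(ch_means))
  expect_lt(abs(mean(m) - post$mean), 4 * se + 0.005)
  expect_equal(sd(m), post$sd, tolerance = 0.1)
  # acceptance strictly inside (0, 1)
  expect_gt(dr$acc_rate, 0)
  expect_lt(dr$acc_rate, 1)
  # thinned draws pass a KS test against the closed-form posterior
  thin <- m[seq(1, length(m), by = 40)]
  ks <- suppressWarnings(ks.test(thin, pnorm, post$mean, post$sd))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampler bookkeeping matches the configured draw counts", {
  pr <- wide_priors(0, 1)
  llf <- function(theta, seed) 0
  ctl <- sampler_control(n_chains = 30, stage1_iters = 1,
                         stage2_iters = 3000, burn_in = 500,
                         purify_prob = 0, redisperse = FALSE)
  set.seed(3)
  init <- list(pop = sample_prior(pr, 30), log_prior = rep(0, 30),
               log_lik = rep(0, 30))
  init$log_prior <- apply(init$pop, 1, log_prior, priors = pr)
  dr <- stage2_demcmc(init, llf, pr, ctl, seed = 3)
  expect_identical(dr$n_generated, 90000L)
  expect_identical(dr$n_retained, 75000L)
  expect_identical(dim(dr$samples), c(30L, 3000L, 1L))
})

test_that("split R-hat flags divergence and passes convergent chains", {
  set.seed(31)
  conv <- array(rnorm(8 * 2000), c(8, 2000, 1),
                dimnames = list(NULL, NULL, "p1"))
  expect_lt(split_rhat(conv, burn_in = 0)["p1"], 1.01)
  div <- conv
  div[1:4, , 1] <- div[1:4, , 1] + 10
  expect_gt(split_rhat(div, burn_in = 0)["p1"], 2)
  flat <- array(1, c(4, 100, 1))
  expect_error(split_rhat(flat, burn_in = 0), "degenerate")
})

test_that("EAP and credible intervals summarize the draws", {
  set.seed(41)
  a <- array(rnorm(6 * 1000, 2, 0.5), c(6, 1000, 1),
             dimnames = list(NULL, NULL, "p1"))
  dr <- structure(list(samples = a, burn_in = 0, par_names = "p1"),
                  class = "dm_draws")
  expect_equal(unname(eap(dr)), 2, tolerance = 0.03)
  expect_equal(unname(eap(dr)),
               unname(median(tvddm:::retained_matrix(dr))),
               tolerance = 0.03)
  const <- structure(list(samples = array(3, c(4, 100, 1),
                                          dimnames = list(NULL, NULL, "c")),
                          burn_in = 10, par_names = "c"),
                     class = "dm_draws")
  expect_equal(unname(eap(const)), 3)
  ci <- credible_interval(dr)
  expect_equal(unname(ci["lower", 1]), qnorm(0.025, 2, 0.5),
               tolerance = 0.05)
  expect_equal(unname(ci["upper", 1]), qnorm(0.975, 2, 0.5),
               tolerance = 0.05)
})
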