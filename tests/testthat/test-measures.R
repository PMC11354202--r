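# distributional measures, repeated-measures ANOVA, overlap indicator

test_that("CDF quantiles follow the 17-level grid", {
  set.seed(1)
  u <- runif(1e5)
  q <- cdf_quantiles(u)
  expect_length(q, 17)
  expect_true(all(diff(q) >= 0))
  expect_equal(unname(q), seq(0.10, 0.90, by = 0.05), tolerance = 0.01)
  expect_equal(unname(cdf_quantiles(rep(0.4, 20))), rep(0.4, 17))
  expect_error(cdf_quantiles(runif(10)), "17")
})

test_that("CAF bins trials into five quantile bands", {
  all_correct <- data.frame(rt = runif(200, 0.3, 1), correct = TRUE)
  cf <- caf(all_correct)
  expect_identical(nrow(cf), 5L)
  expect_equal(cf$accuracy, rep(1, 5))
  expect_equal(cf$level, seq(0.1, 0.9, by = 0.2))
  expect_true(all(diff(cf$rt) > 0))
  # coin-flip correctness independent of RT: band accuracy ~ overall
  set.seed(5)
  n <- 4000
  ind <- data.frame(rt = rexp(n, 2), correct = runif(n) < 0.7)
  cf2 <- caf(ind)
  se <- sqrt(0.7 * 0.3 / (n / 5))
  expect_true(all(abs(cf2$accuracy - mean(ind$correct)) < 3 * se + 0.01))
  expect_error(caf(all_correct[1:5, ]), "10")
})

test_that("model summaries reflect accuracy regimes", {
  easy <- ddm_params(A = 1.2, ter = 0.2, v = 1.5)
  s <- model_summary(easy, n_trials = 2000, seed = 2)
  expect_lt(s$error_rate, 0.01)
  guess <- ddm_params(A = 0.17, ter = 0.2, v = 0)
  s0 <- model_summary(guess, n_trials = 4000, seed = 3)
  expect_equal(s0$error_rate, 0.5, tolerance = 0.03)
  # CDF equals the quantile operation on the same simulated trials
  tr <- simulate_dm(easy, 2000, sim_config(), seed = 2)
  tr <- tr[tr$response != "timeout", ]
  expect_equal(s$cdf_rts, unname(cdf_quantiles(tr$rt)))
})

test_that("repeated-measures ANOVA matches a manual sums-of-squares oracle", {
  # textbook 3-condition within-participant table
  vals <- matrix(c(45, 50, 55,
                   42, 44, 49,
                   36, 41, 43,
                   39, 35, 40,
                   51, 55, 59), nrow = 5, byrow = TRUE)
  res <- rm_anova(vals)
  n <- nrow(vals); k <- ncol(vals)
  grand <- mean(vals)
  ss_cond <- n * sum((colMeans(vals) - grand)^2)
  ss_subj <- k * sum((rowMeans(vals) - grand)^2)
  ss_tot <- sum((vals - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_oracle <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_identical(c(res$df1, res$df2), c(k - 1, (k - 1) * (n - 1)))
  expect_equal(res$p, pf(f_oracle, k - 1, (k - 1) * (n - 1),
                         lower.tail = FALSE), tolerance = 1e-10)
  # location invariance
  expect_equal(rm_anova(vals + 100)$F, res$F, tolerance = 1e-8)
  # identical conditions: no effect
  same <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  r0 <- rm_anova(same)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  expect_error(rm_anova(vals[1:2, ]), "participants")
})

test_that("posterior overlap indicator is calibrated and decisive", {
  set.seed(11)
  n_part <- 8; n_cond <- 4
  null_draws <- lapply(1:n_part, function(i) {
    mu <- rnorm(1, 0, 1)   # participant effect, shared across conditions
    lapply(1:n_cond, function(j) rnorm(400, mu, 0.5))
  })
  ov <- posterior_overlap(null_draws, n_reps = 400, seed = 1)
  expect_lte(ov$proportion_significant, 0.10)
  expect_false(ov$decision)
  sep_draws <- lapply(1:n_part, function(i)
    lapply(1:n_cond, function(j) rnorm(400, 10 * j, 0.5)))
  ov2 <- posterior_overlap(sep_draws, n_reps = 200, seed = 2)
  expect_equal(ov2$proportion_significant, 1.0)
  expect_true(ov2$decision)
})

test_that("credible bands shrink with posterior precision", {
  set.seed(21)
  mk_draws <- function(sd_post) {
    a <- array(NA_real_, c(4, 300, 6),
               dimnames = list(NULL, NULL, par_names("ddm")))
    base <- unlist(ddm_ref(sz = 0.02, sv = 0.05, ster = 0.1))
    for (p in seq_len(6))
      a[, , p] <- pmax(rnorm(4 * 300, base[p], sd_post * base[p]), 1e-4)
    structure(list(samples = a, burn_in = 50,
                   par_names = par_names("ddm")),
              class = "dm_draws")
  }
  wide <- credible_band(list(mk_draws(0.2), mk_draws(0.2)), model = "ddm",
                        n_samples = 60, n_trials = 300, seed = 3)
  tight <- credible_band(list(mk_draws(0.02), mk_draws(0.02)),
                         model = "ddm", n_samples = 60, n_trials = 300,
                         seed = 3)
  expect_gt(mean(wide$upper - wide$lower),
            mean(tight$upper - tight$lower))
  # degenerate posterior (one repeated draw) gives zero-width bands
  degen <- mk_draws(0)
  b0 <- credible_band(list(degen), model = "ddm", n_samples = 30,
                      n_trials = 300, seed = 4)
  expect_equal(b0$upper, b0$lower, tolerance = 1e-12)
})

test_that("integration time inverts the growth function", {
  expect_equal(integration_time(25, 1), -log(0.03) / 25, tolerance = 1e-5)
  # quadrature + bisection oracle for the reference setting
  expect_equal(integration_time(25, 5, 0.97), qgamma(0.97, 5) / 25,
               tolerance = 1e-5)
  # frozen regression value for the reference setting (quadrature +
  # bisection oracle)
  expect_equal(integration_time(25, 5, 0.97), 0.398438, tolerance = 1e-4)
  expect_lt(integration_time(50, 5), integration_time(25, 5))
})
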