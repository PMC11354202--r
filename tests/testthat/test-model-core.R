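# forward simulators and the evidence growth function

test_that("growth function matches its definition and closed forms", {
  # n = 1 closed form: 1 - exp(-beta t)
  expect_equal(growth_theta(0, 25, 5), 0)
  expect_equal(growth_theta(0.1, 25, 1), 1 - exp(-2.5), tolerance = 1e-12)
  # adaptive-quadrature evaluation of the incomplete-gamma integral
  quad_theta <- function(t, beta, n) {
    if (t == 0) return(0)
    integrate(function(s) exp(-s) * s^(n - 1), 0, beta * t,
              rel.tol = 1e-12)$value / gamma(n)
  }
  grid <- expand.grid(t = c(0.01, 0.05, 0.2, 0.5, 2),
                      beta = c(3, 25, 80), n = c(0.5, 1, 5, 9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_lt(abs(growth_theta(g$t, g$beta, g$n) -
                    quad_theta(g$t, g$beta, g$n)), 1e-10)
  }
  # non-decreasing in t, vectorized
  th <- growth_theta(seq(0, 1, by = 0.01), 25, 5)
  expect_true(all(diff(th) >= 0))
  expect_error(growth_theta(0.1, -1, 5))
  expect_error(growth_theta(0.1, 25, 0))
  expect_error(growth_theta(-0.1, 25, 5))
})

test_that("between-trial variability has the stated distributions", {
  p0 <- ddm_ref()
  expect_equal(unlist(sample_trial_variability(p0, 3)[, c("z", "v_trial",
                                                          "ter_trial")]),
               unlist(data.frame(z = rep(0.085, 3), v_trial = rep(0.25, 3),
                                 ter_trial = rep(0.26, 3))),
               ignore_attr = TRUE)
  p <- ddm_ref(sz = 0.05, sv = 0.07, ster = 0.28)
  set.seed(1)
  s <- sample_trial_variability(p, 1e5)
  expect_lt(abs(mean(s$z) - p$A / 2), 4 * p$sz / sqrt(12) / sqrt(1e5))
  expect_equal(sd(s$v_trial), 0.07, tolerance = 0.02)
  expect_true(all(s$z > 0 & s$z < p$A))
  expect_true(all(s$ter_trial >= 0))
})

test_that("DDM upper-boundary probability matches the closed form", {
  # settings spanning negative, zero and positive drift
  cases <- list(c(A = 0.17, v = 0.25), c(A = 0.17, v = -0.25),
                c(A = 0.17, v = 0), c(A = 0.1, v = 0.3),
                c(A = 0.25, v = -0.1), c(A = 0.17, v = 0.08))
  # the Euler scheme overshoots the boundaries; the closed form for the
  # discretized process widens each boundary by 0.5826 * sigma * sqrt(dt)
  # (continuity correction), after which agreement is at Monte-Carlo level
  cc <- 0.5826 * 0.1 * sqrt(0.001)
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    p <- ddm_ref(A = cs[["A"]], v = cs[["v"]])
    tr <- simulate_ddm(p, 1e5, seed = 100 + k)
    phat <- mean(tr$response == "upper")
    ptrue <- wiener_p_upper(cs[["A"]] + 2 * cc, cs[["v"]],
                            z = cs[["A"]] / 2 + cc)
    se <- sqrt(ptrue * (1 - ptrue) / 1e5)
    expect_lt(abs(phat - ptrue), 3 * se + 0.001)
    # and the uncorrected closed form is close on an absolute scale
    expect_lt(abs(phat - wiener_p_upper(cs[["A"]], cs[["v"]])), 0.01)
  }
})

test_that("simulated response times respect the non-decision floor", {
  p <- ddm_ref(sz = 0.05, sv = 0.07, ster = 0.28)
  tr <- simulate_ddm(p, 2000, seed = 5)
  ok <- tr$response != "timeout"
  expect_true(all(tr$rt[ok] >= p$ter - p$ster / 2))
})

test_that("simulators are deterministic given the seed and per-trial streams", {
  p <- ddm_ref(sz = 0.05, sv = 0.07, ster = 0.28)
  expect_identical(simulate_ddm(p, 500, seed = 42),
                   simulate_ddm(p, 500, seed = 42))
  # trial i does not depend on how many trials were requested
  a <- simulate_ddm(p, 100, seed = 42)
  b <- simulate_ddm(p, 500, seed = 42)
  expect_identical(a$rt, b$rt[1:100])
  q <- tvddm_ref()
  expect_identical(simulate_tvddm(q, 300, seed = 7),
                   simulate_tvddm(q, 300, seed = 7))
})

test_that("TV-DDM reduces to the DDM in the instantaneous-growth limit", {
  pt <- tvddm_ref(beta = 1e6, n = 1, sigma2 = 0, sv = 0)
  pd <- ddm_ref(A = 0.2, ter = 0.18, v = 0.3)
  a <- simulate_tvddm(pt, 1e4, seed = 11)
  b <- simulate_ddm(pd, 1e4, seed = 12)
  expect_lt(abs(mean(a$response == "upper") - mean(b$response == "upper")),
            0.02)
  ks <- suppressWarnings(
    ks.test(a$rt[a$response == "upper"], b$rt[b$response == "upper"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("TV-DDM choice symmetry and delayed onset behave as expected", {
  p0 <- tvddm_ref(v = 0, sv = 0)
  tr <- simulate_tvddm(p0, 2e4, seed = 3)
  expect_lt(abs(mean(tr$response == "upper") - 0.5), 0.015)
  # gradual drift onset defers absorption relative to instantaneous drift
  pt <- tvddm_ref(sigma2 = 0, sv = 0)
  pd <- ddm_ref(A = 0.2, ter = 0.18, v = 0.3)
  slow <- simulate_tvddm(pt, 1e5, seed = 21)
  fast <- simulate_ddm(pd, 1e5, seed = 21)
  expect_gt(mean(slow$rt), mean(fast$rt))
})

test_that("halving the Euler step leaves choices and RTs stable", {
  p <- ddm_ref()
  a <- simulate_ddm(p, 1e5, cfg = sim_config(dt = 0.001), seed = 8)
  b <- simulate_ddm(p, 1e5, cfg = sim_config(dt = 0.0005), seed = 9)
  pa <- mean(a$response == "upper")
  pb <- mean(b$response == "upper")
  se_p <- sqrt(pa * (1 - pa) / 1e5)
  expect_lt(abs(pa - pb), 3 * se_p + 0.002)
  se_rt <- sd(a$rt) / sqrt(1e5)
  expect_lt(abs(mean(a$rt) - mean(b$rt)), 3 * se_rt + 0.005)
})

test_that("parameter constructors enforce the model invariants", {
  expect_error(ddm_params(A = -0.1, ter = 0.2, v = 0.2), "A must")
  expect_error(ddm_params(A = 0.1, ter = 0.2, v = 0.2, sz = 0.1), "sz")
  expect_error(ddm_params(A = 0.1, ter = 0.1, v = 0.2, ster = 0.3), "ster")
  expect_error(tvddm_params(A = 0.2, ter = 0.1, v = 0.2, beta = -1, n = 2),
               "beta")
  expect_false(params_valid(c(A = 0.1, ter = 0.2, v = 0.2, sz = 0.2,
                              sv = 0, ster = 0), "ddm"))
  expect_true(params_valid(unlist(ddm_ref()), "ddm"))
})
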