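# defective-KDE likelihood and the analytic first-passage oracle

test_that("defective KDE handles empty categories and normalizes", {
  up <- data.frame(response = rep("upper", 1000),
                   rt = rnorm(1000, 0.5, 0.05))
  kde <- build_defective_kde(up)
  # absent lower category evaluates to exactly the floor
  expect_equal(dkde_density(kde, "lower", 0.5), kde$floor)
  # the single category carries all mass and integrates to ~1
  int <- integrate(function(x) dkde_density(kde, "upper", x), 0, 5,
                   subdivisions = 500)$value
  expect_equal(int, 1, tolerance = 0.01)
  expect_error(build_defective_kde(
    data.frame(response = "timeout", rt = 10)), "degenerate")
})

test_that("KDE density agrees with a histogram oracle at the median", {
  set.seed(2)
  p <- ddm_ref()
  tr <- simulate_ddm(p, 1e4, seed = 31)
  kde <- build_defective_kde(tr)
  x <- tr$rt[tr$response == "upper"]
  med <- median(x)
  h <- hist(x, breaks = "FD", plot = FALSE)
  bin <- findInterval(med, h$breaks, all.inside = TRUE)
  oracle <- h$density[bin] * mean(tr$response == "upper")
  expect_equal(dkde_density(kde, "upper", med), oracle, tolerance = 0.15)
})

test_that("PDA log-likelihood contracts and floors as specified", {
  p <- ddm_ref()
  empty <- data.frame(response = character(0), rt = numeric(0))
  expect_identical(pda_log_likelihood(empty, p, "ddm"), 0)
  # datum far outside simulated support contributes exactly log(floor)
  far <- data.frame(response = "upper", rt = 9.9)
  expect_equal(pda_log_likelihood(far, p, "ddm", n_sim = 1000, seed = 1),
               log(1e-10))
  # invalid parameters reject
  bad <- c(A = -1, ter = 0.2, v = 0.2, sz = 0, sv = 0, ster = 0)
  dat <- simulate_ddm(p, 50, seed = 3)
  expect_identical(pda_log_likelihood(dat, bad, "ddm"), -Inf)
  # cpp and reference engines agree
  l1 <- pda_log_likelihood(dat, p, "ddm", n_sim = 1000, seed = 5,
                           engine = "cpp")
  l2 <- pda_log_likelihood(dat, p, "ddm", n_sim = 1000, seed = 5,
                           engine = "r")
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("analytic first-passage density is a proper defective density", {
  A <- 0.17; v <- 0.25; ter <- 0.26; sigma <- 0.1
  f_up <- function(t) wiener_fpt_density(t, "upper", A, v, ter, sigma)
  f_lo <- function(t) wiener_fpt_density(t, "lower", A, v, ter, sigma)
  p_up <- integrate(f_up, ter, 20, rel.tol = 1e-10)$value
  p_lo <- integrate(f_lo, ter, 20, rel.tol = 1e-10)$value
  expect_equal(p_up + p_lo, 1, tolerance = 1e-6)
  expect_equal(p_up, wiener_p_upper(A, v, sigma), tolerance = 1e-6)
  # zero drift, central start: both boundaries equally likely at every rt
  ts <- seq(0.3, 2, by = 0.1)
  expect_equal(wiener_fpt_density(ts, "upper", A, 0, ter, sigma),
               wiener_fpt_density(ts, "lower", A, 0, ter, sigma),
               tolerance = 1e-12)
  expect_equal(wiener_fpt_density(0.2, "upper", A, v, ter), 0)
})

test_that("PDA density tracks the analytic density per trial", {
  # variability-free DDM: the analytic Wiener density is exact
  p <- ddm_ref()
  dat <- simulate_ddm(p, 200, seed = 17)
  pda <- pda_log_density(dat, p, "ddm", n_sim = 2e4, seed = 55)
  ana <- log(wiener_fpt_density(dat$rt, dat$response, p$A, p$v, p$ter))
  expect_lt(mean(abs(pda - ana)), 0.1)
})

test_that("likelihood discriminates truth from displaced parameters", {
  p <- ddm_ref(sz = 0.05, sv = 0.07, ster = 0.28)
  dat <- simulate_ddm(p, 200, seed = 23)
  off <- unlist(p); off["v"] <- off["v"] * 1.5
  ll_true <- vapply(1:20, function(i)
    pda_log_likelihood(dat, p, "ddm", n_sim = 1000, seed = i), numeric(1))
  ll_off <- vapply(1:20, function(i)
    pda_log_likelihood(dat, off, "ddm", n_sim = 1000, seed = 100 + i),
    numeric(1))
  expect_gt(mean(ll_true), mean(ll_off))
})

test_that("PDA noise shrinks as the simulation count grows", {
  p <- ddm_ref(sz = 0.05, sv = 0.07, ster = 0.28)
  dat <- simulate_ddm(p, 100, seed = 29)
  sds <- vapply(c(250, 1000, 4000), function(ns) {
    sd(vapply(1:15, function(i)
      pda_log_likelihood(dat, p, "ddm", n_sim = ns, seed = 1000 * ns + i),
      numeric(1)))
  }, numeric(1))
  expect_true(sds[3] < sds[2] && sds[2] < sds[1])
})
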