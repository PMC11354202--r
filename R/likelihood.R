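#' Build a defective kernel density estimate from simulated trials
#'
#' A defective density over (response, rt): for each response category
#' present, a Gaussian-kernel KDE of the category's RTs weighted by the
#' category's choice probability (category count / total simulated trials,
#' so timeout trials absorb mass).  Categories with fewer than 2 trials
#' cannot support a kernel estimate and evaluate to the density floor.
#'
#' @param trials `data.frame` with columns `response` and `rt`, typically
#'   from [simulate_ddm()] or [simulate_tvddm()].
#' @param floor minimum density value returned by evaluation, > 0;
#'   prevents `-Inf` log-likelihood contributions from isolated data
#'   points.
#' @param bw bandwidth rule: `"adaptive"` (default; Abramson square-root
#'   per-point bandwidths from a Silverman pilot, clamped at 10x the
#'   pilot — wide kernels in sparse tails stabilize the likelihood),
#'   `"nrd0"` (fixed Silverman) or `"SJ"` (fixed Sheather-Jones).
#' @param log_rt if `TRUE`, densities are estimated on `log(rt)` and
#'   transformed back (off by default).
#' @return An object of class `"defective_kde"`.
#' @seealso [dkde_density()], [pda_log_likelihood()]
#' @export
build_defective_kde <- function(trials, floor = 1e-10,
                                bw = c("adaptive", "nrd0", "SJ"),
                                log_rt = FALSE) {
  bw <- match.arg(bw)
  stopifnot(nrow(trials) > 0, floor > 0)
  ok <- trials$response %in% c("upper", "lower")
  if (!any(ok)) stop("degenerate simulation: all trials timed out",
                     call. = FALSE)
  n_total <- nrow(trials)
  cats <- list()
  for (cat in c("upper", "lower")) {
    x <- trials$rt[trials$response == cat]
    if (length(x) < 2) next
    xs <- sort(if (log_rt) log(x) else x)
    h0 <- if (bw == "SJ") stats::bw.SJ(xs) else stats::bw.nrd0(xs)
    hv <- rep(h0, length(xs))
    if (bw == "adaptive") {
      # pilot on a 128-point grid, interpolated at the kernel centres
      # (the pilot only sets bandwidth ratios)
      grid <- if (xs[length(xs)] > xs[1])
        seq(xs[1], xs[length(xs)], length.out = 128) else xs[1] + 0:127
      pg <- pmax(vapply(grid, function(x0)
        mean(stats::dnorm(x0, xs, h0)), numeric(1)), 1e-300)
      fp <- pmax(stats::approx(grid, pg, xout = xs, rule = 2)$y, 1e-300)
      lam <- pmin(sqrt(exp(mean(log(fp))) / fp), 10)
      hv <- h0 * lam
    }
    cats[[cat]] <- list(x = xs, n = length(x), h = h0, hv = hv,
                        weight = length(x) / n_total)
  }
  structure(list(categories = cats, n_sim = sum(ok), n_total = n_total,
                 floor = floor, log_rt = log_rt, bw = bw),
            class = "defective_kde")
}

#' Evaluate a defective KDE
#'
#' Returns `weight * kernel density` of the requested response category at
#' each `rt`, floored at the KDE's density floor.
#'
#' @param kde a [build_defective_kde()] object.
#' @param response response category, `"upper"` or `"lower"` (recycled).
#' @param rt response times in seconds, >= 0.
#' @return Numeric vector of densities (1/s), each >= `floor`.
#' @export
dkde_density <- function(kde, response, rt) {
  stopifnot(inherits(kde, "defective_kde"))
  k <- max(length(response), length(rt))
  response <- rep_len(response, k)
  rt <- rep_len(rt, k)
  out <- rep(kde$floor, k)
  for (cat in names(kde$categories)) {
    comp <- kde$categories[[cat]]
    idx <- which(response == cat)
    if (!length(idx)) next
    xe <- if (kde$log_rt) log(rt[idx]) else rt[idx]
    dens <- vapply(xe, function(x0)
      mean(stats::dnorm(x0, comp$x, comp$hv)), numeric(1))
    if (kde$log_rt) dens <- dens / rt[idx]
    out[idx] <- pmax(comp$weight * dens, kde$floor)
  }
  out
}

#' @export
print.defective_kde <- function(x, ...) {
  cat("Defective KDE from", x$n_total, "simulated trials\n")
  for (cat_ in names(x$categories)) {
    comp <- x$categories[[cat_]]
    cat(sprintf("  %s: weight %.3f, n %d, bandwidth %.4g\n",
                cat_, comp$weight, comp$n, comp$h))
  }
  invisible(x)
}

#' Simulation-based (PDA) log-likelihood
#'
#' Probability density approximation: simulates `n_sim` trials from the
#' model at `params` (fresh RNG substream per call), builds a defective
#' KDE over the simulated (response, rt) pairs and returns the summed log
#' density of the data, floored at `floor` per datum.  The estimate is
#' stochastic across calls by design; the sampler's purification step
#' exists to correct for likelihoods that were overestimated by chance.
#' Parameter vectors violating the model invariants return `-Inf`.
#'
#' @param data `data.frame` with columns `response` (`"upper"`/`"lower"`)
#'   and `rt` (seconds); RTs should already be cleaned ([clean_rts()]).
#' @param params named numeric vector or `dm_params` object.
#' @param model `"ddm"` or `"tvddm"`.
#' @param n_sim simulated trials per call, >= 100 (default 1000).
#' @param cfg a [sim_config()].
#' @param floor density floor, > 0.
#' @param seed integer seed for this call's simulation substream.
#' @param engine `"cpp"` (fast path, default) or `"r"` (reference path via
#'   [build_defective_kde()]); the two agree to numerical precision for
#'   the default bandwidth rule.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
pda_log_likelihood <- function(data, params, model = c("ddm", "tvddm"),
                               n_sim = 1000, cfg = sim_config(),
                               floor = 1e-10, seed = 1L,
                               engine = c("cpp", "r"),
                               bw = c("adaptive", "nrd0")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  bw <- match.arg(bw)
  stopifnot(n_sim >= 100)
  if (nrow(data) == 0) return(0)
  theta <- unlist(params)
  if (!params_valid(theta, model)) return(-Inf)
  if (engine == "cpp") {
    return(pda_loglik_fast(data$rt, response_code(data$response), theta,
                           model, n_sim, cfg, floor, seed,
                           adaptive = (bw == "adaptive")))
  }
  sim <- simulate_dm(theta, n_sim, cfg, seed = seed, model = model)
  if (!any(sim$response %in% c("upper", "lower")))
    stop("degenerate simulation: all trials timed out", call. = FALSE)
  kde <- build_defective_kde(sim, floor = floor, bw = bw)
  sum(log(dkde_density(kde, data$response, data$rt)))
}

#' Per-datum PDA log densities
#'
#' As [pda_log_likelihood()] but returning the log defective-KDE density
#' of each data row separately (used for density-level diagnostics and
#' oracle comparisons).
#'
#' @inheritParams pda_log_likelihood
#' @return Numeric vector, one log density per data row.
#' @export
pda_log_density <- function(data, params, model = c("ddm", "tvddm"),
                            n_sim = 1000, cfg = sim_config(),
                            floor = 1e-10, seed = 1L) {
  model <- match.arg(model)
  theta <- unlist(params)
  if (!params_valid(theta, model))
    stop("invalid parameters", call. = FALSE)
  sim <- simulate_dm(theta, n_sim, cfg, seed = seed, model = model)
  cpp_kde_logdens(data$rt, response_code(data$response),
                  sim$rt, response_code(sim$response), floor)
}

# fast path: no data.frame round trip; data responses already integer-coded
# (upper = 1, lower = 0).  Assumes theta already validated.
pda_loglik_fast <- function(data_rt, data_code, theta, model, n_sim, cfg,
                            floor, seed, adaptive = TRUE) {
  sim <- if (model == "ddm") {
    cpp_sim_ddm(theta[["A"]], theta[["ter"]], theta[["v"]], theta[["sz"]],
                theta[["sv"]], theta[["ster"]], as.integer(n_sim), cfg$dt,
                cfg$sigma, cfg$max_t, cfg$attempts, as.double(seed))
  } else {
    cpp_sim_tvddm(theta[["A"]], theta[["ter"]], theta[["v"]],
                  theta[["beta"]], theta[["n"]], theta[["sigma2"]],
                  theta[["sv"]], as.integer(n_sim), cfg$dt, cfg$sigma,
                  cfg$max_t, cfg$attempts, as.double(seed))
  }
  if (!any(sim$response >= 0L))
    stop("degenerate simulation: all trials timed out", call. = FALSE)
  sum(cpp_kde_logdens(data_rt, data_code, sim$rt, sim$response, floor,
                      adaptive))
}

#' Analytic first-passage density of the variability-free DDM
#'
#' Defective density of (response, rt) for the Wiener process with drift
#' `v`, diffusion coefficient `sigma`, absorbing boundaries at 0 and `A`,
#' start point `z` and constant non-decision time `ter` (no sz/sv/ster
#' variability).  Standard small-time/large-time series representation,
#' truncated when terms fall below `1e-14` of the running sum; the faster-
#' converging series is selected per evaluation.  Serves as the
#' independent oracle for [pda_log_likelihood()].
#'
#' @param rt response times in seconds (vectorized).
#' @param response `"upper"` or `"lower"` (recycled against `rt`).
#' @param A,v,ter model parameters.
#' @param sigma diffusion coefficient (default 0.1).
#' @param z start point (default `A/2`).
#' @return Density values (1/s); 0 for `rt <= ter`.
#' @export
wiener_fpt_density <- function(rt, response, A, v, ter, sigma = 0.1,
                               z = A / 2) {
  stopifnot(A > 0, sigma > 0, z > 0, z < A)
  k <- max(length(rt), length(response))
  rt <- rep_len(rt, k)
  response <- rep_len(response, k)
  # rescale to unit diffusion: boundaries 0 and a, start z/sigma, drift v/sigma
  a <- A / sigma
  vv <- v / sigma
  w0 <- z / A
  out <- numeric(k)
  for (i in seq_len(k)) {
    t <- rt[i] - ter
    if (t <= 0) next
    # density at the *lower* boundary for drift mu, relative start w:
    # upper-boundary passage = lower passage of the reflected process
    if (response[i] == "upper") {
      mu <- -vv; w <- 1 - w0
    } else {
      mu <- vv; w <- w0
    }
    tau <- t / a^2
    out[i] <- exp(-mu * a * w - mu^2 * t / 2) / a^2 * fpt_std(tau, w)
  }
  out
}

# first-passage density at the lower boundary of a zero-drift unit-diffusion
# process on (0, 1), start w, at scaled time tau
fpt_std <- function(tau, w) {
  if (tau < 0.35) {
    # small-time series over image charges
    s <- 0
    for (j in 0:200) {
      ks <- if (j == 0) 0 else c(-j, j)
      term <- sum((w + 2 * ks) * exp(-(w + 2 * ks)^2 / (2 * tau)))
      s <- s + term
      if (j > 2 && abs(term) < 1e-14 * abs(s)) break
    }
    s / sqrt(2 * pi * tau^3)
  } else {
    s <- 0
    for (j in 1:200) {
      term <- j * exp(-j^2 * pi^2 * tau / 2) * sin(j * pi * w)
      s <- s + term
      if (j > 2 && abs(term) < 1e-14 * max(abs(s), 1e-300)) break
    }
    pi * s
  }
}
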