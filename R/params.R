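#' Parameters of the standard drift-diffusion model
#'
#' Bundles the six parameters of the two-boundary Wiener diffusion model
#' with between-trial variability: boundary separation `A` (evidence units,
#' lower boundary at 0, upper at `A`), non-decision time `ter` (s), mean
#' drift rate `v` (evidence/s), uniform start-point range `sz` (evidence
#' units, centred on `A/2`), normal drift-rate SD `sv` (evidence/s) and
#' uniform non-decision-time range `ster` (s).
#'
#' @param A boundary separation, > 0.
#' @param ter non-decision time in seconds, >= 0.
#' @param v mean drift rate (evidence per second).
#' @param sz start-point range; must satisfy `0 <= sz < A` so the sampled
#'   start point stays strictly inside `(0, A)`.
#' @param sv between-trial SD of the drift rate, >= 0.
#' @param ster non-decision-time range; must satisfy
#'   `0 <= ster <= 2 * ter` so sampled non-decision times are non-negative.
#' @return An object of class `c("ddm_params", "dm_params")`.
#' @seealso [tvddm_params()], [simulate_ddm()]
#' @export
#' @examples
#' ddm_params(A = 0.17, ter = 0.26, v = 0.25, sz = 0.05, sv = 0.07, ster = 0.28)
ddm_params <- function(A, ter, v, sz = 0, sv = 0, ster = 0) {
  theta <- c(A = A, ter = ter, v = v, sz = sz, sv = sv, ster = ster)
  msg <- params_check(theta, "ddm")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  structure(as.list(theta), class = c("ddm_params", "dm_params"))
}

#' Parameters of the time-varying drift-rate diffusion model
#'
#' The TV-DDM replaces the instantaneous drift onset of the standard model
#' with a perceptual-integration stage: drift at time `t` after stimulus
#' onset is `v * theta(t)` and the stimulus-driven diffusion grows with the
#' same growth function, `theta(t)` being the regularized lower incomplete
#' gamma function of `(n, beta * t)` (see [growth_theta()]).  A constant
#' premature-sampling noise `sigma2` is present throughout.  The model has
#' no start-point or non-decision-time variability (7 free parameters).
#'
#' @param A boundary separation, > 0.
#' @param ter non-decision time in seconds, >= 0.
#' @param v asymptotic drift rate (evidence per second).
#' @param beta evidence growth rate (1/s), > 0.
#' @param n evidence growth shape (dimensionless, real-valued), > 0;
#'   interpretable as the number of cascaded linear filters forming the
#'   percept.
#' @param sigma2 premature-sampling diffusion coefficient
#'   (evidence/sqrt(s)), >= 0.
#' @param sv between-trial SD of the drift rate, >= 0.
#' @return An object of class `c("tvddm_params", "dm_params")`.
#' @seealso [ddm_params()], [simulate_tvddm()]
#' @export
#' @examples
#' tvddm_params(A = 0.2, ter = 0.18, v = 0.3, beta = 25, n = 5,
#'              sigma2 = 0.1, sv = 0.25)
tvddm_params <- function(A, ter, v, beta, n, sigma2 = 0, sv = 0) {
  theta <- c(A = A, ter = ter, v = v, beta = beta, n = n,
             sigma2 = sigma2, sv = sv)
  msg <- params_check(theta, "tvddm")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  structure(as.list(theta), class = c("tvddm_params", "dm_params"))
}

#' @export
print.dm_params <- function(x, ...) {
  cat(if (inherits(x, "tvddm_params")) "TV-DDM" else "DDM", "parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Parameter names of a model
#'
#' @param model `"ddm"` or `"tvddm"`.
#' @return Character vector of parameter names in canonical order.
#' @export
par_names <- function(model = c("ddm", "tvddm")) {
  model <- match.arg(model)
  if (model == "ddm") c("A", "ter", "v", "sz", "sv", "ster")
  else c("A", "ter", "v", "beta", "n", "sigma2", "sv")
}

# NULL if valid, otherwise a message.  theta: named numeric vector.
params_check <- function(theta, model) {
  p <- par_names(model)
  theta <- unlist(theta)
  if (!all(p %in% names(theta))) {
    return(paste0("missing parameters: ",
                  paste(setdiff(p, names(theta)), collapse = ", ")))
  }
  theta <- theta[p]
  if (any(!is.finite(theta))) return("all parameters must be finite")
  if (theta["A"] <= 0) return("A must be > 0")
  if (theta["ter"] < 0) return("ter must be >= 0")
  if (theta["sv"] < 0) return("sv must be >= 0")
  if (model == "ddm") {
    if (theta["sz"] < 0 || theta["sz"] >= theta["A"])
      return("sz must satisfy 0 <= sz < A")
    if (theta["ster"] < 0 || theta["ster"] > 2 * theta["ter"])
      return("ster must satisfy 0 <= ster <= 2*ter")
  } else {
    if (theta["beta"] <= 0) return("beta must be > 0")
    if (theta["n"] <= 0) return("n must be > 0")
    if (theta["sigma2"] < 0) return("sigma2 must be >= 0")
  }
  NULL
}

#' Check whether a parameter vector satisfies the model invariants
#'
#' Used by the sampler: proposals violating an invariant (for instance a
#' negative boundary, `sz >= A`, or `ster > 2*ter`) receive log-likelihood
#' `-Inf` rather than an error.
#'
#' @param theta named numeric vector (or `dm_params` object).
#' @param model `"ddm"` or `"tvddm"`.
#' @return `TRUE` or `FALSE`.
#' @export
params_valid <- function(theta, model = c("ddm", "tvddm")) {
  model <- match.arg(model)
  is.null(params_check(theta, model))
}

# coerce a named vector to the right dm_params class without re-validating
as_dm_params <- function(theta, model) {
  theta <- as.list(unlist(theta)[par_names(model)])
  class(theta) <- c(paste0(model, "_params"), "dm_params")
  theta
}

#' Simulation settings for the Euler scheme
#'
#' Both models are integrated in seconds by Euler's method with a fixed
#' step `dt` (default 1 ms) and diffusion coefficient `sigma` (default
#' 0.1).  Trials whose accumulator has not been absorbed by `max_t` are
#' re-simulated up to `attempts` times and then recorded as timeouts;
#' timeouts are excluded from kernel density construction.
#'
#' @param dt Euler integration step in seconds, > 0.
#' @param sigma diffusion coefficient (evidence/sqrt(s)), > 0.
#' @param max_t per-trial decision-time cap in seconds, > `dt`.
#' @param attempts re-simulation attempts for timed-out trials, >= 1.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 0.001, sigma = 0.1, max_t = 10, attempts = 10L) {
  stopifnot(dt > 0, sigma > 0, max_t > dt, attempts >= 1)
  structure(list(dt = dt, sigma = sigma, max_t = max_t,
                 attempts = as.integer(attempts)),
            class = "sim_config")
}

#' Evidence growth function of the TV-DDM
#'
#' The fraction of the perceptual representation formed `t` seconds after
#' stimulus onset: the regularized lower incomplete gamma function
#' `P(n, beta * t)`.  It rises from 0 at `t = 0` to 1 asymptotically, and
#' for `n = 1` reduces to `1 - exp(-beta * t)`.
#'
#' @param t time since stimulus onset in seconds, >= 0 (vectorized).
#' @param beta growth rate (1/s), > 0.
#' @param n growth shape, > 0.
#' @return Numeric vector of values in `[0, 1]`.
#' @export
#' @examples
#' growth_theta(c(0, 0.1, 0.3), beta = 25, n = 5)
growth_theta <- function(t, beta, n) {
  if (length(beta) != 1 || length(n) != 1 || !is.finite(beta) ||
      !is.finite(n) || beta <= 0 || n <= 0)
    stop("beta and n must be single positive numbers", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  stats::pgamma(beta * t, shape = n)
}

#' Draw the between-trial components of a DDM trial
#'
#' Start point `z ~ Uniform(A/2 - sz/2, A/2 + sz/2)`, drift
#' `v_trial ~ Normal(v, sv)` and non-decision time
#' `ter_trial ~ Uniform(ter - ster/2, ter + ster/2)`, using R's global RNG.
#' With all variability parameters at 0 this returns `(A/2, v, ter)`
#' exactly.  (The simulators draw their own variability internally from
#' dedicated per-trial substreams; this function exposes the distributions
#' for inspection.)
#'
#' @param params a [ddm_params()] object.
#' @param n number of draws.
#' @return `data.frame` with columns `z`, `v_trial`, `ter_trial`.
#' @export
sample_trial_variability <- function(params, n = 1) {
  stopifnot(inherits(params, "ddm_params"))
  data.frame(
    z = params$A / 2 + params$sz * (stats::runif(n) - 0.5),
    v_trial = stats::rnorm(n, params$v, params$sv),
    ter_trial = params$ter + params$ster * (stats::runif(n) - 0.5)
  )
}
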