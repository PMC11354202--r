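#' Simulate trials from the standard DDM
#'
#' Euler integration of the Wiener process `dx = v dt + sigma dW` from the
#' start point to absorption at 0 (lower) or `A` (upper).  The reported
#' response time is decision time plus the trial's non-decision time.
#' Trials are deterministic given `seed`; trial `i` uses its own RNG
#' substream, so its outcome does not depend on `n_trials`.
#'
#' @param params a [ddm_params()] object.
#' @param n_trials number of trials, >= 1.
#' @param cfg a [sim_config()].
#' @param seed integer seed for the simulator's own RNG.
#' @return `data.frame` with columns `trial`, `response`
#'   (`"upper"`, `"lower"` or `"timeout"`) and `rt` (seconds).
#' @seealso [simulate_tvddm()]
#' @export
#' @examples
#' p <- ddm_params(A = 0.17, ter = 0.26, v = 0.25)
#' head(simulate_ddm(p, 10, seed = 1))
simulate_ddm <- function(params, n_trials, cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "ddm_params"), n_trials >= 1)
  res <- cpp_sim_ddm(params$A, params$ter, params$v, params$sz, params$sv,
                     params$ster, as.integer(n_trials), cfg$dt, cfg$sigma,
                     cfg$max_t, cfg$attempts, as.double(seed))
  trials_frame(res, n_trials)
}

#' Simulate trials from the TV-DDM
#'
#' Euler integration of the time-varying accumulator
#' `dx = v * theta(t) dt + sqrt(sigma^2 * theta(t) + sigma2^2) dW`,
#' where `theta` is the evidence growth function ([growth_theta()])
#' evaluated on the within-trial clock (time since stimulus onset,
#' excluding non-decision time).  Start point is fixed at `A/2` and
#' non-decision time is fixed at `ter`.
#'
#' @inheritParams simulate_ddm
#' @param params a [tvddm_params()] object.
#' @return `data.frame` with columns `trial`, `response`, `rt`.
#' @seealso [simulate_ddm()], [growth_theta()]
#' @export
simulate_tvddm <- function(params, n_trials, cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "tvddm_params"), n_trials >= 1)
  res <- cpp_sim_tvddm(params$A, params$ter, params$v, params$beta, params$n,
                       params$sigma2, params$sv, as.integer(n_trials),
                       cfg$dt, cfg$sigma, cfg$max_t, cfg$attempts,
                       as.double(seed))
  trials_frame(res, n_trials)
}

#' Simulate trials from either model
#'
#' Dispatches on the class of `params` (or on `model` when `params` is a
#' plain named vector, as inside the sampler).
#'
#' @inheritParams simulate_ddm
#' @param params a `dm_params` object or named numeric vector.
#' @param model model name; only needed when `params` is a plain vector.
#' @return `data.frame` with columns `trial`, `response`, `rt`.
#' @export
simulate_dm <- function(params, n_trials, cfg = sim_config(), seed = 1L,
                        model = NULL) {
  if (!inherits(params, "dm_params")) {
    stopifnot(!is.null(model))
    params <- as_dm_params(params, model)
  }
  if (inherits(params, "tvddm_params")) {
    simulate_tvddm(params, n_trials, cfg, seed)
  } else {
    simulate_ddm(params, n_trials, cfg, seed)
  }
}

trials_frame <- function(res, n_trials) {
  data.frame(
    trial = seq_len(n_trials),
    response = c("timeout", "lower", "upper")[res$response + 2L],
    rt = res$rt,
    stringsAsFactors = FALSE
  )
}

# integer coding used by the C++ kernels: upper = 1, lower = 0, timeout = -1
response_code <- function(response) {
  code <- rep(NA_integer_, length(response))
  code[response == "upper"] <- 1L
  code[response == "lower"] <- 0L
  code[response == "timeout"] <- -1L
  if (anyNA(code)) stop("unknown response code", call. = FALSE)
  code
}

#' Closed-form absorption probability of a drifted Wiener process
#'
#' Probability that diffusion with drift `v` and coefficient `sigma`,
#' started at `z` between absorbing boundaries 0 and `A`, is absorbed at
#' the upper boundary: `(1 - exp(-2 v z / sigma^2)) /
#' (1 - exp(-2 v A / sigma^2))`, with the `v = 0` limit `z / A`.
#' Used as an independent check on the simulators.
#'
#' @param A,v,sigma boundary separation, drift, diffusion coefficient.
#' @param z start point (defaults to `A/2`).
#' @return Probability of an upper-boundary response.
#' @export
wiener_p_upper <- function(A, v, sigma = 0.1, z = A / 2) {
  stopifnot(A > 0, sigma > 0, z > 0, z < A)
  if (abs(v) < 1e-12) return(z / A)
  k <- 2 * v / sigma^2
  expm1(-k * z) / expm1(-k * A)
}
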