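#' Truncated-normal prior specification
#'
#' @param mu,sigma location and scale of the underlying normal, `sigma > 0`.
#' @param lower,upper truncation bounds, `lower < upper`.
#' @return An object of class `"truncnorm_prior"`.
#' @export
trunc_normal_prior <- function(mu, sigma, lower = 0, upper = Inf) {
  stopifnot(sigma > 0, lower < upper)
  structure(list(mu = mu, sigma = sigma, lower = lower, upper = upper),
            class = "truncnorm_prior")
}

#' @export
print.truncnorm_prior <- function(x, ...) {
  cat(sprintf("TN(%g, %g, %g, %g)\n", x$mu, x$sigma, x$lower, x$upper))
  invisible(x)
}

# log normalizing constant of the truncation
tn_log_z <- function(pr) {
  log(stats::pnorm(pr$upper, pr$mu, pr$sigma) -
        stats::pnorm(pr$lower, pr$mu, pr$sigma))
}

tn_log_density <- function(x, pr) {
  ifelse(x < pr$lower | x > pr$upper, -Inf,
         stats::dnorm(x, pr$mu, pr$sigma, log = TRUE) - tn_log_z(pr))
}

tn_sample <- function(n, pr) {
  plo <- stats::pnorm(pr$lower, pr$mu, pr$sigma)
  phi <- stats::pnorm(pr$upper, pr$mu, pr$sigma)
  stats::qnorm(plo + (phi - plo) * stats::runif(n), pr$mu, pr$sigma)
}

#' Default priors for each model
#'
#' Truncated-normal priors with mean equal to scale and lower truncation
#' at 0 for every parameter, centred on plausible values for noisy
#' two-choice perceptual data (DDM: A 0.17, ter 0.26, v 0.25, sz 0.05,
#' sv 0.07, ster 0.28; TV-DDM: A 0.2, ter 0.18, v 0.3, sigma2 0.1,
#' sv 0.25, beta 25, n 5).
#'
#' @param model `"ddm"` or `"tvddm"`.
#' @return Named list of [trunc_normal_prior()] objects, one per model
#'   parameter, of class `"prior_set"`.
#' @export
default_priors <- function(model = c("ddm", "tvddm")) {
  model <- match.arg(model)
  tn <- function(m) trunc_normal_prior(m, m, 0, Inf)
  pr <- if (model == "ddm") {
    list(A = tn(0.17), ter = tn(0.26), v = tn(0.25),
         sz = tn(0.05), sv = tn(0.07), ster = tn(0.28))
  } else {
    list(A = tn(0.2), ter = tn(0.18), v = tn(0.3), beta = tn(25),
         n = tn(5), sigma2 = tn(0.1), sv = tn(0.25))
  }
  structure(pr, class = "prior_set")
}

#' Prior means of a prior set
#'
#' Location parameters `mu` of each marginal prior (note: not the means of
#' the truncated distributions).
#'
#' @param priors a `"prior_set"` (named list of [trunc_normal_prior()]).
#' @return Named numeric vector.
#' @export
prior_means <- function(priors) {
  vapply(priors, function(p) p$mu, numeric(1))
}

#' Joint log prior density
#'
#' Sum of truncated-normal log densities (with the correct truncation
#' normalizer); `-Inf` for any parameter outside its bounds.
#'
#' @param theta named numeric vector of parameters.
#' @param priors named list of [trunc_normal_prior()] covering every
#'   element of `theta`.
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors) {
  theta <- unlist(theta)
  if (!all(names(priors) %in% names(theta)))
    stop("theta must contain every prior parameter", call. = FALSE)
  s <- 0
  for (nm in names(priors)) {
    s <- s + tn_log_density(theta[[nm]], priors[[nm]])
    if (!is.finite(s)) return(-Inf)
  }
  s
}

#' Draw parameter vectors from a prior set
#'
#' @param priors a `"prior_set"`.
#' @param n number of draws.
#' @return `n` x d matrix with parameter columns, using R's global RNG.
#' @export
sample_prior <- function(priors, n = 1) {
  m <- vapply(priors, function(p) tn_sample(n, p), numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(priors)))
  m
}
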