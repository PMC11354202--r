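#' @export
print.dmfit <- function(x, ...) {
  cat(sprintf("%s fit by two-stage DE-MCMC (PDA likelihood, n_sim = %d)\n",
              toupper(x$model), x$n_sim))
  cat(sprintf("  data: %d trials; chains: %d; generations: %d (burn-in %d)\n",
              nrow(x$data), x$control$n_chains, x$control$stage2_iters,
              x$control$burn_in))
  cat(sprintf("  max split R-hat: %.3f (criterion 1.1)\n", max(x$rhat)))
  cat("  EAP estimates:\n")
  print(round(x$eap, 4))
  invisible(x)
}

#' Summarize a fitted diffusion model
#'
#' @param object a [fit_dm()] result.
#' @param level credible-interval mass.
#' @param ... unused.
#' @return A `summary.dmfit` object: per-parameter EAP, posterior SD,
#'   central credible interval and split R-hat.
#' @export
summary.dmfit <- function(object, level = 0.95, ...) {
  m <- retained_matrix(object$draws)
  ci <- credible_interval(object$draws, level)
  tab <- cbind(eap = colMeans(m), sd = apply(m, 2, stats::sd),
               lower = ci["lower", ], upper = ci["upper", ],
               rhat = object$rhat)
  structure(list(model = object$model, table = tab, level = level,
                 n_trials = nrow(object$data),
                 acc_rate = object$draws$acc_rate,
                 n_purify = object$draws$n_purify,
                 n_retained = object$draws$n_retained),
            class = "summary.dmfit")
}

#' @export
print.summary.dmfit <- function(x, ...) {
  cat(sprintf("%s posterior summary (%d trials, %d retained draws)\n",
              toupper(x$model), x$n_trials, x$n_retained))
  cat(sprintf("  acceptance rate %.2f, purifications %d\n",
              x$acc_rate, x$n_purify))
  print(round(x$table, 4))
  invisible(x)
}

#' Point estimates (EAPs) of a fitted diffusion model
#'
#' @param object a [fit_dm()] result.
#' @param ... unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.dmfit <- function(object, ...) object$eap

#' Trace and marginal-density plots for a fitted diffusion model
#'
#' One row per parameter: chain traces (burn-in shaded region left of the
#' dashed line) and the marginal posterior density of the retained draws.
#'
#' @param x a [fit_dm()] result.
#' @param pars parameters to plot (default all).
#' @param ... unused.
#' @return Invisibly, `x`.
#' @export
plot.dmfit <- function(x, pars = x$draws$par_names, ...) {
  a <- x$draws$samples
  old <- graphics::par(mfrow = c(length(pars), 2),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::matplot(t(a[, , p]), type = "l", lty = 1,
                      col = grDevices::grey(0.2, 0.35),
                      xlab = "", ylab = p, main = "")
    graphics::abline(v = x$draws$burn_in, lty = 2)
    dens <- stats::density(retained_matrix(x$draws)[, p])
    plot(dens, main = "", xlab = "", ylab = paste0("p(", p, "|D)"))
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fitted diffusion model
#'
#' Simulates `nsim` trials from the model at the EAP estimates (default)
#' or at parameter vectors drawn from the posterior.
#'
#' @param object a [fit_dm()] result.
#' @param nsim number of trials to simulate.
#' @param seed integer simulation seed.
#' @param posterior if `TRUE`, each trial's parameters are a fresh
#'   posterior draw; if `FALSE` (default) all trials use the EAPs.
#' @param ... unused.
#' @return `data.frame` of trials as from [simulate_ddm()].
#' @export
simulate.dmfit <- function(object, nsim = 2000, seed = 1L,
                           posterior = FALSE, ...) {
  if (!posterior) {
    return(simulate_dm(object$eap, nsim, object$cfg, seed = seed,
                       model = object$model))
  }
  m <- retained_matrix(object$draws)
  set.seed(seed)
  idx <- sample.int(nrow(m), nsim, replace = TRUE)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    out[[i]] <- simulate_dm(m[idx[i], ], 1, object$cfg,
                            seed = seed + i, model = object$model)
  }
  res <- do.call(rbind, out)
  res$trial <- seq_len(nsim)
  res
}
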