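#' RT distribution quantiles (CDF measure)
#'
#' Empirical RT quantiles at the 17 probability levels 10%, 15%, ..., 90%
#' (linear-interpolation, type-7 estimator).
#'
#' @param rts response times in seconds; at least 17 values.
#' @return Named numeric vector of 17 RTs, non-decreasing.
#' @export
cdf_quantiles <- function(rts) {
  if (length(rts) < 17)
    stop("need at least 17 observations for the CDF measure", call. = FALSE)
  stats::quantile(rts, probs = cdf_levels(), type = 7)
}

cdf_levels <- function() seq(0.10, 0.90, by = 0.05)
caf_levels <- function() seq(0.10, 0.90, by = 0.20)

#' Conditional accuracy function (CAF)
#'
#' Trials (correct and error pooled) are binned by the RT-quantile bands
#' `[0-20%)`, `[20-40%)`, ..., `[80-100%]`, whose centres are the levels
#' 10%, 30%, 50%, 70%, 90%; each band reports its mean RT and fraction
#' correct.
#'
#' @param trials `data.frame` with columns `rt` (seconds) and `correct`
#'   (logical or 0/1); at least 10 trials.
#' @return `data.frame` with columns `level`, `rt`, `accuracy` (5 rows).
#' @export
caf <- function(trials) {
  if (nrow(trials) < 10)
    stop("need at least 10 trials for the CAF measure", call. = FALSE)
  n <- nrow(trials)
  # empirical quantile rank of each trial ("first" tie-breaking keeps the
  # five bands equally filled even with tied RTs)
  q <- (rank(trials$rt, ties.method = "first") - 0.5) / n
  band <- pmin(5L, floor(q * 5) + 1L)
  out <- data.frame(level = caf_levels(), rt = NA_real_,
                    accuracy = NA_real_)
  for (b in seq_len(5)) {
    rows <- which(band == b)
    out$rt[b] <- mean(trials$rt[rows])
    out$accuracy[b] <- mean(as.numeric(trials$correct[rows]))
  }
  out
}

#' Distributional summary of a model at given parameters
#'
#' Simulates `n_trials` trials, maps upper-boundary responses to correct,
#' and computes the CDF quantiles, the CAF and the overall error rate.
#' Timeout trials (if any) are excluded.
#'
#' @param params `dm_params` object or named vector.
#' @param model `"ddm"` or `"tvddm"` (needed for plain vectors).
#' @param n_trials simulated trials (default 2000).
#' @param cfg a [sim_config()].
#' @param seed integer simulation seed.
#' @return An object of class `"dist_summary"`: `cdf_levels`, `cdf_rts`,
#'   `caf` (data frame), `error_rate`, `n_trials`.
#' @export
model_summary <- function(params, model = NULL, n_trials = 2000,
                          cfg = sim_config(), seed = 1L) {
  trials <- simulate_dm(params, n_trials, cfg, seed = seed, model = model)
  trials <- trials[trials$response != "timeout", ]
  trials$correct <- trials$response == "upper"
  structure(list(cdf_levels = cdf_levels(),
                 cdf_rts = unname(cdf_quantiles(trials$rt)),
                 caf = caf(trials),
                 error_rate = mean(!trials$correct),
                 n_trials = nrow(trials)),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("Distributional summary over %d trials\n", x$n_trials))
  cat(sprintf("  error rate %.3f\n", x$error_rate))
  cat(sprintf("  CDF RTs (10%%..90%%): %s\n",
              paste(sprintf("%.3f", x$cdf_rts[c(1, 5, 9, 13, 17)]),
                    collapse = " ")))
  invisible(x)
}

# stack the numeric measures of a dist_summary into one vector
summary_vector <- function(s) {
  c(s$cdf_rts, s$caf$rt, s$caf$accuracy, s$error_rate)
}

#' Posterior credible bands for the distributional measures
#'
#' For each of `n_samples` posterior samples, one parameter vector is
#' drawn per participant, each participant's distributional summary is
#' computed and summaries are averaged across participants; the band is
#' the central 95% interval across samples at every measure point
#' (17 CDF RTs, 5 CAF RTs, 5 CAF accuracies, error rate).
#'
#' @param fits list of [fit_dm()] results (or `"dm_draws"`), one per
#'   participant, for a single condition and model.
#' @param model `"ddm"` or `"tvddm"`; taken from the first fit if `NULL`.
#' @param n_samples posterior samples (default 1000).
#' @param n_trials simulated trials per summary.
#' @param cfg a [sim_config()].
#' @param level band mass (default 0.95).
#' @param seed integer seed.
#' @return List with matrices `lower`, `upper`, `mean` (named measure
#'   points) and the measure-point `names`.
#' @export
credible_band <- function(fits, model = NULL, n_samples = 1000,
                          n_trials = 500, cfg = sim_config(),
                          level = 0.95, seed = 1L) {
  if (is.null(model)) {
    model <- if (inherits(fits[[1]], "dmfit")) fits[[1]]$model else
      stop("supply `model`", call. = FALSE)
  }
  mats <- lapply(fits, function(f)
    retained_matrix(if (inherits(f, "dmfit")) f$draws else f))
  set.seed(seed)
  pts <- NULL
  for (s in seq_len(n_samples)) {
    per_part <- vapply(seq_along(mats), function(j) {
      m <- mats[[j]]
      theta <- m[sample.int(nrow(m), 1), ]
      # simulation seed derived from the drawn parameters: identical
      # draws give identical summaries (so a degenerate posterior yields
      # zero-width bands), and the whole band is deterministic given seed
      sim_seed <- (seed + 131 * j +
                     floor(sum(theta) * 1e6)) %% 2147483647
      summary_vector(model_summary(theta, model, n_trials, cfg,
                                   seed = sim_seed))
    }, numeric(28))
    avg <- rowMeans(per_part, na.rm = TRUE)
    if (is.null(pts)) pts <- matrix(NA_real_, n_samples, length(avg))
    pts[s, ] <- avg
  }
  al <- (1 - level) / 2
  nm <- c(paste0("cdf_", format(cdf_levels())),
          paste0("caf_rt_", format(caf_levels())),
          paste0("caf_acc_", format(caf_levels())), "error_rate")
  lo <- apply(pts, 2, stats::quantile, probs = al, na.rm = TRUE,
              names = FALSE)
  hi <- apply(pts, 2, stats::quantile, probs = 1 - al, na.rm = TRUE,
              names = FALSE)
  list(lower = stats::setNames(lo, nm), upper = stats::setNames(hi, nm),
       mean = stats::setNames(colMeans(pts, na.rm = TRUE), nm),
       names = nm)
}

#' One-way repeated-measures ANOVA
#'
#' Within-participant one-way ANOVA via `stats::aov` with an
#' `Error(participant)` stratum; F has `(k - 1, (k - 1)(n - 1))` degrees
#' of freedom (no sphericity correction).
#'
#' @param values numeric matrix, participants x conditions (complete).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3 || ncol(values) < 2)
    stop("need >= 3 participants and >= 2 conditions", call. = FALSE)
  if (anyNA(values)) stop("missing cells", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  df <- data.frame(
    y = as.vector(values),
    subj = factor(rep(seq_len(n), k)),
    cond = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ cond + Error(subj), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["cond", "F value"]
  df1 <- tab["cond", "Df"]
  df2 <- tab["Residuals", "Df"]
  # guard against 0/0 round-off when all conditions agree per participant
  if (is.na(Fv) ||
      tab["cond", "Sum Sq"] < 1e-10 * (1 + mean(values^2)) * n * k)
    Fv <- 0
  p <- if (Fv == 0) 1 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = unname(Fv), df1 = unname(df1), df2 = unname(df2),
       p = unname(p))
}

#' Posterior overlap indicator
#'
#' Assesses whether a condition effect on a parameter's EAPs survives
#' posterior uncertainty: in each of `n_reps` replicates, `n_draws`
#' posterior values of the parameter are sampled and averaged per
#' participant and condition, and a one-way repeated-measures ANOVA is
#' run across conditions.  The indicator is the proportion of replicates
#' with `p < alpha`; a proportion of at least 0.95 confirms the effect.
#'
#' @param draws_by_cell list (participants) of lists (conditions) of
#'   numeric vectors: the retained posterior draws of one parameter.
#' @param n_draws posterior values averaged per cell (default 10; small
#'   on purpose — using all draws is too liberal).
#' @param n_reps replicate ANOVAs (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return An object of class `"overlap_result"`:
#'   `proportion_significant`, `n_reps`, `n_draws_per_cell`, `alpha`,
#'   `decision` (`proportion >= 0.95`).
#' @export
posterior_overlap <- function(draws_by_cell, n_draws = 10, n_reps = 1000,
                              alpha = 0.05, seed = 1L) {
  n_part <- length(draws_by_cell)
  n_cond <- length(draws_by_cell[[1]])
  stopifnot(n_part >= 3, n_cond >= 2,
            all(vapply(draws_by_cell, length, 1L) == n_cond))
  set.seed(seed)
  sig <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cell <- matrix(NA_real_, n_part, n_cond)
    for (i in seq_len(n_part)) for (j in seq_len(n_cond)) {
      v <- draws_by_cell[[i]][[j]]
      cell[i, j] <- mean(v[sample.int(length(v), n_draws,
                                      replace = TRUE)])
    }
    sig[r] <- rm_anova(cell)$p < alpha
  }
  prop <- mean(sig)
  structure(list(proportion_significant = prop, n_reps = n_reps,
                 n_draws_per_cell = n_draws, alpha = alpha,
                 decision = prop >= 0.95),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Posterior overlap indicator: %.3f of %d replicate ANOVAs significant (alpha %.2f)\n",
    x$proportion_significant, x$n_reps, x$alpha))
  cat(if (x$decision) "  effect confirmed (>= 0.95)\n" else
    "  effect not confirmed\n")
  invisible(x)
}

#' Perceptual integration time
#'
#' The smallest time at which the evidence growth function
#' [growth_theta()] reaches `level` (default 97%), found by bisection to
#' `1e-6` s.  For `n = 1` this equals `-log(1 - level) / beta`.
#'
#' @param beta,n growth-function parameters, > 0.
#' @param level target fraction in (0, 1).
#' @return Time in seconds.
#' @export
integration_time <- function(beta, n, level = 0.97) {
  stopifnot(beta > 0, n > 0, level > 0, level < 1)
  lo <- 0
  hi <- 1
  while (growth_theta(hi, beta, n) < level) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (growth_theta(mid, beta, n) >= level) hi <- mid else lo <- mid
  }
  hi
}
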