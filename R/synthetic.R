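#' Study design for synthetic behavioral data
#'
#' Describes a 2 x k repeated-measures design: two stimulus identities and
#' `k` noise levels, with `trials_per_cell` trials per participant and
#' noise level (stimulus identities balanced within the cell).  Defaults
#' emulate a four-level noise manipulation (10/40/70/80% noise) with 32
#' trials per level, and RT cleaning thresholds of 150 ms and 3000 ms.
#'
#' @param n_participants number of participants.
#' @param noise_levels ordered condition labels.
#' @param stimuli two stimulus identity labels.
#' @param trials_per_cell trials per participant x noise level, >= 1.
#' @param rt_bounds cleaning bounds in seconds, `low < high`.
#' @param seed integer master seed of the generator.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_participants = 46,
                         noise_levels = c("10", "40", "70", "80"),
                         stimuli = c("left", "right"),
                         trials_per_cell = 32,
                         rt_bounds = c(0.150, 3.000), seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_cell >= 1,
            length(stimuli) == 2, rt_bounds[1] < rt_bounds[2])
  structure(list(n_participants = as.integer(n_participants),
                 noise_levels = as.character(noise_levels),
                 stimuli = as.character(stimuli),
                 trials_per_cell = as.integer(trials_per_cell),
                 rt_bounds = rt_bounds, seed = as.integer(seed)),
            class = "study_design")
}

#' Generative ground truth for a synthetic study
#'
#' Per-condition parameter sets of one model plus a relative
#' per-participant jitter SD.  [default_ground_truth()] encodes the
#' qualitative pattern expected of noisy perceptual discrimination: drift
#' rate decreasing and boundary increasing with noise, constant
#' non-decision time.
#'
#' @param model `"ddm"` or `"tvddm"`.
#' @param params_by_condition named list (one entry per condition label)
#'   of `dm_params` objects.
#' @param jitter_sd relative SD of the per-participant parameter jitter
#'   (default 0.1, i.e. 10% of each parameter's value).
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(model = c("ddm", "tvddm"), params_by_condition,
                         jitter_sd = 0.1) {
  model <- match.arg(model)
  stopifnot(length(params_by_condition) >= 1, jitter_sd >= 0)
  for (p in params_by_condition) {
    msg <- params_check(p, model)
    if (!is.null(msg)) stop(msg, call. = FALSE)
  }
  structure(list(model = model,
                 params_by_condition = params_by_condition,
                 jitter_sd = jitter_sd),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param noise_levels condition labels, matched to four noise steps.
#' @export
default_ground_truth <- function(model = c("ddm", "tvddm"),
                                 noise_levels = c("10", "40", "70", "80"),
                                 jitter_sd = 0.1) {
  model <- match.arg(model)
  k <- length(noise_levels)
  # v decreasing, A increasing across noise, ter constant; values chosen
  # so group error rates rise from a few percent to roughly 25-30%,
  # matching the accuracy range reported for noisy dot discrimination
  # (~70-100%) while keeping all conditions off ceiling
  if (model == "ddm") {
    v <- seq(0.34, 0.09, length.out = k)
    A <- seq(0.11, 0.17, length.out = k)
    pars <- lapply(seq_len(k), function(i)
      ddm_params(A = A[i], ter = 0.26, v = v[i], sz = 0.05, sv = 0.07,
                 ster = 0.28))
  } else {
    v <- seq(0.48, 0.13, length.out = k)
    A <- seq(0.15, 0.24, length.out = k)
    pars <- lapply(seq_len(k), function(i)
      tvddm_params(A = A[i], ter = 0.18, v = v[i], beta = 25, n = 5,
                   sigma2 = 0.1, sv = 0.25))
  }
  names(pars) <- noise_levels
  ground_truth(model, pars, jitter_sd)
}

#' Ground truth with identical parameters in every condition
#'
#' Convenience constructor used for calibration and recovery studies:
#' every condition shares one parameter set and no participant jitter by
#' default.
#'
#' @inheritParams ground_truth
#' @param params a single `dm_params` object.
#' @param noise_levels condition labels.
#' @export
flat_ground_truth <- function(model = c("ddm", "tvddm"), params,
                              noise_levels = c("10", "40", "70", "80"),
                              jitter_sd = 0) {
  model <- match.arg(model)
  pars <- rep(list(params), length(noise_levels))
  names(pars) <- noise_levels
  ground_truth(model, pars, jitter_sd)
}

# jitter each parameter by Normal(0, jitter_sd * value), redrawing until
# the jittered set satisfies the model invariants
jitter_params <- function(params, model, jitter_sd, max_tries = 100) {
  theta <- unlist(params)
  if (jitter_sd == 0) return(theta)
  for (k in seq_len(max_tries)) {
    prop <- theta * (1 + jitter_sd * stats::rnorm(length(theta)))
    if (params_valid(prop, model)) return(prop)
  }
  stop("could not draw valid jittered parameters after ", max_tries,
       " attempts", call. = FALSE)
}

#' Generate a synthetic behavioral dataset
#'
#' For every participant x condition cell, the condition's generative
#' parameters are jittered per participant (truncated-by-redraw normal
#' jitter), `trials_per_cell` trials are simulated from the ground-truth
#' model, stimulus identities are assigned in balanced randomized order,
#' and the upper boundary is mapped to the correct response.  The result
#' is deterministic given the design seed.
#'
#' @param design a [study_design()].
#' @param truth a [ground_truth()] whose condition labels cover the
#'   design's noise levels.
#' @param cfg a [sim_config()].
#' @return A `data.frame` ("behavioral table") with columns
#'   `participant`, `condition`, `stimulus`, `response`, `correct`, `rt`.
#' @export
#' @examples
#' d <- study_design(n_participants = 2, trials_per_cell = 8, seed = 3)
#' head(generate_dataset(d, default_ground_truth("ddm")))
generate_dataset <- function(design, truth, cfg = sim_config()) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  if (!all(design$noise_levels %in% names(truth$params_by_condition)))
    stop("ground truth lacks parameters for some noise levels",
         call. = FALSE)
  set.seed(design$seed)
  out <- vector("list", design$n_participants * length(design$noise_levels))
  idx <- 0L
  npc <- design$trials_per_cell
  for (p in seq_len(design$n_participants)) {
    for (cond in design$noise_levels) {
      theta <- jitter_params(truth$params_by_condition[[cond]],
                             truth$model, truth$jitter_sd)
      trials <- simulate_dm(theta, npc, cfg, seed = new_sim_seed(),
                            model = truth$model)
      n_to <- sum(trials$response == "timeout")
      if (n_to > 0) {
        warning(sprintf("dropping %d timeout trial(s) in participant %d",
                        n_to, p))
        trials <- trials[trials$response != "timeout", ]
      }
      n <- nrow(trials)
      # balanced randomized stimulus assignment (counts differ by <= 1)
      stim <- sample(rep_len(design$stimuli, n))
      correct <- trials$response == "upper"
      other <- stats::setNames(rev(design$stimuli), design$stimuli)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        participant = p, condition = cond, stimulus = stim,
        response = ifelse(correct, stim, other[stim]),
        correct = correct, rt = trials$rt, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(idx)])
  rownames(res) <- NULL
  res
}

#' Remove implausibly fast and slow response times
#'
#' Drops rows with `rt < bounds[1]` or `rt > bounds[2]` (strict
#' inequalities: boundary values are kept).  Defaults: 150 ms and
#' 3000 ms.
#'
#' @param table behavioral table with an `rt` column in seconds.
#' @param bounds length-2 numeric, `c(low, high)`.
#' @return List with `table` (cleaned), `n_removed`, `fraction_removed`.
#' @export
clean_rts <- function(table, bounds = c(0.150, 3.000)) {
  stopifnot(bounds[1] < bounds[2], "rt" %in% names(table))
  keep <- table$rt >= bounds[1] & table$rt <= bounds[2]
  if (!any(keep)) stop("no trials survive cleaning", call. = FALSE)
  list(table = table[keep, , drop = FALSE],
       n_removed = sum(!keep),
       fraction_removed = mean(!keep))
}

#' Flag participants performing below chance
#'
#' @param table behavioral table with `participant` and `correct` columns.
#' @param chance chance accuracy (default 0.5); participants with overall
#'   accuracy strictly below it are flagged.
#' @return Vector of participant ids to exclude (possibly empty).
#' @export
exclusion_screen <- function(table, chance = 0.5) {
  stopifnot(all(c("participant", "correct") %in% names(table)))
  acc <- tapply(as.numeric(table$correct), table$participant, mean)
  ids <- names(acc)[acc < chance]
  if (is.numeric(table$participant)) as.numeric(ids) else ids
}
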