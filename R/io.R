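#' Read a behavioral table from delimited text
#'
#' Expects columns `participant`, `condition`, `rt` plus `response`
#' and/or `correct` (and optionally `stimulus`).  RTs are coerced to
#' seconds; when `unit = "auto"` and typical values exceed 100 the column
#' is assumed to be in milliseconds, converted, and a warning is issued.
#' When `response` carries stimulus identities rather than boundary
#' labels, a `mapping` from stimulus to the upper-boundary response can
#' be used to derive `correct`.
#'
#' @param path CSV file path.
#' @param unit `"auto"` (heuristic), `"s"` or `"ms"`.
#' @param mapping optional named character vector mapping each stimulus
#'   identity to the response counted as correct, used to derive a
#'   missing `correct` column.
#' @return Behavioral `data.frame`; schema violations are reported with
#'   row numbers.
#' @export
read_behavioral_csv <- function(path, unit = c("auto", "s", "ms"),
                                mapping = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "rt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tab$rt)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$rt))))
    stop("non-numeric rt in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (unit == "ms" || (unit == "auto" && stats::median(tab$rt) > 100)) {
    if (unit == "auto")
      warning("rt values look like milliseconds; converting to seconds")
    tab$rt <- tab$rt / 1000
  }
  if (!"correct" %in% names(tab)) {
    if (is.null(mapping) || !all(c("stimulus", "response") %in% names(tab)))
      stop("no `correct` column; supply `mapping` plus stimulus/response",
           call. = FALSE)
    unknown <- which(!tab$stimulus %in% names(mapping))
    if (length(unknown))
      stop("stimulus without mapping in row(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    tab$correct <- tab$response == mapping[tab$stimulus]
  }
  if ("response" %in% names(tab)) {
    known <- tab$response %in%
      c("upper", "lower", if (!is.null(mapping)) unname(mapping),
        if ("stimulus" %in% names(tab)) unique(tab$stimulus))
    if (!all(known))
      stop("unknown response code in row(s): ",
           paste(utils::head(which(!known), 5), collapse = ", "),
           call. = FALSE)
  }
  tab
}

# map a behavioral table's correct flag to boundary responses for fitting
as_boundary_responses <- function(table) {
  stopifnot("correct" %in% names(table))
  data.frame(response = ifelse(as.logical(table$correct), "upper", "lower"),
             rt = table$rt, stringsAsFactors = FALSE)
}

# small stable config fingerprint (FNV-1a over the serialized object)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), b)
    # multiply in double space, reduce to keep within integer range
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Configuration of an end-to-end synthetic study
#'
#' @param design a [study_design()].
#' @param truth a [ground_truth()].
#' @param models models to fit and compare (default both).
#' @param control a [sampler_control()].
#' @param cfg a [sim_config()].
#' @param n_sim simulated trials per likelihood evaluation.
#' @param tide list of TIDE settings: `n_temps`, `n_gens`, `burn_in`.
#' @param rhat_criterion convergence gate (default 1.1).
#' @param overlap_params parameters tested with [posterior_overlap()]
#'   (default `A`, `ter`, `v`).
#' @param seed master seed.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(design, truth, models = c("ddm", "tvddm"),
                       control = sampler_control(), cfg = sim_config(),
                       n_sim = 1000,
                       tide = list(n_temps = 30, n_gens = 10000,
                                   burn_in = 1500),
                       rhat_criterion = 1.1,
                       overlap_params = c("A", "ter", "v"), seed = 1L) {
  structure(list(design = design, truth = truth, models = models,
                 control = control, cfg = cfg, n_sim = n_sim,
                 tide = tide, rhat_criterion = rhat_criterion,
                 overlap_params = overlap_params,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run a complete synthetic study end to end
#'
#' Generates data, cleans RTs, screens participants, fits every model to
#' every participant x condition cell, gates fits on split R-hat,
#' summarizes EAPs, compares models per cell by thermodynamic
#' integration (Bayes factor with Jeffreys category, DIC, BPIC when two
#' models are configured) and computes the posterior overlap indicator
#' for the configured parameters of the first model.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the report is written
#'   as JSON (requires the `jsonlite` package).
#' @return A report list: `config_hash`, `seed`, `cleaning`, `excluded`,
#'   per-fit `rhat_max`, EAP tables, `evidence_counts` (category x
#'   condition counts of cells won), `overlap`, and per-cell details.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  data <- generate_dataset(design, config$truth, config$cfg)
  cl <- clean_rts(data, design$rt_bounds)
  data <- cl$table
  excluded <- exclusion_screen(data)
  data <- data[!data$participant %in% excluded, , drop = FALSE]
  participants <- unique(data$participant)
  conds <- design$noise_levels
  fits <- list()
  rhat_max <- list()
  bf_rows <- NULL
  for (p in participants) {
    for (cond in conds) {
      cell <- data[data$participant == p & data$condition == cond, ]
      cell_fit <- list()
      fit_seed <- config$seed + 1000L * match(p, participants) +
        match(cond, conds)
      for (m in config$models) {
        f <- fit_dm(as_boundary_responses(cell), m,
                    control = config$control, cfg = config$cfg,
                    n_sim = config$n_sim, seed = fit_seed)
        key <- paste(p, cond, m, sep = ".")
        fits[[key]] <- f
        rhat_max[[key]] <- max(f$rhat)
        cell_fit[[m]] <- f
      }
      if (length(config$models) == 2) {
        converged <- all(unlist(rhat_max[paste(p, cond, config$models,
                                               sep = ".")]) <=
                           config$rhat_criterion)
        ml <- lapply(cell_fit, function(f)
          tide_log_ml(f$data, f$model, f$priors, eap_init = f$eap,
                      n_temps = config$tide$n_temps,
                      n_gens = config$tide$n_gens,
                      burn_in = config$tide$burn_in, cfg = config$cfg,
                      n_sim = config$n_sim, seed = fit_seed + 7L))
        bf <- bayes_factor(ml[[config$models[2]]],
                           ml[[config$models[1]]])
        bf_rows <- rbind(bf_rows, data.frame(
          participant = p, condition = cond, bf = bf$bf,
          log_bf = bf$log_bf, category = bf$category,
          converged = converged, stringsAsFactors = FALSE))
      }
    }
  }
  # evidence-count table over converged cells (M1 = second model,
  # typically tvddm, vs M2 = first)
  evidence_counts <- NULL
  if (!is.null(bf_rows)) {
    use <- bf_rows[bf_rows$converged, , drop = FALSE]
    evidence_counts <- table(category = use$category,
                             condition = use$condition)
  }
  # EAP table and overlap for the first model
  m1 <- config$models[1]
  eap_tab <- list()
  overlap <- list()
  for (par in config$overlap_params) {
    cellmat <- matrix(NA_real_, length(participants), length(conds))
    draws_by_cell <- lapply(participants, function(p)
      lapply(conds, function(cond)
        retained_matrix(fits[[paste(p, cond, m1,
                                    sep = ".")]]$draws)[, par]))
    for (i in seq_along(participants)) for (j in seq_along(conds))
      cellmat[i, j] <- mean(draws_by_cell[[i]][[j]])
    eap_tab[[par]] <- stats::setNames(colMeans(cellmat), conds)
    overlap[[par]] <- if (length(participants) >= 3)
      posterior_overlap(draws_by_cell, seed = config$seed + 77L)
    else NULL
  }
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 cleaning = cl[c("n_removed", "fraction_removed")],
                 excluded = excluded,
                 n_participants = length(participants),
                 rhat_max = unlist(rhat_max),
                 rhat_criterion = config$rhat_criterion,
                 eap = eap_tab,
                 bf = bf_rows,
                 evidence_counts = evidence_counts,
                 overlap = lapply(overlap, function(o)
                   if (is.null(o)) NULL else unclass(o)))
  if (!is.null(out_dir)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing reports requires the jsonlite package", call. = FALSE)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report, file.path(out_dir, "study_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
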