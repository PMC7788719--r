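#' Experiment grids for the Monte-Carlo power study
#'
#' An `experiment_grid` bundles everything a simulation experiment needs:
#' the study template (generator, covariate model, outcome scale), the
#' number of fictitious hospitals, the grid of patients-per-hospital values,
#' the number of replicates per cell, the between-hospital SD, the
#' scenarios (A: true effects drawn N(0, sd); B: all zero) and the outcome
#' analyses to run. The full-scale defaults mirror the published experiment
#' (250 hospitals, 25-200 patients per hospital, 500 runs per cell,
#' SD 0.35); [desk_grid()] gives a scaled-down preset (50 hospitals, 100
#' replicates) for desk-sized reruns.
#'
#' @param template `"impact"`, `"practise"`, or a list with components
#'   `generator` (an `outcome_generator`), `cov_model` (a `covariate_model`
#'   or `NULL`) and optionally `label`.
#' @param H number of hospitals.
#' @param n_grid strictly increasing positive integers: patients per
#'   hospital.
#' @param n_reps replicates per (scenario, n) cell.
#' @param sd between-hospital SD of true center effects (scenario A).
#' @param scenarios subset of `c("A", "B")`.
#' @param analyses subset of `c("ordinal", "favorable", "mortality")`.
#' @param master_seed integer master seed; every replicate's seed is derived
#'   from it deterministically.
#' @param alpha significance level for outlier flagging.
#' @param rule detection rule passed to [flag_outliers()].
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(template = "impact", H = 250L,
                            n_grid = seq(25L, 200L, by = 25L),
                            n_reps = 500L, sd = 0.35,
                            scenarios = c("A", "B"),
                            analyses = c("ordinal", "favorable",
                                         "mortality"),
                            master_seed = 1L, alpha = 0.05,
                            rule = "ci_screen") {
  tpl <- resolve_template(template)
  H <- stop_if_not_count(H, "H", min = 2L)
  n_reps <- stop_if_not_count(n_reps, "n_reps")
  n_grid <- as.integer(n_grid)
  if (!length(n_grid) || any(n_grid <= 0L) || is.unsorted(n_grid,
                                                          strictly = TRUE))
    stop("'n_grid' must be strictly increasing positive integers")
  if (!all(scenarios %in% c("A", "B")) || !length(scenarios))
    stop("'scenarios' must be a subset of c('A', 'B')")
  if (!all(analyses %in% c("ordinal", "favorable", "mortality")) ||
      !length(analyses))
    stop("'analyses' must be a subset of c('ordinal', 'favorable', 'mortality')")
  if (sd < 0) stop("'sd' must be non-negative")
  rule <- match.arg(rule, c("ci_screen", "wald_vs_mean", "mean_ci"))
  structure(list(template = tpl, H = H, n_grid = n_grid, n_reps = n_reps,
                 sd = sd, scenarios = unique(scenarios),
                 analyses = unique(analyses),
                 master_seed = as.integer(master_seed), alpha = alpha,
                 rule = rule),
            class = "experiment_grid")
}

#' @rdname experiment_grid
#' @param ... overrides passed on to [experiment_grid()].
#' @export
desk_grid <- function(template = "impact", ...) {
  args <- list(...)
  defaults <- list(template = template, H = 50L,
                   n_grid = c(25L, 50L, 100L, 150L, 200L), n_reps = 100L)
  do.call(experiment_grid, utils::modifyList(defaults, args))
}

resolve_template <- function(template) {
  if (is.character(template)) return(study_template(template))
  stopifnot(is.list(template), inherits(template$generator,
                                        "outcome_generator"))
  if (is.null(template$label)) template$label <- "custom"
  if (is.null(template$cov_model)) template["cov_model"] <- list(NULL)
  template
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf(
    "Experiment grid '%s': H = %d, n per hospital {%s}, %d reps/cell\n",
    x$template$label, x$H, paste(x$n_grid, collapse = ", "), x$n_reps))
  cat(sprintf("  scenarios %s; analyses %s; sd = %g; rule = %s; seed = %d\n",
              paste(x$scenarios, collapse = "/"),
              paste(x$analyses, collapse = "/"), x$sd, x$rule,
              x$master_seed))
  invisible(x)
}

#' Run one simulation replicate
#'
#' Simulates a single cohort for one (scenario, patients-per-hospital) cell
#' and analyses it with each requested outcome treatment: the same patients
#' and the same ordinal outcome draw feed all analyses, only the outcome
#' coding differs, which removes between-analysis Monte-Carlo noise. Model
#' failures are recorded per analysis rather than dropped.
#'
#' @param grid an [experiment_grid()].
#' @param scenario `"A"` or `"B"`.
#' @param n_per_hospital patients per hospital for this cell.
#' @param seed integer seed for this replicate (all of the replicate's
#'   randomness flows from it).
#' @return A `data.frame` with one row per analysis: counts of flagged and
#'   non-estimable hospitals, convergence and failure flags.
#' @export
run_replicate <- function(grid, scenario, n_per_hospital, seed) {
  stopifnot(inherits(grid, "experiment_grid"))
  cohort <- with_seed(seed, {
    eff <- sample_center_effects(grid$H, sd = grid$sd, scenario = scenario)
    simulate_cohort(grid$template$generator, grid$template$cov_model,
                    grid$H, n_per_hospital, eff)
  })
  rows <- lapply(grid$analyses, function(an) {
    res <- tryCatch({
      fit <- fit_center_effects(cohort, analysis = an)
      det <- flag_outliers(fit, rule = grid$rule, alpha = grid$alpha)
      list(n_flagged = det$n_flagged, n_estimable = det$n_estimable,
           n_non_estimable = grid$H - det$n_estimable,
           converged = fit$converged, failed = FALSE)
    }, error = function(e) {
      list(n_flagged = NA_integer_, n_estimable = NA_integer_,
           n_non_estimable = NA_integer_, converged = FALSE, failed = TRUE)
    })
    data.frame(scenario = scenario, analysis = an,
               n_per_hospital = n_per_hospital,
               n_flagged = res$n_flagged, n_estimable = res$n_estimable,
               n_non_estimable = res$n_non_estimable,
               converged = res$converged, failed = res$failed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a full Monte-Carlo experiment
#'
#' Iterates [run_replicate()] over every (scenario, patients-per-hospital)
#' cell of the grid. Per-replicate seeds are pre-derived from the master
#' seed, so results are identical whether replicates run serially or on
#' several cores.
#'
#' @param grid an [experiment_grid()].
#' @param cores number of worker processes (forked; 1 = serial).
#' @param verbose print per-cell progress.
#' @return A `detection_summary`: `data.frame` with one row per
#'   (scenario, analysis, n_per_hospital, replicate), the grid attached as
#'   attribute `"grid"`.
#' @export
run_experiment <- function(grid, cores = 1L, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- expand.grid(scenario = grid$scenarios, n = grid$n_grid,
                       stringsAsFactors = FALSE)
  seeds <- replicate_seeds(grid$master_seed, nrow(cells), grid$n_reps)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]; np <- cells$n[ci]
    if (verbose)
      message(sprintf("cell %d/%d: scenario %s, n = %d", ci, nrow(cells),
                      sc, np))
    one <- function(r) {
      res <- run_replicate(grid, sc, np, seed = seeds[ci, r])
      res$rep <- r
      res
    }
    reps <- if (cores > 1L)
      parallel::mclapply(seq_len(grid$n_reps), one, mc.cores = cores)
    else lapply(seq_len(grid$n_reps), one)
    out[[ci]] <- do.call(rbind, reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "grid") <- grid
  class(res) <- c("detection_summary", "data.frame")
  res
}

#' Aggregate a detection summary
#'
#' Collapses per-replicate outlier counts to one row per
#' (scenario, analysis, n_per_hospital) cell: the mean flagged fraction
#' (flagged / estimable hospitals), its Monte-Carlo standard error, and
#' failure/non-estimability accounting. The aggregated fraction is exactly
#' the mean of per-replicate fractions.
#'
#' @param summary a `detection_summary` from [run_experiment()].
#' @return A `data.frame` with columns `scenario`, `analysis`,
#'   `n_per_hospital`, `n_reps`, `frac_flagged`, `mc_se`,
#'   `mean_non_estimable`, `n_failed`.
#' @export
aggregate_detection <- function(summary) {
  stopifnot(is.data.frame(summary),
            all(c("scenario", "analysis", "n_per_hospital", "n_flagged",
                  "n_estimable") %in% names(summary)))
  key <- interaction(summary$scenario, summary$analysis,
                     summary$n_per_hospital, drop = TRUE)
  frac <- summary$n_flagged / summary$n_estimable
  agg <- do.call(rbind, lapply(split(seq_len(nrow(summary)), key),
                               function(idx) {
    f <- frac[idx]
    ok <- !is.na(f)
    data.frame(scenario = summary$scenario[idx[1L]],
               analysis = summary$analysis[idx[1L]],
               n_per_hospital = summary$n_per_hospital[idx[1L]],
               n_reps = length(idx),
               frac_flagged = mean(f[ok]),
               mc_se = stats::sd(f[ok]) / sqrt(sum(ok)),
               mean_non_estimable = mean(summary$n_non_estimable[idx],
                                         na.rm = TRUE),
               n_failed = sum(!ok), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$scenario, agg$analysis, agg$n_per_hospital), ]
  rownames(agg) <- NULL
  agg
}

#' Write and read detection summaries
#'
#' Tidy CSV round trip of the per-replicate detection results, together
#' with a small JSON run manifest (grid settings and master seed).
#'
#' @param summary a `detection_summary`.
#' @param path CSV path; the manifest is written next to it with extension
#'   `.manifest.json`.
#' @export
write_detection_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  grid <- attr(summary, "grid")
  if (!is.null(grid)) {
    manifest <- list(template = grid$template$label, H = grid$H,
                     n_grid = grid$n_grid, n_reps = grid$n_reps,
                     sd = grid$sd, scenarios = grid$scenarios,
                     analyses = grid$analyses,
                     master_seed = grid$master_seed, alpha = grid$alpha,
                     rule = grid$rule)
    jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_detection_summary
#' @export
read_detection_summary <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("detection_summary", "data.frame")
  x
}
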