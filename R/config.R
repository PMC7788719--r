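#' Study templates
#'
#' Bundles the outcome generator, covariate model and outcome scale that
#' emulate each of the two example study populations: `"impact"` (TBI,
#' 4-point collapsed GOS; the real study comprised 9578 patients in 265
#' centers) and `"practise"` (acute stroke, 6-point collapsed mRS; 1657
#' patients in 12 centers). The real center counts are recorded as metadata
#' only; simulations use the grid's number of fictitious hospitals.
#'
#' @param name `"impact"` or `"practise"`.
#' @return List with `label`, `generator`, `cov_model`, `scale`,
#'   `real_centers`, `real_patients`.
#' @export
study_template <- function(name = c("impact", "practise")) {
  name <- match.arg(name)
  if (name == "impact")
    list(label = "impact", generator = impact_generator(),
         cov_model = impact_covariates(), scale = builtin_scale("gos4"),
         real_centers = 265L, real_patients = 9578L)
  else
    list(label = "practise", generator = practise_generator(),
         cov_model = practise_covariates(), scale = builtin_scale("mrs6"),
         real_centers = 12L, real_patients = 1657L)
}

.config_keys <- c("template", "H", "n_grid", "n_reps", "sd", "scenarios",
                  "analyses", "master_seed", "alpha", "rule", "scale",
                  "marginals", "preset")

#' Load an experiment configuration from YAML
#'
#' Reads a YAML file describing an experiment, validates it field by field,
#' fills in defaults and returns a ready-to-run [experiment_grid()]. The
#' file must name a `template` (`impact`, `practise`, or `custom`); a custom
#' template must supply `scale` (list with `name`, `categories`,
#' `favorable_cut`) and `marginals` (baseline category probabilities).
#' Unknown keys are rejected. `preset: desk` applies the scaled-down
#' defaults of [desk_grid()].
#'
#' @param path YAML file path.
#' @return An `experiment_grid`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || !length(cfg))
    stop("config is empty: a 'template' field is required")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$template))
    stop("field 'template' is required (impact, practise or custom)")
  if (!cfg$template %in% c("impact", "practise", "custom"))
    stop("field 'template' must be one of impact, practise, custom")

  template <- if (cfg$template == "custom") {
    if (is.null(cfg$scale) || is.null(cfg$marginals))
      stop("custom template requires 'scale' and 'marginals' fields")
    sc <- outcome_scale(cfg$scale$name %||% "custom",
                        unlist(cfg$scale$categories),
                        cfg$scale$favorable_cut,
                        cfg$scale$mortality_cut %||% 1L)
    list(label = "custom",
         generator = configured_generator(sc, unlist(cfg$marginals)),
         cov_model = NULL, scale = sc)
  } else {
    if (!is.null(cfg$scale) || !is.null(cfg$marginals))
      stop("'scale'/'marginals' are only allowed with template: custom")
    study_template(cfg$template)
  }

  maker <- if (identical(cfg$preset, "desk")) desk_grid else experiment_grid
  args <- cfg[intersect(names(cfg), c("H", "n_grid", "n_reps", "sd",
                                      "scenarios", "analyses",
                                      "master_seed", "alpha", "rule"))]
  args$n_grid <- if (!is.null(args$n_grid)) unlist(args$n_grid)
  args$scenarios <- if (!is.null(args$scenarios)) unlist(args$scenarios)
  args$analyses <- if (!is.null(args$analyses)) unlist(args$analyses)
  args <- Filter(Negate(is.null), args)
  do.call(maker, c(list(template = template), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write small deterministic fixture files
#'
#' Generates a tiny reproducible cohort CSV (4 hospitals x 30 patients from
#' the TBI template, scenario A) and a toy per-replicate detection summary
#' CSV, for examples and tests. Byte-identical across runs for a given
#' seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named character vector of the files written.
#' @export
make_fixtures <- function(dir = ".", seed = 20260901) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- study_template("impact")
  eff <- sample_center_effects(4L, sd = 0.35, scenario = "A", seed = seed)
  cohort <- simulate_cohort(tpl$generator, tpl$cov_model, 4L, 30L, eff,
                            seed = seed + 1L)
  cohort_path <- file.path(dir, "fixture_cohort.csv")
  write_cohort(cohort, cohort_path)
  grid <- desk_grid("impact", H = 6L, n_grid = c(25L, 50L), n_reps = 2L,
                    scenarios = "A", master_seed = seed)
  summ <- run_experiment(grid)
  summary_path <- file.path(dir, "fixture_detection_summary.csv")
  write_detection_summary(summ, summary_path)
  c(cohort = cohort_path, summary = summary_path)
}
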