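#' Covariate models for synthetic cohorts
#'
#' A `covariate_model` is an ordered list of marginal specifications, one per
#' baseline covariate. Categorical covariates are sampled independently from
#' their stated frequencies; continuous covariates from parametric families
#' calibrated to printed summaries (log-normal matched to a median and IQR
#' for age; an integer-rounded gamma matched to a mean and SD for stroke
#' severity scores). Covariates are sampled independently of each other and,
#' by default, carry no effect on outcome; they exist so that the analysis
#' models perform the same case-mix adjustment they would on real data.
#'
#' @param ... covariate component specifications created by
#'   [cov_categorical()], [cov_lognormal()] or [cov_gamma_count()].
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(...) {
  comps <- list(...)
  if (!length(comps)) stop("at least one covariate component is required")
  nm <- vapply(comps, function(c) c$name, character(1))
  if (anyDuplicated(nm)) stop("covariate names must be distinct")
  structure(stats::setNames(comps, nm), class = "covariate_model")
}

#' @rdname covariate_model
#' @param name covariate name.
#' @param labels category labels (first label is the factor reference level).
#' @param prob category probabilities; must be positive and are checked to
#'   sum to 1 within 1e-12 after normalization of supplied counts.
#' @export
cov_categorical <- function(name, labels, prob) {
  stopifnot(length(labels) == length(prob), all(prob > 0))
  prob <- prob / sum(prob)
  if (abs(sum(prob) - 1) > 1e-12) stop("probabilities must sum to 1")
  list(name = name, type = "categorical", labels = as.character(labels),
       prob = as.numeric(prob))
}

#' @rdname covariate_model
#' @param median,iqr target median and length-2 interquartile range; the
#'   log-normal meanlog is `log(median)` and sdlog is set from the log-scale
#'   IQR width.
#' @export
cov_lognormal <- function(name, median, iqr) {
  stopifnot(median > 0, length(iqr) == 2L, iqr[1] > 0, iqr[2] > iqr[1])
  sdlog <- (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75))
  list(name = name, type = "lognormal", meanlog = log(median), sdlog = sdlog,
       median = median, iqr = as.numeric(iqr))
}

#' @rdname covariate_model
#' @param mean,sd target mean and SD of the underlying gamma; draws are
#'   rounded to non-negative integers (severity-score style).
#' @export
cov_gamma_count <- function(name, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  list(name = name, type = "gamma_count", shape = (mean / sd)^2,
       rate = mean / sd^2, mean = mean, sd = sd)
}

#' @export
print.covariate_model <- function(x, ...) {
  cat(sprintf("Covariate model with %d components: %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Baseline covariate templates
#'
#' `impact_covariates()` emulates the case mix of a large multi-study TBI
#' cohort: age (median 30, IQR 21-45), 78% male, 80% with both pupils
#' reactive to light, and a 6-level GCS motor score with the published
#' frequency table. `practise_covariates()` emulates an acute-stroke trial
#' population: age (median 73, IQR 62-80), 54% male, 18% atrial
#' fibrillation, 17% diabetes, 20% prior ischemic stroke, and an NIHSS
#' score with mean 8 (SD 6 by default; the source reports only the mean).
#'
#' @param nihss_sd SD for the NIHSS gamma draw (stroke template only).
#' @return A `covariate_model`.
#' @export
impact_covariates <- function() {
  motor_labels <- c("none", "extension", "abnormal flexion",
                    "flexion/withdrawal", "localizes", "obeys")
  motor_counts <- c(1490, 1166, 1244, 2208, 2593, 291)
  covariate_model(
    cov_lognormal("age", median = 30, iqr = c(21, 45)),
    cov_categorical("sex", c("female", "male"), c(0.22, 0.78)),
    cov_categorical("pupils", c("nonreactive", "reactive"), c(0.20, 0.80)),
    cov_categorical("motor_score", motor_labels, motor_counts))
}

#' @rdname impact_covariates
#' @export
practise_covariates <- function(nihss_sd = 6) {
  covariate_model(
    cov_lognormal("age", median = 73, iqr = c(62, 80)),
    cov_categorical("sex", c("female", "male"), c(0.46, 0.54)),
    cov_categorical("af", c("no", "yes"), c(0.82, 0.18)),
    cov_categorical("dm", c("no", "yes"), c(0.83, 0.17)),
    cov_categorical("prior_stroke", c("no", "yes"), c(0.80, 0.20)),
    cov_gamma_count("nihss", mean = 8, sd = nihss_sd))
}

#' Sample baseline covariates
#'
#' Draws `n` independent patients from a covariate model. Reproducible given
#' `seed`; with `n = 0` an empty table with the model's columns is returned.
#'
#' @param model a `covariate_model`.
#' @param n number of patients.
#' @param seed optional integer seed.
#' @return A `data.frame` with one column per covariate.
#' @export
sample_covariates <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "covariate_model"))
  n <- stop_if_not_count(n, "n", min = 0L)
  with_seed(seed, {
    cols <- lapply(model, function(cmp) {
      switch(cmp$type,
        categorical = factor(
          sample(cmp$labels, n, replace = TRUE, prob = cmp$prob),
          levels = cmp$labels),
        lognormal = stats::rlnorm(n, cmp$meanlog, cmp$sdlog),
        gamma_count = as.integer(round(stats::rgamma(n, cmp$shape,
                                                     rate = cmp$rate))),
        stop("unknown covariate type: ", cmp$type))
    })
    as.data.frame(cols, optional = FALSE)
  })
}
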