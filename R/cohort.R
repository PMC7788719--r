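#' Sample per-hospital center effects
#'
#' Scenario A draws one true center effect per hospital i.i.d. from
#' N(0, sd) on the cumulative-logit (log-odds) scale, so hospitals genuinely
#' differ in the outcomes they produce; scenario B sets every effect to 0
#' (no true differences), the null configuration used to measure
#' specificity. The default SD of 0.35 is the between-hospital spread used
#' throughout the simulation experiments.
#'
#' @param H number of hospitals (>= 2).
#' @param sd non-negative SD of the effect distribution.
#' @param scenario `"A"` (effects drawn) or `"B"` (all zero).
#' @param seed optional integer seed.
#' @return Object of class `center_effects`: list with `beta` (length `H`),
#'   `sd`, `scenario`.
#' @export
sample_center_effects <- function(H, sd = 0.35, scenario = c("A", "B"),
                                  seed = NULL) {
  scenario <- match.arg(scenario)
  H <- stop_if_not_count(H, "H", min = 2L)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("'sd' must be a single non-negative number")
  # sd = 0 draws no random numbers, so a degenerate scenario A matches
  # scenario B bit-for-bit under a shared seed
  beta <- if (scenario == "B" || sd == 0) rep(0, H)
          else with_seed(seed, stats::rnorm(H, 0, sd))
  structure(list(beta = beta, sd = sd, scenario = scenario),
            class = "center_effects")
}

#' @export
print.center_effects <- function(x, ...) {
  cat(sprintf("Center effects, scenario %s: H = %d, generative SD = %g\n",
              x$scenario, length(x$beta), x$sd))
  if (x$scenario == "A")
    cat(sprintf("  empirical SD of draws: %.4f\n", stats::sd(x$beta)))
  invisible(x)
}

# Draw one ordinal outcome per row of a probability matrix (rows sum to 1).
.sample_categories <- function(P) {
  n <- nrow(P)
  if (!n) return(integer(0))
  cs <- P
  for (k in seq_len(ncol(P))[-1L]) cs[, k] <- cs[, k - 1L] + P[, k]
  u <- stats::runif(n)
  pmin(rowSums(u > cs) + 1L, ncol(P))
}

#' Simulate a patient cohort
#'
#' Generates `H * n_per_hospital` patients: covariates from `cov_model`,
#' hospital assignment in equal blocks, and ordinal outcomes drawn from
#' [outcome_probabilities()] with each patient's hospital effect applied on
#' the cumulative-logit scale. Fully reproducible given `seed`.
#'
#' @param gen an `outcome_generator`.
#' @param cov_model a `covariate_model`, or `NULL` for no covariates.
#' @param H number of hospitals.
#' @param n_per_hospital patients per hospital (equal allocation).
#' @param effects a `center_effects` object of length `H`.
#' @param seed optional integer seed.
#' @param max_patients guard on the total cohort size.
#' @return A `data.frame` with columns `hospital_id`, the covariates, and
#'   integer `outcome` (1 = worst category); the generating scale is
#'   attached as attribute `"scale"`.
#' @export
simulate_cohort <- function(gen, cov_model, H, n_per_hospital, effects,
                            seed = NULL, max_patients = 2e6) {
  stopifnot(inherits(gen, "outcome_generator"),
            inherits(effects, "center_effects"))
  H <- stop_if_not_count(H, "H")
  n_per_hospital <- stop_if_not_count(n_per_hospital, "n_per_hospital")
  if (length(effects$beta) != H)
    stop("'effects' must contain exactly one effect per hospital")
  n <- H * n_per_hospital
  if (n > max_patients)
    stop(sprintf("cohort of %d patients exceeds max_patients = %g", n,
                 max_patients))
  with_seed(seed, {
    covs <- if (is.null(cov_model)) NULL else sample_covariates(cov_model, n)
    hospital_id <- rep(seq_len(H), each = n_per_hospital)
    P <- outcome_probabilities(gen, covs, beta = effects$beta[hospital_id])
    outcome <- .sample_categories(P)
    out <- if (is.null(covs)) data.frame(hospital_id = hospital_id)
           else data.frame(hospital_id = hospital_id, covs)
    out$outcome <- outcome
    attr(out, "scale") <- gen$scale
    out
  })
}

#' Read and write patient cohorts as CSV
#'
#' Plain CSV with header (`hospital_id`, covariates..., `outcome`);
#' character columns come back as factors so that design matrices are
#' reproducible.
#'
#' @param cohort cohort `data.frame` as from [simulate_cohort()].
#' @param path file path.
#' @param scale optional [outcome_scale()] to attach on read.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, scale = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = TRUE)
  if (!all(c("hospital_id", "outcome") %in% names(x)))
    stop("cohort file must have 'hospital_id' and 'outcome' columns")
  if (!is.null(scale)) attr(x, "scale") <- scale
  x
}
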