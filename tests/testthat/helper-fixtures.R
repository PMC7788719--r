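# Shared fixtures: small cohorts built in code.

# Cohort with known per-hospital effects from the TBI template.
tiny_cohort <- function(H = 4L, n_per = 50L, beta = rep(0, H), seed = 11L,
                        template = "impact") {
  tpl <- study_template(template)
  eff <- structure(list(beta = beta, sd = stats::sd(beta), scenario = "A"),
                   class = "center_effects")
  simulate_cohort(tpl$generator, tpl$cov_model, H, n_per, eff, seed = seed)
}

# Minimal hand-built center_fit for outlier-rule arithmetic.
fake_fit <- function(d, se, se_mean = 0.1) {
  nm <- as.character(seq_along(d))
  structure(list(center_effects = stats::setNames(d, nm),
                 se = stats::setNames(se, nm),
                 vcov = diag(se^2), se_mean = se_mean,
                 covariate_coefs = numeric(0), thresholds = 0,
                 loglik = 0, converged = TRUE, iterations = 1L,
                 grad_max = 0, non_estimable = character(0),
                 analysis = "ordinal", scale = builtin_scale("gos4"),
                 H = length(d), nobs = 100L),
            class = "center_fit")
}
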