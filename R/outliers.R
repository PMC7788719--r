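#' Flag outlying hospitals from a center-effect fit
#'
#' Scores each estimable hospital against the overall mean center effect at
#' the `1 - alpha` confidence level. Three rules are available; all compare
#' the deviation-from-mean estimate `d_h` to a normal critical value
#' `z = qnorm(1 - alpha/2)`:
#'
#' * `"ci_screen"` (default): flag when `|d_h| > z * sqrt(se_h^2 + mean(se^2))`,
#'   i.e. the hospital's estimate must clear the joint uncertainty of its own
#'   effect and that of a typical center. This conservative screening is
#'   what per-hospital confidence intervals built from the model's
#'   hospital-coefficient standard errors produce, and it keeps the
#'   fraction of false outliers under the null well below 1%.
#' * `"wald_vs_mean"`: the exact per-hospital Wald test `|d_h| / se_h > z`,
#'   with a per-hospital type-I rate of about `alpha`.
#' * `"mean_ci"`: flag when `d_h` falls outside `z` times the standard error
#'   of the overall mean effect (the literal "outside the CI of the mean"
#'   reading).
#'
#' Non-estimable hospitals are never flagged.
#'
#' @param fit a [fit_center_effects()] result.
#' @param rule detection rule, see Details.
#' @param alpha two-sided significance level (default 0.05, i.e. 95% CIs).
#' @return Object of class `center_outliers`: list with `flags` (per
#'   hospital: `"outlier"`, `"not_outlier"` or `"non_estimable"`),
#'   `n_flagged`, `n_estimable`, `rule`, `alpha`, `threshold` description.
#' @export
flag_outliers <- function(fit, rule = c("ci_screen", "wald_vs_mean",
                                        "mean_ci"),
                          alpha = 0.05) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "center_fit"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  d <- fit$center_effects
  se <- fit$se
  est <- !is.na(d)
  if (!any(est)) stop("no estimable hospitals in fit")
  if (any(se[est] <= 0 & abs(d[est]) > 0))
    stop("missing or zero standard errors for estimable hospitals")
  z <- stats::qnorm(1 - alpha / 2)
  crit <- switch(rule,
    ci_screen = z * sqrt(se^2 + mean(se[est]^2)),
    wald_vs_mean = z * se,
    mean_ci = rep(z * fit$se_mean, length(d)))
  out <- ifelse(!est, "non_estimable",
                ifelse(abs(d) > crit, "outlier", "not_outlier"))
  structure(list(flags = stats::setNames(out, names(d)),
                 n_flagged = sum(out == "outlier"),
                 n_estimable = sum(est), rule = rule, alpha = alpha,
                 analysis = fit$analysis),
            class = "center_outliers")
}

#' @export
print.center_outliers <- function(x, ...) {
  cat(sprintf(
    "Outlier detection (%s rule, alpha = %g, %s analysis):\n  %d of %d estimable hospitals flagged",
    x$rule, x$alpha, x$analysis, x$n_flagged, x$n_estimable))
  ne <- sum(x$flags == "non_estimable")
  if (ne) cat(sprintf(" (%d non-estimable)", ne))
  cat("\n")
  if (x$n_flagged)
    cat("  flagged:", paste(names(x$flags)[x$flags == "outlier"],
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.center_outliers <- function(x, ...) {
  data.frame(hospital_id = names(x$flags), flag = unname(x$flags),
             stringsAsFactors = FALSE)
}
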