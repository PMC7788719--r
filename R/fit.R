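# Core fixed-effect fitters.
#
# Both analysis models are fitted with hospital as a categorical variable in
# reference coding (numerically full-rank), then transformed to
# deviations-from-the-mean with full-covariance delta-method standard
# errors. The proportional-odds likelihood is maximized by Newton iterations
# on the observed information with step-halving; the binary model by IRLS
# via stats::glm.fit.

# Proportional-odds (cumulative logit) Newton fitter.
#   logit P(Y >= k) = theta_k + x'beta,  k = 2..K, theta strictly decreasing.
# y: integer 1..K; X: n x p design (no intercept; thresholds absorb it).
# Returns parameters in order (theta_2..theta_K, beta_1..beta_p).
.fit_po <- function(y, K, X, tol = 1e-8, maxit = 100L) {
  n <- length(y)
  p <- ncol(X)
  counts <- tabulate(y, nbins = K)
  if (sum(counts > 0L) < 2L) stop("need at least 2 observed outcome categories")
  # start: empirical cumulative logits (clamped), beta = 0
  cum <- rev(cumsum(rev(counts)))[-1L] / n
  cum <- pmin(pmax(cum, 0.5 / n), 1 - 0.5 / n)
  cum <- rev(cummax(rev(cum + seq_len(K - 1L) * 1e-9)))  # ensure decreasing
  theta <- stats::qlogis(cum)
  beta <- numeric(p)
  par <- c(theta, beta)

  lo_idx <- y - 1L          # theta slot of eta_y   (0 when y == 1)
  hi_idx <- ifelse(y < K, y, 0L)  # theta slot of eta_{y+1}
  has_lo <- lo_idx > 0L
  has_hi <- hi_idx > 0L

  loglik_at <- function(par) {
    theta <- par[seq_len(K - 1L)]
    if (is.unsorted(rev(theta), strictly = TRUE)) return(-Inf)
    eta <- if (p) drop(X %*% par[K:(K + p - 1L)]) else numeric(n)
    S <- stats::plogis(outer(eta, theta, "+"))     # n x (K-1), col k-1 = P(Y>=k)
    G <- cbind(1, S, 0)
    pr <- G[cbind(seq_len(n), y)] - G[cbind(seq_len(n), y + 1L)]
    if (any(pr <= 0)) return(-Inf)
    sum(log(pr))
  }

  ll <- loglik_at(par)
  if (!is.finite(ll)) stop("invalid starting values for proportional-odds fit")
  converged <- FALSE
  H <- NULL
  iter <- 0L
  grad_max <- Inf
  for (iter in seq_len(maxit)) {
    theta <- par[seq_len(K - 1L)]
    eta <- if (p) drop(X %*% par[K:(K + p - 1L)]) else numeric(n)
    lin_lo <- ifelse(has_lo, theta[pmax(lo_idx, 1L)] + eta, 0)
    lin_hi <- ifelse(has_hi, theta[pmax(hi_idx, 1L)] + eta, 0)
    sig_lo <- stats::plogis(lin_lo)
    sig_hi <- stats::plogis(lin_hi)
    phi_lo <- ifelse(has_lo, sig_lo * (1 - sig_lo), 0)
    phi_hi <- ifelse(has_hi, sig_hi * (1 - sig_hi), 0)
    Slo <- ifelse(has_lo, sig_lo, 1)   # P(Y >= y)
    Shi <- ifelse(has_hi, sig_hi, 0)   # P(Y >= y+1)
    pr <- Slo - Shi
    glo <- phi_lo / pr
    ghi <- phi_hi / pr

    # gradient
    g_theta <- numeric(K - 1L)
    t1 <- rowsum(glo[has_lo], lo_idx[has_lo])
    g_theta[as.integer(rownames(t1))] <- t1
    t2 <- rowsum(ghi[has_hi], hi_idx[has_hi])
    g_theta[as.integer(rownames(t2))] <-
      g_theta[as.integer(rownames(t2))] - t2
    g_beta <- if (p) drop(crossprod(X, glo - ghi)) else numeric(0)
    g <- c(g_theta, g_beta)
    grad_max <- max(abs(g))
    if (grad_max < tol) { converged <- TRUE }

    # observed-information Hessian of the log-likelihood
    dphi_lo <- ifelse(has_lo, phi_lo * (1 - 2 * sig_lo), 0)
    dphi_hi <- ifelse(has_hi, phi_hi * (1 - 2 * sig_hi), 0)
    w_ll <- dphi_lo / pr - glo^2
    w_hh <- -dphi_hi / pr - ghi^2
    w_lh <- glo * ghi
    w_ll[!has_lo] <- 0; w_hh[!has_hi] <- 0
    w_lh[!(has_lo & has_hi)] <- 0

    Htt <- matrix(0, K - 1L, K - 1L)
    d1 <- rowsum(w_ll[has_lo], lo_idx[has_lo])
    Htt[cbind(as.integer(rownames(d1)), as.integer(rownames(d1)))] <- d1
    d2 <- rowsum(w_hh[has_hi], hi_idx[has_hi])
    jj <- as.integer(rownames(d2))
    Htt[cbind(jj, jj)] <- Htt[cbind(jj, jj)] + d2
    both <- has_lo & has_hi
    if (any(both)) {
      d3 <- rowsum(w_lh[both], lo_idx[both])
      jj <- as.integer(rownames(d3))      # couples theta slots jj and jj+1
      Htt[cbind(jj, jj + 1L)] <- Htt[cbind(jj, jj + 1L)] + d3
      Htt[cbind(jj + 1L, jj)] <- Htt[cbind(jj + 1L, jj)] + d3
    }
    if (p) {
      Hbb <- crossprod(X, X * (w_ll + w_hh + 2 * w_lh))
      M <- matrix(0, n, K - 1L)
      M[cbind(which(has_lo), lo_idx[has_lo])] <- (w_ll + w_lh)[has_lo]
      M[cbind(which(has_hi), hi_idx[has_hi])] <-
        M[cbind(which(has_hi), hi_idx[has_hi])] + (w_hh + w_lh)[has_hi]
      Htb <- crossprod(M, X)
      H <- rbind(cbind(Htt, Htb), cbind(t(Htb), Hbb))
    } else H <- Htt
    if (converged) break

    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix in proportional-odds fit")
    step <- -step                     # H is negative definite at solutions
    # step-halving: likelihood must not decrease, thresholds stay ordered
    lam <- 1
    repeat {
      cand <- par + lam * step
      ll_new <- loglik_at(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      lam <- lam / 2
      if (lam < 1e-10) stop("step-halving failed in proportional-odds fit")
    }
    par <- par + lam * step
    ll <- ll_new
  }
  vcov <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, length(par), length(par)))
  list(theta = par[seq_len(K - 1L)],
       beta = if (p) par[K:(K + p - 1L)] else numeric(0),
       vcov = vcov, loglik = loglik_at(par), converged = converged,
       iter = iter, grad_max = grad_max)
}

# Binary logistic fit via IRLS (glm.fit); same return shape as .fit_po with
# the intercept playing the role of the single cumulative intercept.
.fit_bin <- function(y, X, tol = 1e-10, maxit = 100L) {
  X1 <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(
    X1, y, family = stats::binomial(),
    control = list(epsilon = tol, maxit = maxit)))
  mu <- fit$fitted.values
  # crossprod(sqrt(w) X) is the Fisher information for logistic regression
  vcov <- tryCatch(solve(crossprod(X1 * sqrt(fit$weights))),
                   error = function(e) matrix(NA_real_, ncol(X1), ncol(X1)))
  list(theta = fit$coefficients[1L],
       beta = fit$coefficients[-1L],
       vcov = vcov,
       loglik = sum(stats::dbinom(y, 1, mu, log = TRUE)),
       converged = fit$converged, iter = fit$iter,
       grad_max = max(abs(crossprod(X1, y - mu))))
}

# Hospitals whose outcomes are all in a single category are separated
# (their fixed-effect MLE is infinite); they are excluded from the fit and
# reported as non-estimable.
.degenerate_hospitals <- function(y, hosp) {
  rng <- tapply(y, hosp, function(v) length(unique(v)))
  names(rng)[rng < 2L]
}

# Deviation-from-mean transform with delta-method covariance.
# b_ref: coefficients of hospitals 2..H' versus hospital 1; Sigma_ref their
# covariance (from the fit's vcov). Returns deviations summing to zero, the
# full deviation covariance, and the SE of the overall mean effect.
.deviations_from_mean <- function(b_ref, Sigma_ref) {
  Hp <- length(b_ref) + 1L
  b <- c(0, b_ref)
  Sigma <- matrix(0, Hp, Hp)
  if (Hp > 1L) Sigma[-1L, -1L] <- Sigma_ref
  C <- diag(Hp) - 1 / Hp
  d <- drop(C %*% b)
  Sd <- C %*% Sigma %*% C
  list(d = d, se = sqrt(pmax(diag(Sd), 0)), vcov = Sd,
       se_mean = sqrt(max(sum(Sigma), 0)) / Hp)
}

#' Fit center effects with hospital as a categorical variable
#'
#' The workhorse fitter. Fits a fixed-effect regression of the outcome on
#' the case-mix covariates plus hospital as a categorical variable --
#' proportional-odds (cumulative logit) regression for the ordinal analysis,
#' binary logistic regression for the dichotomized analyses -- and expresses
#' each hospital's estimated center effect as its deviation from the mean
#' center effect, with delta-method standard errors from the full
#' coefficient covariance. Positive deviations mean better-than-average
#' outcomes.
#'
#' Hospitals whose patients all share one outcome value are separated (their
#' maximum-likelihood effect is infinite); they are dropped from the fit,
#' excluded from the mean, and reported in `non_estimable`.
#'
#' @param data cohort `data.frame` (e.g. from [simulate_cohort()] or
#'   [read_cohort()]) with a hospital column and an integer ordinal outcome.
#' @param analysis `"ordinal"` (full scale), `"favorable"` (favorable vs
#'   unfavorable dichotomy) or `"mortality"` (bottom collapsed category vs
#'   the rest).
#' @param scale an [outcome_scale()]; defaults to `attr(data, "scale")`.
#' @param covariates covariate column names for case-mix adjustment;
#'   defaults to every column except hospital and outcome. Use
#'   `character(0)` for an unadjusted fit.
#' @param hospital,outcome column names.
#' @return An object of class `center_fit` with elements `center_effects`
#'   (named deviations; `NA` for non-estimable hospitals), `se`, `vcov`
#'   (deviation covariance), `se_mean`, `covariate_coefs`, `thresholds`
#'   (cumulative intercepts, `logit P(Y >= k)` at the reference hospital and
#'   covariate baseline; a single intercept for binary analyses), `loglik`,
#'   `converged`, `non_estimable`, `analysis`, `H`, `nobs`.
#' @seealso [flag_outliers()] for the outlier rules, [summary.center_fit()].
#' @export
fit_center_effects <- function(data,
                               analysis = c("ordinal", "favorable",
                                            "mortality"),
                               scale = attr(data, "scale"),
                               covariates = NULL,
                               hospital = "hospital_id",
                               outcome = "outcome") {
  analysis <- match.arg(analysis)
  stopifnot(is.data.frame(data))
  if (is.null(scale))
    stop("an outcome_scale is required (pass 'scale' or attach attr(data, 'scale'))")
  stopifnot(inherits(scale, "outcome_scale"))
  yord <- as.integer(data[[outcome]])
  if (anyNA(yord) || min(yord) < 1L || max(yord) > scale$n_categories)
    stop(sprintf("outcomes must be category indices in 1..%d",
                 scale$n_categories))
  y <- switch(analysis,
              ordinal = yord,
              favorable = dichotomize(yord, scale, "favorable"),
              mortality = dichotomize(yord, scale, "mortality"))
  K <- if (analysis == "ordinal") scale$n_categories else 2L
  if (analysis != "ordinal") y <- y + 1L   # recode 0/1 -> 1/2 internally

  hosp_all <- factor(data[[hospital]])
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(hospital, outcome))
  bad <- .degenerate_hospitals(y, hosp_all)
  keep <- !(hosp_all %in% bad)
  if (!any(keep))
    stop("no estimable hospitals: every hospital has a degenerate outcome distribution")
  y <- y[keep]
  hosp <- droplevels(hosp_all[keep])
  Hp <- nlevels(hosp)
  if (length(unique(y)) < 2L)
    stop("outcome is constant among estimable hospitals")

  Xh <- if (Hp > 1L) stats::model.matrix(~ hosp)[, -1L, drop = FALSE]
        else matrix(nrow = length(y), ncol = 0L)
  Xc <- if (length(covariates))
          stats::model.matrix(~ ., data = data[keep, covariates,
                                               drop = FALSE])[, -1L,
                                                              drop = FALSE]
        else matrix(nrow = length(y), ncol = 0L)
  X <- cbind(Xh, Xc)
  ih <- seq_len(ncol(Xh))
  ic <- if (ncol(Xc)) ncol(Xh) + seq_len(ncol(Xc)) else integer(0)

  fit <- if (analysis == "ordinal") .fit_po(y, K, X)
         else .fit_bin(as.integer(y == 2L), X)
  if (!fit$converged)
    warning(sprintf("%s fit did not converge (max |gradient| = %.2e)",
                    analysis, fit$grad_max))

  nb <- K - 1L                             # threshold block size in vcov
  bh <- if (length(ih)) fit$beta[ih] else numeric(0)
  Sh <- fit$vcov[nb + ih, nb + ih, drop = FALSE]
  dev <- .deviations_from_mean(bh, Sh)

  lev_all <- levels(hosp_all)
  ce <- se <- stats::setNames(rep(NA_real_, length(lev_all)), lev_all)
  ce[levels(hosp)] <- dev$d
  se[levels(hosp)] <- dev$se
  V <- matrix(NA_real_, length(lev_all), length(lev_all),
              dimnames = list(lev_all, lev_all))
  V[levels(hosp), levels(hosp)] <- dev$vcov

  cc <- if (length(ic)) stats::setNames(fit$beta[ic], colnames(Xc))
        else stats::setNames(numeric(0), character(0))
  structure(
    list(center_effects = ce, se = se, vcov = V, se_mean = dev$se_mean,
         covariate_coefs = cc,
         thresholds = stats::setNames(
           fit$theta,
           if (analysis == "ordinal")
             paste0("logitP(Y>=", 2:K, ")") else "(Intercept)"),
         loglik = fit$loglik, converged = fit$converged,
         iterations = fit$iter, grad_max = fit$grad_max,
         non_estimable = bad, analysis = analysis, scale = scale,
         H = length(lev_all), nobs = length(y),
         call = match.call()),
    class = "center_fit")
}

#' Fit a binary logistic center-effect model
#'
#' Thin wrappers around [fit_center_effects()] for cohorts whose outcome is
#' already coded: `fit_binary_logistic` expects a 0/1 outcome column and
#' fits the standard fixed-effect logistic regression;
#' `fit_proportional_odds` expects ordinal category indices and fits the
#' cumulative-logit model with common slopes. With two categories the two
#' fits coincide.
#'
#' @inheritParams fit_center_effects
#' @return A `center_fit`.
#' @export
fit_binary_logistic <- function(data, covariates = NULL,
                                hospital = "hospital_id",
                                outcome = "outcome") {
  y <- data[[outcome]]
  if (!all(y %in% c(0L, 1L))) stop("outcome must be 0/1 for the binary fit")
  data[[outcome]] <- as.integer(y) + 1L
  sc <- outcome_scale("binary", c("event", "no event"), favorable_cut = 2L)
  fit <- fit_center_effects(data, analysis = "ordinal", scale = sc,
                            covariates = covariates, hospital = hospital,
                            outcome = outcome)
  fit$analysis <- "binary"
  fit
}

#' @rdname fit_binary_logistic
#' @param scale the [outcome_scale()] of the ordinal outcome.
#' @export
fit_proportional_odds <- function(data, scale = attr(data, "scale"),
                                  covariates = NULL,
                                  hospital = "hospital_id",
                                  outcome = "outcome") {
  fit_center_effects(data, analysis = "ordinal", scale = scale,
                     covariates = covariates, hospital = hospital,
                     outcome = outcome)
}

#' @export
print.center_fit <- function(x, ...) {
  cat(sprintf("Center-effect fit (%s analysis): %d hospitals, %d patients\n",
              x$analysis, x$H, x$nobs))
  cat(sprintf("  log-likelihood %.3f, converged: %s (%d iterations)\n",
              x$loglik, x$converged, x$iterations))
  est <- x$center_effects[!is.na(x$center_effects)]
  cat(sprintf("  center-effect deviations: range [%.3f, %.3f], SD %.3f\n",
              min(est), max(est), stats::sd(est)))
  if (length(x$non_estimable))
    cat("  non-estimable hospitals:",
        paste(x$non_estimable, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a center-effect fit
#'
#' @param object a `center_fit`.
#' @param ... unused.
#' @return A `data.frame` with one row per hospital: estimate (deviation
#'   from the mean), SE, Wald z, and estimability flag.
#' @export
summary.center_fit <- function(object, ...) {
  out <- data.frame(hospital_id = names(object$center_effects),
                    estimate = unname(object$center_effects),
                    se = unname(object$se),
                    z = unname(object$center_effects / object$se),
                    estimable = !is.na(object$center_effects),
                    stringsAsFactors = FALSE)
  attr(out, "analysis") <- object$analysis
  out
}

#' @export
coef.center_fit <- function(object, ...) object$center_effects

#' @export
vcov.center_fit <- function(object, ...) object$vcov

#' @export
logLik.center_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$thresholds) +
              sum(!is.na(object$center_effects)) - 1L +
              length(object$covariate_coefs),
            nobs = object$nobs, class = "logLik")
}

#' @export
confint.center_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$center_effects
  out <- cbind(est - z * object$se, est + z * object$se)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2,
                                        1 - (1 - level) / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
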