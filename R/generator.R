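#' Outcome generators
#'
#' An `outcome_generator` maps a patient's baseline covariates and their
#' hospital's center effect to a probability vector over the categories of an
#' [outcome_scale()]. Two modes exist:
#'
#' * **configured**: category marginals are stated directly (optionally with
#'   covariate coefficients on the cumulative-logit scale). The marginals are
#'   stored as strictly ordered cumulative intercepts
#'   `theta_k = logit P(Y >= k)`, k = 2..K.
#' * **fitted**: a multinomial (generalized) logit model estimated from a
#'   user-supplied patient-level table via [fit_generator()].
#'
#' In both modes a hospital's center effect `beta` enters as an additive
#' shift on *every* cumulative logit, `logit P(Y >= k) + beta`, so a positive
#' effect raises the chance of a good outcome uniformly across cut points
#' (the proportional-odds mechanism). This keeps the analysis model
#' correctly specified when true center effects are present.
#'
#' @param scale an [outcome_scale()].
#' @param probs baseline category probabilities, worst to best; positive,
#'   normalized to sum to 1.
#' @param coefs optional named numeric vector of covariate coefficients on
#'   the cumulative-logit scale, matched against columns of
#'   `model.matrix(~ ., covariates)`.
#' @return An object of class `outcome_generator`.
#' @export
configured_generator <- function(scale, probs, coefs = NULL) {
  stopifnot(inherits(scale, "outcome_scale"))
  K <- scale$n_categories
  if (length(probs) != K) stop("'probs' must have one entry per category")
  if (any(probs <= 0)) stop("all category probabilities must be positive")
  probs <- probs / sum(probs)
  # theta_k = logit P(Y >= k), strictly decreasing in k
  theta <- stats::qlogis(rev(cumsum(rev(probs)))[-1L])
  if (!is.null(coefs) && is.null(names(coefs)))
    stop("'coefs' must be named")
  structure(list(mode = "configured", scale = scale,
                 baseline = as.numeric(probs), theta = as.numeric(theta),
                 coefs = coefs),
            class = "outcome_generator")
}

#' @export
print.outcome_generator <- function(x, ...) {
  cat(sprintf("Outcome generator (%s mode) on scale '%s' (%d categories)\n",
              x$mode, x$scale$name, x$scale$n_categories))
  cat("Baseline category probabilities (worst to best):\n")
  print(round(stats::setNames(x$baseline, x$scale$categories), 4))
  invisible(x)
}

#' Study outcome templates
#'
#' Configured generators reproducing the published marginal outcome
#' distributions. The TBI template uses the 4-point collapsed GOS with 32%
#' in the bottom (death/vegetative) category and 52% favorable; the stroke
#' template the 6-point collapsed mRS with 21% in the bottom (death/mRS 5)
#' category and 56% favorable (mRS 0-2). Within-band splits not pinned down
#' by those figures are fixed at values typical for the respective
#' populations (see the methods vignette).
#'
#' @return An `outcome_generator` in configured mode.
#' @export
impact_generator <- function() {
  configured_generator(builtin_scale("gos4"),
                       probs = c(0.32, 0.16, 0.22, 0.30))
}

#' @rdname impact_generator
#' @export
practise_generator <- function() {
  configured_generator(builtin_scale("mrs6"),
                       probs = c(0.21, 0.11, 0.12, 0.17, 0.22, 0.17))
}

# Linear predictor from configured-mode covariate coefficients (0 if none).
.cov_lp <- function(gen, covariates, n) {
  if (is.null(gen$coefs) || !length(gen$coefs)) return(rep(0, n))
  if (is.null(covariates)) stop("generator has covariate coefficients but no covariates were supplied")
  mm <- stats::model.matrix(~ ., data = covariates)
  miss <- setdiff(names(gen$coefs), colnames(mm))
  if (length(miss))
    stop("covariate coefficients refer to unknown design columns: ",
         paste(miss, collapse = ", "))
  drop(mm[, names(gen$coefs), drop = FALSE] %*% gen$coefs)
}

# Multinomial-logit probabilities for a fitted generator.
.multinom_probs <- function(gen, covariates) {
  if (is.null(covariates)) {
    if (!length(gen$covariates)) covariates <- data.frame(row.names = 1L)
    else stop("fitted generator requires covariates: ",
              paste(gen$covariates, collapse = ", "))
  }
  miss <- setdiff(gen$covariates, names(covariates))
  if (length(miss))
    stop("missing covariates: ", paste(miss, collapse = ", "))
  df <- covariates[gen$covariates]
  for (v in names(gen$xlevels)) df[[v]] <- factor(df[[v]], levels = gen$xlevels[[v]])
  mm <- if (length(gen$covariates)) stats::model.matrix(~ ., data = df)
        else matrix(1, nrow = max(nrow(df), 1L), ncol = 1L)
  eta <- mm %*% t(gen$coef)                       # n x (K-1), vs category 1
  expeta <- cbind(1, exp(eta))
  expeta / rowSums(expeta)
}

#' Per-category outcome probabilities
#'
#' Computes, for each covariate profile, the probability of each outcome
#' category under a generator, with a hospital center effect applied as an
#' additive shift on all cumulative logits. `beta = 0` returns the
#' generator's baseline probabilities unchanged.
#'
#' @param gen an `outcome_generator`.
#' @param covariates `data.frame` of covariate profiles (may be `NULL` when
#'   the generator uses none), one row per patient.
#' @param beta center effect(s) on the log-odds scale; scalar or one per row.
#' @return Numeric matrix, rows = profiles, columns = categories (worst to
#'   best); each row sums to 1.
#' @export
outcome_probabilities <- function(gen, covariates = NULL, beta = 0) {
  stopifnot(inherits(gen, "outcome_generator"))
  K <- gen$scale$n_categories
  n <- if (!is.null(covariates)) nrow(covariates)
       else max(length(beta), 1L)
  if (!length(beta)) beta <- 0
  if (length(beta) == 1L) beta <- rep(beta, n)
  if (length(beta) != n) stop("'beta' must be scalar or one value per profile")
  if (anyNA(beta)) stop("non-finite center effect")

  if (gen$mode == "configured") {
    lp <- .cov_lp(gen, covariates, n) + beta
    if (any(is.nan(lp))) stop("non-finite linear predictor")
    # S[, k-1] = P(Y >= k | profile)
    S <- stats::plogis(outer(lp, gen$theta, "+"))
  } else {
    base <- .multinom_probs(gen, covariates)
    if (nrow(base) != n) stop("covariate/beta dimension mismatch")
    # cumulative P(Y >= k) of the multinomial baseline, then shift
    cum <- t(apply(base, 1L, function(p) rev(cumsum(rev(p)))))[, -1L, drop = FALSE]
    cum <- pmin(pmax(cum, 1e-12), 1 - 1e-12)
    S <- stats::plogis(stats::qlogis(cum) + beta)
  }
  P <- cbind(1, S) - cbind(S, 0)
  colnames(P) <- gen$scale$categories
  P
}

#' Fit a multinomial outcome generator to patient-level data
#'
#' Estimates a multinomial generalized-logit model for the ordinal outcome
#' given baseline covariates (maximum likelihood, category 1 as reference),
#' returning a generator in `"fitted"` mode whose predicted marginals match
#' the observed ones at the sample level. Every outcome category must be
#' observed at least once; coefficients of implausible magnitude trigger a
#' separation error.
#'
#' @param data `data.frame` with an integer outcome column (category
#'   indices) and covariate columns.
#' @param scale the [outcome_scale()] of the outcome.
#' @param outcome name of the outcome column.
#' @param covariates names of covariate columns; defaults to all columns
#'   except the outcome and `hospital_id`.
#' @return An `outcome_generator` in fitted mode.
#' @export
fit_generator <- function(data, scale, outcome = "outcome",
                          covariates = setdiff(names(data),
                                               c(outcome, "hospital_id"))) {
  stopifnot(inherits(scale, "outcome_scale"), is.data.frame(data))
  K <- scale$n_categories
  y <- as.integer(data[[outcome]])
  if (anyNA(y) || !length(y)) stop("invalid outcome column")
  counts <- tabulate(y, nbins = K)
  if (min(y) < 1L || max(y) > K)
    stop(sprintf("outcome indices must be in 1..%d", K))
  if (any(counts == 0L))
    stop("every outcome category must be observed at least once; empty: ",
         paste(which(counts == 0L), collapse = ", "))
  df <- data.frame(.y = factor(y, levels = seq_len(K)),
                   data[covariates], check.names = FALSE)
  form <- if (length(covariates)) .y ~ . else .y ~ 1
  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 500,
                        MaxNWts = 10000)
  cf <- stats::coef(fit)
  if (K == 2L) cf <- matrix(cf, nrow = 1L,
                            dimnames = list("2", names(cf)))
  if (any(abs(cf) > 15))
    stop("apparent separation: multinomial coefficients diverged")
  xlev <- lapply(Filter(is.factor, df[covariates]), levels)
  gen <- structure(
    list(mode = "fitted", scale = scale, coef = unname(as.matrix(cf)),
         coef_names = colnames(cf), covariates = covariates,
         xlevels = xlev, baseline = NULL),
    class = "outcome_generator")
  gen$baseline <- colMeans(.multinom_probs(gen, data[covariates]))
  gen
}

#' Serialize a generator to JSON and back
#'
#' Configured and fitted generators round-trip through a plain JSON file
#' (scale, mode, marginals/coefficient table).
#'
#' @param gen an `outcome_generator`.
#' @param path file path.
#' @return `read_generator` returns an `outcome_generator`;
#'   `write_generator` returns `path` invisibly.
#' @export
write_generator <- function(gen, path) {
  stopifnot(inherits(gen, "outcome_generator"))
  x <- unclass(gen)
  x$scale <- unclass(x$scale)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_generator
#' @export
read_generator <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- outcome_scale(x$scale$name, x$scale$categories,
                      x$scale$favorable_cut, x$scale$mortality_cut)
  if (x$mode == "configured") {
    configured_generator(sc, x$baseline,
                         coefs = if (length(x$coefs)) unlist(x$coefs))
  } else {
    structure(list(mode = "fitted", scale = sc,
                   coef = matrix(unlist(x$coef), nrow = sc$n_categories - 1L),
                   coef_names = x$coef_names, covariates = x$covariates,
                   xlevels = lapply(x$xlevels, as.character),
                   baseline = as.numeric(x$baseline)),
              class = "outcome_generator")
  }
}
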