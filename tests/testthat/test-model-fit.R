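# Independent log-likelihood for the cumulative-logit model, written
# directly from the category probabilities (kept separate from the package's
# fitter so it can serve as an oracle).
naive_po_loglik <- function(par, y, K, X) {
  theta <- par[seq_len(K - 1L)]
  if (is.unsorted(rev(theta), strictly = TRUE)) return(-Inf)
  beta <- par[-seq_len(K - 1L)]
  eta <- if (length(beta)) drop(X %*% beta) else rep(0, length(y))
  ll <- 0
  for (i in seq_along(y)) {
    cum <- c(1, plogis(theta + eta[i]), 0)   # P(Y >= 1..K+1)
    p <- cum[y[i]] - cum[y[i] + 1L]
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

test_that("intercept-only binary fit equals the closed-form sample log-odds", {
  dat <- data.frame(hospital_id = 1L,
                    outcome = rep(c(1L, 0L), c(4949L, 4629L)))
  fit <- fit_binary_logistic(dat, covariates = character(0))
  expect_equal(unname(fit$thresholds), log(4949 / 4629), tolerance = 1e-8)
  expect_equal(unname(fit$center_effects), 0)
})

test_that("a single binary covariate recovers the 2x2 table log odds ratio", {
  # x = 0: 30 events / 70 non-events;  x = 1: 45 / 55
  dat <- data.frame(hospital_id = 1L,
                    x = rep(c(0, 0, 1, 1), c(30, 70, 45, 55)),
                    outcome = rep(c(1L, 0L, 1L, 0L), c(30, 70, 45, 55)))
  fit <- fit_binary_logistic(dat, covariates = "x")
  expect_equal(unname(fit$covariate_coefs["x"]), 0.6466271649,
               tolerance = 1e-8)
  expect_equal(unname(fit$thresholds), log(30 / 70), tolerance = 1e-8)
})

test_that("proportional-odds optimum matches a derivative-free optimizer on tiny data", {
  set.seed(41)
  n <- 30L
  dat <- data.frame(hospital_id = rep(1:2, each = n / 2),
                    x = rnorm(n),
                    outcome = sample(1:3, n, replace = TRUE,
                                     prob = c(0.3, 0.4, 0.3)))
  sc <- outcome_scale("k3", c("low", "mid", "high"), favorable_cut = 3)
  fit <- fit_center_effects(dat, "ordinal", scale = sc, covariates = "x")
  X <- cbind(h2 = as.numeric(dat$hospital_id == 2), x = dat$x)
  orc <- optim(c(0.5, -0.5, 0, 0), naive_po_loglik, y = dat$outcome, K = 3L,
               X = X, method = "Nelder-Mead",
               control = list(fnscale = -1, reltol = 1e-14, maxit = 20000))
  expect_lt(abs(fit$loglik - orc$value), 1e-6)
  expect_gte(fit$loglik, orc$value - 1e-6)  # ours is the maximum
})

test_that("binary logistic optimum matches a derivative-free optimizer on tiny data", {
  set.seed(42)
  n <- 24L
  dat <- data.frame(hospital_id = rep(1:2, each = n / 2),
                    x = rnorm(n),
                    outcome = rbinom(n, 1, 0.5))
  fit <- fit_binary_logistic(dat, covariates = "x")
  X <- cbind(h2 = as.numeric(dat$hospital_id == 2), x = dat$x)
  orc <- optim(rep(0, 3), naive_po_loglik, y = dat$outcome + 1L, K = 2L,
               X = X, method = "Nelder-Mead",
               control = list(fnscale = -1, reltol = 1e-14, maxit = 20000))
  expect_lt(abs(fit$loglik - orc$value), 1e-6)
})

test_that("two-category proportional odds equals binary logistic", {
  coh <- tiny_cohort(H = 5L, n_per = 60L, beta = c(0.4, 0, 0, -0.2, 0.1),
                     seed = 43L)
  sc2 <- outcome_scale("bin", c("unfavorable", "favorable"),
                       favorable_cut = 2)
  dat <- coh
  dat$outcome <- dichotomize(coh$outcome, attr(coh, "scale"),
                             "favorable") + 1L
  po <- fit_center_effects(dat, "ordinal", scale = sc2)
  dat$outcome <- dat$outcome - 1L
  bin <- fit_binary_logistic(dat)
  expect_equal(po$loglik, bin$loglik, tolerance = 1e-6)
  expect_equal(po$center_effects, bin$center_effects, tolerance = 1e-5)
  expect_equal(po$se, bin$se, tolerance = 1e-5)
})

test_that("the proportional-odds fit agrees with an established implementation", {
  skip_if_not_installed("MASS")
  set.seed(44)
  coh <- tiny_cohort(H = 8L, n_per = 120L, beta = rnorm(8, 0, 0.35),
                     seed = 45L)
  fit <- fit_center_effects(coh, "ordinal")
  d <- coh
  d$y <- factor(d$outcome, levels = 1:4, ordered = TRUE)
  d$h <- factor(d$hospital_id)
  ref <- MASS::polr(y ~ h + age + sex + pupils + motor_score, data = d)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  b <- c(0, coef(ref)[paste0("h", 2:8)])
  expect_equal(unname(fit$center_effects), unname(b - mean(b)),
               tolerance = 1e-3)
})

test_that("center-effect deviations sum to zero with positive SEs", {
  set.seed(46)
  coh <- tiny_cohort(H = 6L, n_per = 80L, beta = rnorm(6, 0, 0.35),
                     seed = 47L)
  for (an in c("ordinal", "favorable", "mortality")) {
    fit <- fit_center_effects(coh, an)
    est <- fit$center_effects[!is.na(fit$center_effects)]
    expect_lt(abs(sum(est)), 1e-8)
    expect_true(all(fit$se[!is.na(fit$se)] > 0))
    expect_true(fit$converged)
    expect_lt(fit$grad_max, 1e-8)
  }
})

test_that("reversing the category order flips all signs", {
  coh <- tiny_cohort(H = 4L, n_per = 100L, beta = c(0.5, -0.5, 0.2, -0.2),
                     seed = 48L)
  sc <- attr(coh, "scale")
  fit <- fit_center_effects(coh, "ordinal", covariates = character(0))
  rev_dat <- coh
  rev_dat$outcome <- sc$n_categories + 1L - coh$outcome
  rev_sc <- outcome_scale("rev", rev(sc$categories), favorable_cut = 2)
  rfit <- fit_center_effects(rev_dat, "ordinal", scale = rev_sc,
                             covariates = character(0))
  expect_equal(fit$center_effects, -rfit$center_effects, tolerance = 1e-6)
  expect_equal(unname(fit$thresholds), rev(-unname(rfit$thresholds)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, rfit$loglik, tolerance = 1e-8)
})

test_that("standard errors shrink like one over root n", {
  set.seed(49)
  b <- rnorm(10, 0, 0.35)
  f1 <- fit_center_effects(tiny_cohort(H = 10L, n_per = 100L, beta = b,
                                       seed = 50L), "ordinal")
  f2 <- fit_center_effects(tiny_cohort(H = 10L, n_per = 200L, beta = b,
                                       seed = 51L), "ordinal")
  ratio <- median(f1$se, na.rm = TRUE) / median(f2$se, na.rm = TRUE)
  expect_equal(ratio, sqrt(2), tolerance = 0.1)
})

test_that("degenerate hospitals are flagged non-estimable and excluded", {
  set.seed(52)
  coh <- tiny_cohort(H = 4L, n_per = 30L, beta = rep(0, 4), seed = 53L)
  coh$outcome[coh$hospital_id == 3] <- 4L    # hospital 3 all top category
  fit <- fit_center_effects(coh, "ordinal")
  expect_equal(fit$non_estimable, "3")
  expect_true(is.na(fit$center_effects["3"]))
  est <- fit$center_effects[!is.na(fit$center_effects)]
  expect_lt(abs(sum(est)), 1e-8)             # mean over estimable set only
  # all outcomes identical -> no estimable information at all
  coh$outcome[] <- 2L
  expect_error(fit_center_effects(coh, "ordinal"), "degenerate|constant")
})
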