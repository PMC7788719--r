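test_that("zero center effect returns the configured baseline exactly", {
  gen <- impact_generator()
  P <- outcome_probabilities(gen, beta = 0)
  expect_equal(unname(P[1, ]), c(0.32, 0.16, 0.22, 0.30), tolerance = 1e-12)
})

test_that("a center effect shifts every cumulative logit additively", {
  # frozen values from direct cumulative-logit arithmetic on the baseline
  # (0.32, 0.16, 0.22, 0.30) with a shift of +0.35
  gen <- configured_generator(builtin_scale("gos4"),
                              c(0.32, 0.16, 0.22, 0.30))
  P <- outcome_probabilities(gen, beta = 0.35)
  expect_equal(unname(P[1, ]),
               c(0.2490338396, 0.1450822939, 0.2277079751, 0.3781758914),
               tolerance = 1e-9)
  # limit: a huge positive effect moves all mass to the top category
  Pinf <- outcome_probabilities(gen, beta = 50)
  expect_equal(unname(Pinf[1, 4]), 1, tolerance = 1e-6)
})

test_that("probability vectors sum to one and respect stochastic ordering", {
  gen <- practise_generator()
  betas <- seq(-3, 3, by = 0.5)
  P <- outcome_probabilities(gen, beta = betas)
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  expect_true(all(P > 0))
  # larger beta => P(Y >= k) larger for every k (exact, by construction)
  K <- ncol(P)
  cum <- t(apply(P, 1, function(p) rev(cumsum(rev(p)))))[, -1]
  for (k in seq_len(K - 1L))
    expect_true(all(diff(cum[, k]) > 0))
})

test_that("intercept-only multinomial fit recovers sample proportions", {
  counts <- c(320, 160, 220, 300)
  dat <- data.frame(outcome = rep(1:4, counts))
  gen <- fit_generator(dat, builtin_scale("gos4"), covariates = character(0))
  expect_equal(unname(gen$baseline), counts / sum(counts), tolerance = 1e-4)
})

test_that("multinomial fit recovers a known generator from simulated data", {
  # configured generator with a binary covariate effect on the cumulative
  # logits; within each covariate level the category probabilities are known
  # exactly, so the implied multinomial log-odds are available in closed form
  sc <- outcome_scale("k3", c("low", "mid", "high"), favorable_cut = 3)
  gen <- configured_generator(sc, c(0.3, 0.4, 0.3), coefs = c(grpb = 0.8))
  covs <- data.frame(grp = factor(rep(c("a", "b"), each = 5e4)))
  P <- outcome_probabilities(gen, covs, beta = 0)
  set.seed(301)
  y <- vapply(seq_len(nrow(covs)), function(i)
    sample.int(3L, 1L, prob = P[i, ]), integer(1))
  dat <- data.frame(outcome = y, grp = covs$grp)
  fit <- fit_generator(dat, sc, covariates = "grp")
  # closed-form implied multinomial coefficients vs category 1
  pa <- P[1, ]; pb <- P[nrow(P), ]
  true_int <- log(pa[2:3] / pa[1])
  true_slope <- log(pb[2:3] / pb[1]) - true_int
  expect_equal(unname(fit$coef[, 1]), unname(true_int), tolerance = 0.05)
  expect_equal(unname(fit$coef[, 2]), unname(true_slope), tolerance = 0.05)
  # predicted marginals match observed at the sample level
  Phat <- outcome_probabilities(fit, covs, beta = 0)
  expect_equal(colMeans(Phat), tabulate(y, 3) / length(y), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("empty outcome categories abort the generator fit", {
  dat <- data.frame(outcome = rep(c(1L, 2L, 4L), each = 20))
  expect_error(fit_generator(dat, builtin_scale("gos4"),
                             covariates = character(0)),
               "every outcome category")
})

test_that("generators round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  gen <- configured_generator(builtin_scale("mrs6"),
                              c(0.21, 0.11, 0.12, 0.17, 0.22, 0.17))
  write_generator(gen, path)
  back <- read_generator(path)
  expect_equal(back$baseline, gen$baseline, tolerance = 1e-12)
  expect_equal(back$theta, gen$theta, tolerance = 1e-12)
  expect_equal(outcome_probabilities(back, beta = 0.4),
               outcome_probabilities(gen, beta = 0.4), tolerance = 1e-12)

  dat <- data.frame(outcome = rep(1:3, c(30, 40, 30)),
                    grp = factor(rep(c("a", "b"), 50)))
  sc <- outcome_scale("k3", c("low", "mid", "high"), favorable_cut = 3)
  fg <- fit_generator(dat, sc, covariates = "grp")
  write_generator(fg, path)
  fback <- read_generator(path)
  expect_equal(outcome_probabilities(fback, dat["grp"], beta = 0.2),
               outcome_probabilities(fg, dat["grp"], beta = 0.2),
               tolerance = 1e-10)
})
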