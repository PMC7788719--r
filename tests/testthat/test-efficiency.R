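mk_curve <- function(n, power) {
  structure(data.frame(n = n, power = power, mc_se = 0),
            class = c("power_curve", "data.frame"), analysis = "test")
}

test_that("required n interpolates linearly on a monotone curve", {
  cv <- mk_curve(c(50, 100), c(0.20, 0.40))
  expect_equal(required_n(cv, 0.30), 75)
  # exact at grid points
  expect_equal(required_n(cv, 0.20), 50)
  expect_equal(required_n(cv, 0.40), 100)
  # target above the maximum is undefined
  expect_true(is.na(required_n(cv, 0.41)))
  # target below the minimum achieved power returns the smallest n
  expect_equal(required_n(cv, 0.05), 50)
  expect_error(required_n(cv, 1.2), "fraction")
  expect_error(required_n(cv, -0.1), "fraction")
})

test_that("non-monotone curves are isotonically smoothed before interpolation", {
  # pool-adjacent-violators by hand: (0.30, 0.20, 0.60) -> (0.25, 0.25, 0.60);
  # target 0.40 then interpolates between (50, 0.25) and (100, 0.60):
  # 50 + 0.15/0.35 * 50 = 500/7
  cv <- mk_curve(c(25, 50, 100), c(0.30, 0.20, 0.60))
  expect_equal(required_n(cv, 0.40), 500 / 7, tolerance = 1e-10)
  # required n is nonincreasing as the target drops
  targets <- seq(0.6, 0.05, by = -0.05)
  ns <- vapply(targets, function(t) required_n(cv, t), numeric(1))
  expect_true(all(diff(ns) <= 1e-12))
})

test_that("efficiency gain is the relative sample-size reduction", {
  expect_equal(efficiency_gain(73, 200), 0.635)
  expect_equal(efficiency_gain(73, 134), 0.455, tolerance = 5e-4)
  expect_equal(efficiency_gain(120, 120), 0)
  # sign characterisation: positive iff the comparator needs fewer patients
  expect_gt(efficiency_gain(50, 80), 0)
  expect_lt(efficiency_gain(80, 50), 0)
  expect_error(efficiency_gain(-5, 100), "positive")
  expect_error(efficiency_gain(50, 0), "positive")
})

test_that("identical detection curves yield zero reductions", {
  s <- do.call(rbind, lapply(c("ordinal", "favorable", "mortality"),
    function(a) data.frame(scenario = "A", analysis = a,
                           n_per_hospital = rep(c(25, 50, 100), each = 4),
                           rep = rep(1:4, 3),
                           n_flagged = rep(c(2, 4, 8), each = 4),
                           n_estimable = 50, n_non_estimable = 0,
                           converged = TRUE, failed = FALSE)))
  class(s) <- c("detection_summary", "data.frame")
  eff <- summarize_efficiency(s)
  expect_true(all(abs(eff$comparisons$reduction) < 1e-12))
  expect_equal(unname(eff$max_reduction), c(0, 0))
})

test_that("a dominating ordinal curve yields nonnegative defined reductions", {
  mk <- function(a, p) data.frame(scenario = "A", analysis = a,
                                  n_per_hospital = c(25, 50, 100),
                                  rep = 1, n_flagged = round(50 * p),
                                  n_estimable = 50, n_non_estimable = 0,
                                  converged = TRUE, failed = FALSE)
  s <- rbind(mk("ordinal", c(0.10, 0.30, 0.60)),
             mk("favorable", c(0.06, 0.20, 0.44)),
             mk("mortality", c(0.02, 0.10, 0.30)))
  class(s) <- c("detection_summary", "data.frame")
  eff <- summarize_efficiency(s)
  def <- !is.na(eff$comparisons$reduction)
  expect_true(any(def))
  expect_true(all(eff$comparisons$reduction[def] >= 0))
  expect_gt(eff$max_reduction[["mortality"]],
            eff$max_reduction[["favorable"]])
})

test_that("power curves require matching scenario-A cells", {
  s <- data.frame(scenario = "B", analysis = "ordinal",
                  n_per_hospital = 25, rep = 1, n_flagged = 0,
                  n_estimable = 50, n_non_estimable = 0, converged = TRUE,
                  failed = FALSE)
  class(s) <- c("detection_summary", "data.frame")
  expect_error(power_curve(s, "ordinal"), "no scenario-A")
})
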