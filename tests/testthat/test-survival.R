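test_that("weibull_survival matches hand evaluation and the median identity", {
  pfs <- weibull_curve(scale = 0.04191, shape = 1.4165)
  expect_identical(weibull_survival(pfs, 0), 1)
  # exp(-0.04191 * 10^1.4165) evaluated by hand
  expect_equal(weibull_survival(pfs, 10), 0.335044, tolerance = 1e-4)
  expect_equal(weibull_survival(pfs, weibull_median(pfs)), 0.5)
  expect_error(weibull_survival(pfs, -1), "t")
})

test_that("weibull survival is monotone non-increasing for random curves", {
  set.seed(42)
  t <- seq(0, 200, by = 0.5)
  for (rep in 1:25) {
    s <- weibull_survival(random_curve(), t)
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))  # may underflow to 0 in the far tail
  }
})

test_that("cloglog fit recovers exact Weibull points to machine precision", {
  truth <- weibull_curve(scale = 0.02, shape = 1.2)
  t <- seq(4, 40, by = 4)
  pts <- data.frame(time_weeks = t, survival = weibull_survival(truth, t))
  fit <- fit_weibull(pts)
  expect_equal(fit$curve$scale, 0.02, tolerance = 1e-10)
  expect_equal(fit$curve$shape, 1.2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate survival points are dropped or fail the fit", {
  truth <- weibull_curve(scale = 0.02, shape = 1.2)
  t <- c(0.0001, 4, 8, 12)
  s <- weibull_survival(truth, t)
  s[1] <- 1  # saturated point, undefined on the cloglog scale
  expect_warning(fit <- fit_weibull(data.frame(time_weeks = t, survival = s)),
                 "dropping")
  expect_equal(fit$n_points, 3L)
  expect_error(fit_weibull(data.frame(time_weeks = 5, survival = 0.5)),
               "at least 2")
  expect_error(
    suppressWarnings(
      fit_weibull(data.frame(time_weeks = c(1, 2), survival = c(1, 0)))),
    "at least 2")
})

test_that("hazard-ratio adjustment is the power transform of survival", {
  i <- base_inputs()
  ref <- i$control_os
  expect_equal(adjust_survival(ref, 1), ref)
  # S_ref = 0.5 raised to HR 0.57
  t_med <- weibull_median(ref)
  adj <- adjust_survival(ref, 0.57)
  expect_equal(weibull_survival(adj, t_med), 0.5^0.57, tolerance = 1e-12)
  expect_error(adjust_survival(ref, 0), "hr")

  set.seed(7)
  t <- seq(0, 150, by = 1.5)
  for (rep in 1:20) {
    curve <- random_curve()
    hr <- runif(1, 0.2, 2)
    expect_equal(weibull_survival(adjust_survival(curve, hr), t),
                 weibull_survival(curve, t)^hr, tolerance = 1e-12)
  }
  # protective HR dominates the reference pointwise
  dom <- adjust_survival(ref, 0.6)
  expect_true(all(weibull_survival(dom, t) >= weibull_survival(ref, t)))
})

test_that("hr_estimate derives the log-HR SE from the 95% CI", {
  h <- hr_estimate(0.57, ci_low = 0.4, ci_high = 0.8)
  expect_equal(h$log_se, (log(0.8) - log(0.4)) / (2 * qnorm(0.975)))
  overridden <- hr_estimate(0.57, ci_low = 0.4, ci_high = 0.8, log_se = 0.3)
  expect_equal(overridden$log_se, 0.3)
  expect_error(hr_estimate(-1, log_se = 0.1), "hr")
})

test_that("fixed-effect pooling matches the inverse-variance closed form", {
  # single estimate is returned unchanged
  one <- hr_estimate(0.5, log_se = 0.2)
  pooled1 <- pool_hazard_ratios(list(one))
  expect_equal(pooled1$hr, 0.5, tolerance = 1e-10)
  expect_equal(pooled1$log_se, 0.2, tolerance = 1e-10)

  # equal SEs: pooled HR is the geometric mean
  pair <- list(hr_estimate(0.4, log_se = 0.25), hr_estimate(0.9, log_se = 0.25))
  expect_equal(pool_hazard_ratios(pair)$hr, sqrt(0.4 * 0.9), tolerance = 1e-10)

  # independent oracle: hand-computed inverse-variance weighted mean
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    ests <- lapply(seq_len(k), function(j)
      hr_estimate(exp(rnorm(1, -0.5, 0.4)), log_se = runif(1, 0.05, 0.4)))
    w <- vapply(ests, function(e) 1 / e$log_se^2, numeric(1))
    y <- vapply(ests, function(e) log(e$hr), numeric(1))
    pooled <- pool_hazard_ratios(ests)
    expect_equal(log(pooled$hr), sum(w * y) / sum(w), tolerance = 1e-8)
    expect_equal(pooled$log_se, sqrt(1 / sum(w)), tolerance = 1e-8)
    # pooled CI no wider than the narrowest input CI (on the log scale)
    widths <- vapply(ests, function(e) log(e$ci_high / e$ci_low), numeric(1))
    expect_lte(log(pooled$ci_high / pooled$ci_low), min(widths) + 1e-10)
  }

  expect_error(pool_hazard_ratios(list()), "empty")
})
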