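test_that("ICER computation applies the sign and dominance conventions", {
  i <- base_inputs()
  ctrl <- run_strategy(i, "control")
  pap <- run_strategy(i, "apatinib_pap")

  res <- compute_icer(ctrl, pap)
  expect_identical(res$tag, "icer")
  expect_equal(res$icer, res$delta_cost / res$delta_qalys)
  expect_gt(res$icer, 0)

  expect_identical(compute_icer(ctrl, ctrl)$tag, "equivalent")

  # cheaper and more effective: free drug, no supportive-care cost, and a
  # survival gain that defers the discounted end-of-life charge
  cheap <- neutralized_inputs(i)
  cheap$costs$supportive_care_per_cycle <- ranged(0)
  cheap$hr_os <- hr_estimate(0.57, log_se = 0)
  cheap$hr_pfs <- hr_estimate(0.34, log_se = 0)
  dom <- compute_icer(run_strategy(cheap, "control"),
                      run_strategy(cheap, "apatinib_pap"))
  expect_identical(dom$tag, "dominant")
  expect_true(is.na(dom$icer))

  other_cfg <- i
  other_cfg$config$horizon_years <- 5
  expect_error(compute_icer(ctrl, run_strategy(other_cfg, "apatinib_pap")),
               "config")
})

test_that("net monetary benefit is linear and consistent with the ICER", {
  i <- base_inputs()
  ctrl <- run_strategy(i, "control")
  pap <- run_strategy(i, "apatinib_pap")
  expect_equal(net_monetary_benefit(ctrl, 0), -ctrl$costs$total)
  expect_equal(net_monetary_benefit(ctrl, 40000) + ctrl$costs$total,
               2 * (net_monetary_benefit(ctrl, 20000) + ctrl$costs$total))

  icer <- compute_icer(ctrl, pap)$icer
  for (wtp in c(10000, 22200, 40000)) {
    inmb <- net_monetary_benefit(pap, wtp) - net_monetary_benefit(ctrl, wtp)
    expect_identical(inmb > 0, icer < wtp)
  }
})

test_that("tornado analysis covers every ranged parameter, sorted by span", {
  i <- base_inputs()
  tor <- suppressWarnings(one_way_sensitivity(i))
  expect_setequal(tor$parameter,
                  c("apatinib_unit_cost", "supportive_care_per_cycle",
                    "end_of_life_palliative", "coverage_fraction",
                    "u_pfs", "u_pd", "hr_pfs", "hr_os"))
  expect_true(all(is.finite(tor$icer_low) & is.finite(tor$icer_high)))
  expect_true(all(diff(tor$span) <= 0))
  expect_equal(tor$span, abs(tor$icer_high - tor$icer_low))

  # a degenerate range pins the ICER and gives span zero
  flat <- i
  flat$costs$end_of_life_palliative <- ranged(1483.9)
  tor2 <- suppressWarnings(one_way_sensitivity(flat))
  expect_equal(tor2$span[tor2$parameter == "end_of_life_palliative"], 0)
})

test_that("PSA draws are seed-reproducible and collapse to the base case", {
  i <- base_inputs()
  p1 <- run_psa(i, n = 40, seed = 123)
  p2 <- run_psa(i, n = 40, seed = 123)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$parameters, p2$parameters)
  expect_equal(nrow(p1$draws), 40L * 3L)
  expect_false(identical(run_psa(i, n = 40, seed = 124)$draws, p1$draws))

  base_pap <- run_strategy(i, "apatinib_pap")
  degen <- suppressMessages(run_psa(degenerate_inputs(i), n = 5, seed = 1))
  pap_draws <- degen$draws[degen$draws$strategy == "apatinib_pap", ]
  expect_true(all(abs(pap_draws$cost - base_pap$costs$total) < 1e-9))
  expect_true(all(abs(pap_draws$qalys - base_pap$qalys) < 1e-12))
})

test_that("sampled parameters match their distributions' moments", {
  i <- base_inputs()
  set.seed(2024)
  n <- 1000
  params <- draw_psa_parameters(i, n)

  check_mean <- function(x, mean, var) {
    expect_lt(abs(mean(x) - mean), 3 * sqrt(var / n))
  }
  tm <- triangle_moments(53.2, 106.5, 106.5)
  check_mean(params$apatinib_unit_cost, tm$mean, tm$var)
  tm <- triangle_moments(1072.3, 1483.9, 2119.3)
  check_mean(params$end_of_life_palliative, tm$mean, tm$var)
  tm <- triangle_moments(32.3, 117.1, 322.6)
  check_mean(params$supportive_care_per_cycle, tm$mean, tm$var)
  check_mean(params$u_pfs, 0.88, ((0.97 - 0.80) / 4)^2)
  check_mean(params$u_pd, 0.41, ((0.63 - 0.28) / 4)^2)
  check_mean(params$coverage_fraction, 0.60, ((0.75 - 0.45) / 4)^2)
  # lognormal HRs: median at the point estimate
  se <- i$hr_pfs$log_se
  check_mean(log(params$hr_pfs), log(0.34), se^2)
  expect_true(all(params$hr_pfs > 0))
})

test_that("acceptability curves behave as step and monotone curves", {
  i <- base_inputs()

  # degenerate PSA: the CEAC is a 0/1 step at the base-case ICER
  degen <- suppressMessages(run_psa(degenerate_inputs(i), n = 3, seed = 1))
  base_icer <- compute_icer(run_strategy(i, "control"),
                            run_strategy(i, "apatinib_pap"))$icer
  step <- ceac(degen, wtp_grid = c(floor(base_icer) - 5000,
                                   ceiling(base_icer) + 5000))
  pap_step <- step[step$strategy == "apatinib_pap", ]
  expect_equal(pap_step$p_ce, c(0, 1))

  # all QALY-gaining draws: probability is non-decreasing in WTP
  set.seed(31)
  fake <- structure(list(draws = data.frame(
    draw = rep(1:50, 2),
    strategy = rep(c("control", "apatinib_pap"), each = 50),
    cost = c(rep(2500, 50), 2500 + rnorm(50, 4400, 2000)),
    qalys = c(rep(0.27, 50), 0.27 + runif(50, 0.05, 0.3))
  ), n = 50, seed = 1), class = "psa_result")
  curve <- ceac(fake, wtp_grid = seq(0, 60000, by = 1000))
  expect_true(all(diff(curve$p_ce) >= 0))

  expect_error(ceac(degen, wtp_grid = numeric(0)), "empty")
  expect_error(ceac(degen, wtp_grid = c(2, 1)), "increasing")
})
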