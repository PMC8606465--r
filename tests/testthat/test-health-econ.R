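test_that("discount factors follow the compound formula", {
  expect_equal(discount_factor(0.04, 0), 1)
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  expect_equal(discount_factor(0.015, 5), 1.015^-5)
  expect_equal(discount_factor(0, 3), 1)
})

test_that("cost_for_cycle anchors by year category and zeroes the dead", {
  econ <- simple_econ()
  expect_equal(cost_for_cycle("DEAD", 1, econ), 0)
  expect_equal(cost_for_cycle("DEAD", 5, econ), 0)
  # no inflation, unit price factor: years 3..5 equal the year-3+ anchor
  for (t in 3:5) {
    expect_equal(cost_for_cycle("MRS3", t, econ),
                 unname(econ$cost_year3plus["MRS3"]))
  }
  expect_equal(cost_for_cycle("MRS3", 1, econ), unname(econ$cost_year1["MRS3"]))
  expect_equal(cost_for_cycle("MRS3", 2, econ), unname(econ$cost_year2["MRS3"]))
  expect_error(cost_for_cycle("MRS3", 6, econ), "1..5")

  # with zero rehabilitation share, year 3 differs from year 2 by one
  # inflation factor only
  econ_nr <- economic_inputs(
    utility = c(0.9, 0.7, 0.5, 0.3, -0.1),
    cost_year1 = rep(1000, 5), cost_year2 = rep(800, 5),
    cost_year3plus = rep(800, 5), inflation = 0.017
  )
  expect_equal(cost_for_cycle("MRS2", 3, econ_nr) / cost_for_cycle("MRS2", 2, econ_nr),
               1.017, tolerance = 1e-12)

  # price-year adjustment and inflation multiply in
  econ_i <- simple_econ(inflation = 0.02, price_year_factor = 1.1)
  expect_equal(cost_for_cycle("MRS2", 1, econ_i),
               unname(econ_i$cost_year1["MRS2"]) * 1.1 * 1.02, tolerance = 1e-12)
})

test_that("accrual reproduces closed forms", {
  # whole cohort dead at cycle 0: nothing accrues
  psd <- toy_params()
  trd <- run_cohort(mrs_distribution(c(0, 0, 0, 0, 0, 1)), psd)
  acc <- accrue(trd, psd$econ)
  expect_equal(acc$qalys, 0)
  expect_equal(acc$costs, 0)

  # zero risk, one state, no discounting: QALYs = 5u
  ps1 <- toy_params(econ = simple_econ())
  tr1 <- run_cohort(mrs_distribution(c(0, 1, 0, 0, 0, 0)), ps1)
  acc1 <- accrue(tr1, ps1$econ)
  expect_equal(acc1$qalys, 5 * unname(ps1$econ$utility["MRS2"]), tolerance = 1e-12)
  expect_equal(acc1$costs,
               unname(ps1$econ$cost_year1["MRS2"] + ps1$econ$cost_year2["MRS2"] +
                        3 * ps1$econ$cost_year3plus["MRS2"]), tolerance = 1e-9)

  # constant occupancy with discounting: geometric series
  econ_d <- simple_econ(discount_qaly = 0.015, discount_cost = 0.04)
  ps2 <- toy_params(econ = econ_d)
  tr2 <- run_cohort(mrs_distribution(c(1, 0, 0, 0, 0, 0)), ps2)
  u <- unname(econ_d$utility["MRS0_1"])
  expect_equal(accrue(tr2, econ_d)$qalys, u * sum(1.015^-(1:5)), tolerance = 1e-9)
  c1 <- unname(econ_d$cost_year1["MRS0_1"]); c2 <- unname(econ_d$cost_year2["MRS0_1"])
  c3 <- unname(econ_d$cost_year3plus["MRS0_1"])
  expect_equal(accrue(tr2, econ_d)$costs,
               c1 / 1.04 + c2 / 1.04^2 + c3 * sum(1.04^-(3:5)), tolerance = 1e-9)

  # the optional cycle-0 accrual adds one undiscounted year at year-1 prices
  acc0 <- accrue(tr2, econ_d, include_cycle0 = TRUE)
  expect_equal(acc0$qalys - accrue(tr2, econ_d)$qalys, u, tolerance = 1e-12)
  expect_equal(acc0$costs - accrue(tr2, econ_d)$costs, c1, tolerance = 1e-9)
})

test_that("net monetary value is the defining identity", {
  expect_equal(nmv(1, 0, 80000), 80000)
  expect_equal(nmv(0, 100, 80000), -100)
  expect_equal(nmv(0.5, 10000, 80000), 30000)
  expect_error(nmv(1, 0, -5))
})

test_that("NMV identity holds for every simulated stratum", {
  ps <- gen_parameter_set(synthetic_config(seed = 23))
  strata <- simulate_strata(ps)
  expect_equal(nrow(strata), 6L)
  expect_true(all(abs(strata$nmv - (strata$qalys * ps$econ$wtp - strata$costs)) < 1e-6))
})

test_that("adjacent-pair differences and NMB are oriented faster-minus-slower", {
  strata <- data.frame(hour = 1:6, qalys = seq(3, 2, length.out = 6),
                       costs = rep(1000, 6))
  strata$nmv <- strata$qalys * 80000 - strata$costs
  pairs <- nmb_between_strata(strata, 80000)
  expect_equal(nrow(pairs), 5L)
  expect_true(all(pairs$d_qalys > 0))
  expect_equal(pairs$d_costs, rep(0, 5))
  expect_equal(pairs$nmb, pairs$d_qalys * 80000 - pairs$d_costs, tolerance = 1e-9)
  # identical strata give all-zero differences
  same <- data.frame(hour = 1:6, qalys = 2, costs = 500, nmv = 2 * 80000 - 500)
  expect_equal(unlist(nmb_between_strata(same, 80000)[, -1]),
               setNames(rep(0, 15), NULL), ignore_attr = TRUE)
  # NMB is invariant to a constant shift of both strata's NMV
  shifted <- strata; shifted$nmv <- shifted$nmv + 12345
  expect_equal(nmb_between_strata(shifted, 80000)$nmb, pairs$nmb)
})

test_that("per_hour_median takes the middle of exactly five differences", {
  expect_equal(per_hour_median(c(1, 2, 3, 4, 5)), 3)
  expect_equal(per_hour_median(c(23799, 14052, 30143, 13125, 10560)), 14052)
  expect_equal(per_hour_median(rep(7, 5)), 7)
  expect_error(per_hour_median(1:4), "five")
  expect_error(per_hour_median(1:6), "five")
})

test_that("time-unit conversion is linear with euro rounding half away from zero", {
  expect_equal(convert_time_unit(0, 1), 0)
  expect_equal(convert_time_unit(600, 10), 100)
  expect_equal(convert_time_unit(90, 1, round_euro = TRUE), 2)   # 1.5 -> 2
  expect_equal(convert_time_unit(-90, 1, round_euro = TRUE), -2) # -1.5 -> -2
  expect_error(convert_time_unit(60, 30), "1 or 10")
  # linearity before rounding
  a <- 123.4; b <- 567.8
  expect_equal(convert_time_unit(a + b, 10), convert_time_unit(a, 10) + convert_time_unit(b, 10))
})

test_that("QALY-to-disability-free-day conversion uses 365 days per QALY", {
  expect_equal(qalys_to_disability_free_days(0, 1), 0)
  expect_equal(qalys_to_disability_free_days(0.6, 1, round_days = FALSE),
               0.6 * 365 / 60, tolerance = 1e-12)
  expect_equal(qalys_to_disability_free_days(0.6, 10, round_days = FALSE),
               0.6 * 365 / 6, tolerance = 1e-12)
})

test_that("outcome_summary is internally consistent", {
  ps <- gen_parameter_set(synthetic_config(seed = 19))
  s <- outcome_summary(ps)
  expect_equal(s$per_hour[["nmb"]], per_hour_median(s$per_pair$nmb))
  expect_equal(s$per_minute[["nmb"]],
               convert_time_unit(s$per_hour[["nmb"]], 1, round_euro = TRUE))
  expect_equal(s$per_10min[["d_qalys"]], s$per_hour[["d_qalys"]] / 6, tolerance = 1e-12)
  expect_equal(s$disability_free_days[["per_minute"]],
               round(s$per_hour[["d_qalys"]] * 365 / 60, 1))
  path <- tempfile(fileext = ".csv")
  write_outcomes_csv(s, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6 + 5)
  unlink(path)
})
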