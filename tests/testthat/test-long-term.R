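test_that("annual_death_prob applies the hazard ratio on the cumulative-hazard scale", {
  # hr = 1 returns the mixed background probability exactly
  lt <- life_table(18:110, rep(0.2, 93), rep(0.1, 93))
  hz1 <- hazard_ratios(matrix(1, 5, 5))
  expect_equal(annual_death_prob(69, 0.5, "MRS2", 1, lt, hz1),
               0.5 * 0.2 + 0.5 * 0.1, tolerance = 1e-15)
  # sex mixing respects the fraction male
  expect_equal(annual_death_prob(69, 1, "MRS2", 1, lt, hz1), 0.2)
  expect_equal(annual_death_prob(69, 0, "MRS2", 1, lt, hz1), 0.1)

  # zero background mortality stays zero under any hazard ratio
  lt0 <- flat_life_table(0)
  hz9 <- hazard_ratios(matrix(9, 5, 5))
  expect_equal(annual_death_prob(69, 0.5, "MRS5", 3, lt0, hz9), 0)

  # q = 0.1, hr = 2: p = 1 - 0.9^2 = 0.19
  lt01 <- flat_life_table(0.1)
  hz2 <- hazard_ratios(matrix(2, 5, 5))
  expect_equal(annual_death_prob(69, 0.5, "MRS3", 2, lt01, hz2), 0.19,
               tolerance = 1e-12)

  # certain background death stays certain; invalid ratios raise
  lt1 <- life_table(18:110, rep(1, 93), rep(1, 93))
  expect_equal(annual_death_prob(69, 0.5, "MRS2", 1, lt1, hz2), 1)
  hz_bad <- hazard_ratios(matrix(2, 5, 5)); hz_bad[1, 1] <- NA
  expect_error(annual_death_prob(69, 0.5, "MRS0_1", 1, lt01, hz_bad), "positive")
  expect_error(annual_death_prob(69, 0.5, "DEAD", 1, lt01, hz2), "alive")
  expect_error(annual_death_prob(200, 0.5, "MRS2", 1, lt01, hz2), "range")
})

test_that("recurrence redistribution truncates and renormalizes", {
  base <- c(0.3, 0.2, 0.2, 0.2, 0.1)
  # worst state keeps all mass; best state leaves the distribution unchanged
  r5 <- recurrence_redistribution("MRS5", base)
  expect_equal(unname(r5), c(0, 0, 0, 0, 1))
  r1 <- recurrence_redistribution("MRS0_1", base)
  expect_equal(unname(r1), base)
  # hand-computed truncation at MRS3
  r3 <- recurrence_redistribution("MRS3", base)
  expect_equal(unname(r3), c(0, 0, 0.4, 0.4, 0.2))
  # no available outcome is an explicit error
  expect_error(recurrence_redistribution("MRS5", c(0.5, 0.3, 0.1, 0.1, 0)),
               "no post-recurrence outcome")
})

test_that("redistribution matches the brute-force oracle on random distributions", {
  set.seed(2024)
  for (rep in 1:100) {
    base <- rgamma(5, 1); base <- base / sum(base)
    for (i in 1:5) {
      got <- recurrence_redistribution(alive_states()[i], base)
      expect_equal(unname(got), brute_redistribution(i, base), tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-12)
      if (i > 1) expect_true(all(got[1:(i - 1)] == 0))
    }
  }
})

test_that("the transition matrix has the structure the model promises", {
  # no mortality, no recurrence: identity
  m0 <- build_transition_matrix(1, toy_params(q = 0, hr = 1, p_rec = 0))
  expect_equal(unname(m0), diag(6), tolerance = 1e-15)

  # no recurrence: only diagonal and the DEAD column populated
  m1 <- build_transition_matrix(1, toy_params(q = 0.05, hr = 2, p_rec = 0))
  off <- m1[alive_states(), alive_states()]
  expect_equal(sum(off) - sum(diag(off)), 0)
  expect_true(all(m1[alive_states(), "DEAD"] > 0))

  # realistic parameters: rows stochastic, no spontaneous improvement
  ps <- gen_parameter_set(synthetic_config(seed = 6))
  for (t in 1:5) {
    m <- build_transition_matrix(t, ps)
    expect_true(all(abs(rowSums(m) - 1) < 1e-12))
    expect_true(all(m >= 0))
    for (i in 1:5) for (j in seq_len(i - 1)) {
      expect_identical(m[alive_states()[i], alive_states()[j]], 0)
    }
    expect_equal(unname(m["DEAD", ]), c(0, 0, 0, 0, 0, 1))
  }
})

test_that("cohort traces conserve mass and absorb into death monotonically", {
  ps <- gen_parameter_set(synthetic_config(seed = 8))
  tr <- run_cohort(ps$short_term$hour2, ps)
  expect_equal(dim(tr), c(6L, 6L))
  expect_true(all(abs(rowSums(tr) - 1) < 1e-10))
  expect_true(all(diff(tr[, "DEAD"]) >= 0))
  # cycle 0 is exactly the short-term outcome
  expect_equal(unname(tr[1, ]), unname(unclass(ps$short_term$hour2)))
})

test_that("degenerate cohorts behave as closed forms predict", {
  # zero risk: occupancy constant across all cycles
  ps0 <- toy_params(q = 0, hr = 1, p_rec = 0)
  tr0 <- run_cohort(ps0$short_term$hour1, ps0)
  for (t in 1:5) expect_equal(unname(tr0[t + 1, ]), unname(tr0[1, ]))

  # all mass dead stays dead
  dead_start <- mrs_distribution(c(0, 0, 0, 0, 0, 1))
  ps <- gen_parameter_set(synthetic_config(seed = 2))
  trd <- run_cohort(dead_start, ps)
  expect_true(all(trd[, "DEAD"] == 1))

  # pure recurrence with a point-mass base distribution funnels into MRS5
  psr <- toy_params(q = 0, hr = 1, p_rec = 1, base_dist = c(0, 0, 0, 0, 1))
  trr <- run_cohort(mrs_distribution(c(1, 0, 0, 0, 0, 0)), psr)
  expect_equal(unname(trr[2, "MRS5"]), 1)
})

test_that("worse starting distributions never yield more survivors", {
  ps <- gen_parameter_set(synthetic_config(seed = 14))
  better <- mrs_distribution(c(0.5, 0.2, 0.15, 0.1, 0.05, 0))
  worse <- mrs_distribution(c(0.05, 0.1, 0.15, 0.2, 0.5, 0))
  trb <- run_cohort(better, ps)
  trw <- run_cohort(worse, ps)
  expect_true(all(1 - trw[, "DEAD"] <= 1 - trb[, "DEAD"] + 1e-12))
})

test_that("matrix propagation agrees with the microsimulation oracle", {
  ps <- gen_parameter_set(synthetic_config(seed = 16))
  start <- ps$short_term$hour4
  n <- 20000
  tr <- run_cohort(start, ps)
  ms <- microsimulate_cohort(start, ps, n = n, seed = 99)
  se <- sqrt(pmax(tr * (1 - tr), 1e-12) / n)
  expect_true(all(abs(ms - tr) <= 3 * se + 1e-9))
})

test_that("trace CSV export has one row per stratum-cycle", {
  ps <- gen_parameter_set(synthetic_config(seed = 3))
  traces <- lapply(ps$short_term[1:2], function(d) run_cohort(d, ps))
  path <- tempfile(fileext = ".csv")
  write_traces_csv(traces, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 2 * 6)
  expect_equal(names(df), c("stratum", "cycle", mrs_states()))
  unlink(path)
})
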