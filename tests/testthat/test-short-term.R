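make_record <- function(minutes = 120, mrs90 = 2, loc = "M1", age = 70,
                        center = TRUE) {
  data.frame(onset_to_groin_minutes = minutes, mrs90 = mrs90,
             occlusion_location = loc, age = age,
             treated_in_trial_center = center, stringsAsFactors = FALSE)
}

test_that("filter_registry applies the six criteria with an inclusive 360-min bound", {
  res <- filter_registry(make_record(minutes = 400))
  expect_equal(nrow(res$included), 0L)
  expect_equal(unname(res$exclusions["time_le_360"]), 1L)

  res <- filter_registry(make_record(minutes = 360))
  expect_equal(nrow(res$included), 1L)
  expect_true(all(res$exclusions == 0))
})

test_that("exclusions attribute each record to its first failing criterion", {
  recs <- rbind(
    make_record(),                               # clean
    make_record(loc = "basilar"),                # fails criterion 1
    make_record(age = 16),                       # fails criterion 3
    make_record(mrs90 = NA),                     # fails criterion 4
    make_record(loc = "other", minutes = 999)    # fails 1 first, not the time rule
  )
  res <- filter_registry(recs)
  expect_equal(nrow(res$included), 1L)
  expect_equal(unname(res$exclusions["anterior_lvo"]), 2L)
  expect_equal(unname(res$exclusions["age_ge_18"]), 1L)
  expect_equal(unname(res$exclusions["mrs90_available"]), 1L)
  expect_equal(unname(res$exclusions["time_le_360"]), 0L)
  expect_equal(sum(res$exclusions), nrow(recs) - nrow(res$included))
})

test_that("filter_registry is idempotent", {
  reg <- gen_registry(synthetic_config(n_per_hour = 50, seed = 12))
  reg$age[1:5] <- 15
  once <- filter_registry(reg)
  twice <- filter_registry(once$included)
  expect_identical(twice$included, once$included)
  expect_true(all(twice$exclusions == 0))
})

test_that("estimate_mrs_by_hour returns empirical frequencies with merged mRS 0-1", {
  # degenerate stratum: everyone at mRS 0 or 1
  recs <- do.call(rbind, lapply(1:6, function(h) {
    rbind(
      make_record(minutes = 60 * h - 30, mrs90 = 0),
      make_record(minutes = 60 * h - 20, mrs90 = 1)
    )
  }))
  est <- estimate_mrs_by_hour(recs)
  expect_equal(unname(unclass(est$hour1$dist)), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(est$hour4$counts), c(2L, 0L, 0L, 0L, 0L, 0L))

  # known frequencies in one stratum
  recs2 <- do.call(rbind, c(
    lapply(c(0, 1, 2, 2, 3, 3, 4, 4, 5, 6), function(m) make_record(minutes = 30, mrs90 = m)),
    lapply(1:5, function(h) make_record(minutes = 60 * h + 30, mrs90 = 3))
  ))
  est2 <- estimate_mrs_by_hour(recs2)
  expect_equal(unname(unclass(est2$hour1$dist)), c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1))

  # an empty stratum is an explicit error naming the hour
  only5 <- make_record(minutes = 30)
  expect_error(estimate_mrs_by_hour(only5), "hour 2")
})

test_that("hour binning is left-open right-closed", {
  # 60 min belongs to hour 1; 60.5 to hour 2; 360 to hour 6
  recs <- rbind(make_record(minutes = 60, mrs90 = 0),
                make_record(minutes = 60.5, mrs90 = 5))
  recs <- rbind(recs, do.call(rbind, lapply(3:6, function(h)
    make_record(minutes = 60 * h - 1, mrs90 = 3))))
  est <- estimate_mrs_by_hour(recs)
  expect_equal(unname(est$hour1$counts["MRS0_1"]), 1L)
  expect_equal(unname(est$hour2$counts["MRS5"]), 1L)
})

test_that("estimated per-hour probabilities recover the generator truth", {
  cfg <- synthetic_config(n_per_hour = 500, ordinal_slope = 0.25, seed = 77)
  reg <- gen_registry(cfg)
  est <- estimate_mrs_by_hour(filter_registry(reg)$included)
  n <- cfg$n_per_hour
  inside <- 0L; total <- 0L
  for (h in 1:6) {
    truth <- evtvalue:::prop_odds_probs(h, cfg$ordinal_slope)
    phat <- unclass(est[[paste0("hour", h)]]$dist)
    for (s in 1:6) {
      ci <- binom.test(round(phat[s] * n), n)$conf.int
      total <- total + 1L
      if (truth[s] >= ci[1] && truth[s] <= ci[2]) inside <- inside + 1L
    }
  }
  expect_gte(inside / total, 0.9)
})

test_that("independent ordinal-regression fit recovers the generator slope", {
  skip_if_not_installed("MASS")
  cfg <- synthetic_config(n_per_hour = 2000, ordinal_slope = 0.25, seed = 31)
  reg <- gen_registry(cfg)
  hour <- ceiling(reg$onset_to_groin_minutes / 60)
  merged <- factor(ifelse(reg$mrs90 <= 1, 1, reg$mrs90), levels = 1:6)
  fit <- MASS::polr(merged ~ hour, Hess = TRUE)
  est <- unname(coef(fit)["hour"])
  se <- sqrt(diag(vcov(fit)))[["hour"]]
  expect_lt(abs(est - cfg$ordinal_slope), 3 * se)
})

test_that("Dirichlet draws concentrate, average to counts/total, and are seeded", {
  counts <- list(hour1 = c(1e6, 1, 1, 1, 1, 1))
  d <- sample_short_term(counts, seed = 5)$hour1
  expect_gt(d[["MRS0_1"]], 0.99)
  expect_equal(sum(d), 1, tolerance = 1e-12)

  counts2 <- list(hour1 = c(20, 10, 30, 15, 15, 10))
  draws <- replicate(10000, unclass(sample_short_term(counts2)$hour1))
  m <- rowMeans(draws)
  alpha <- counts2$hour1; a0 <- sum(alpha)
  expected <- alpha / a0
  se <- sqrt(expected * (1 - expected) / (a0 + 1)) / sqrt(10000)
  expect_true(all(abs(m - expected) < 3 * se + 1e-9))

  expect_identical(sample_short_term(counts2, seed = 9),
                   sample_short_term(counts2, seed = 9))
  expect_error(sample_short_term(list(hour1 = rep(0, 6))), "all-zero")
})

test_that("zero-count cells are structural zeros in every draw", {
  counts <- list(hour1 = c(50, 0, 30, 0, 15, 5))
  for (i in 1:20) {
    d <- sample_short_term(counts, seed = i)$hour1
    expect_identical(unname(d[c(2, 4)]), c(0, 0))
  }
})

test_that("Dirichlet means converge to empirical frequencies at huge counts", {
  base <- c(2, 2, 2, 2, 1, 1)
  counts <- list(hour1 = base * 1e6)
  d <- sample_short_term(counts, seed = 13)$hour1
  expect_true(all(abs(unclass(d) - base / sum(base)) < 1e-3))
})
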