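# Health-economic accrual: discounted QALYs, discounted inflation-adjusted
# costs, Net Monetary Value per delay stratum, Net Monetary Benefit between
# adjacent strata, and the per-hour -> per-10-minute -> per-minute and
# QALY -> disability-free-day conversions.

#' Discount factor
#'
#' @param rate Annual discount rate (>= 0).
#' @param t Year (>= 0).
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' Nominal annual cost of a state in a given model year
#'
#' Year 1 uses the year-1 cost anchor (90-day mRS reference point), year 2 the
#' year-2 anchor (18-month reference point), and years 3+ the year-2 costs
#' excluding rehabilitation. The historical price adjustment and `t` years of
#' inflation are applied; discounting is separate (see [accrue()]). `DEAD`
#' accrues zero cost.
#'
#' @param state State label.
#' @param t Model year 1..5.
#' @param econ An [economic_inputs()].
#' @return Nominal (pre-discount) cost in euros.
#' @export
cost_for_cycle <- function(state, t, econ) {
  if (!t %in% 1:5) stop("`t` must be in 1..5", call. = FALSE)
  if (state == "DEAD") return(0)
  base <- if (t == 1) econ$cost_year1[state]
          else if (t == 2) econ$cost_year2[state]
          else econ$cost_year3plus[state]
  unname(base) * econ$price_year_factor * (1 + econ$inflation)^t
}

#' Accrue discounted QALYs and costs over a cohort trace
#'
#' Sums over model years 1..horizon:
#' `QALYs = sum_t sum_s occ(t, s) * utility(s) * (1 + r_q)^(-t)` and
#' `costs = sum_t sum_s occ(t, s) * cost_for_cycle(s, t) * (1 + r_c)^(-t)`.
#' Cycle 0 (the first 90 days) carries no long-term accrual by default; acute
#' treatment costs enter through the year-1 cost anchor. With
#' `include_cycle0 = TRUE` the cycle-0 occupancy additionally accrues one
#' undiscounted year at year-1 prices.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param econ An [economic_inputs()].
#' @param include_cycle0 Accrue cycle 0 as an extra undiscounted year?
#'   Default `FALSE`.
#' @return Named list `qalys`, `costs` (both scalars).
#' @export
accrue <- function(trace, econ, include_cycle0 = FALSE) {
  horizon <- nrow(trace) - 1L
  sts <- mrs_states()
  util <- c(econ$utility, DEAD = 0)[sts]
  qalys <- 0
  costs <- 0
  for (t in seq_len(horizon)) {
    occ <- trace[t + 1L, ]
    cost_t <- vapply(sts, cost_for_cycle, numeric(1), t = t, econ = econ)
    qalys <- qalys + sum(occ * util) * discount_factor(econ$discount_qaly, t)
    costs <- costs + sum(occ * cost_t) * discount_factor(econ$discount_cost, t)
  }
  if (include_cycle0) {
    occ0 <- trace[1L, ]
    cost_1 <- vapply(sts, cost_for_cycle, numeric(1), t = 1, econ = econ)
    qalys <- qalys + sum(occ0 * util)
    costs <- costs + sum(occ0 * cost_1)
  }
  list(qalys = qalys, costs = costs)
}

#' Net Monetary Value
#'
#' @param qalys Discounted QALYs.
#' @param costs Discounted costs in euros.
#' @param wtp Willingness to pay in euros per QALY.
#' @return `qalys * wtp - costs`, euros.
#' @export
nmv <- function(qalys, costs, wtp) {
  stopifnot(wtp > 0)
  qalys * wtp - costs
}

#' Simulate every delay stratum through the full model
#'
#' Runs the five-year cohort model from each hour's 90-day distribution and
#' accrues discounted QALYs, costs and NMV.
#'
#' @param params A [parameter_set()].
#' @param include_cycle0 Passed to [accrue()].
#' @param age_offset Passed to [run_cohort()].
#' @return data.frame with one row per delay hour: `hour`, `qalys`, `costs`,
#'   `nmv`.
#' @export
simulate_strata <- function(params, include_cycle0 = FALSE, age_offset = 0) {
  rows <- lapply(HOUR_STRATA, function(h) {
    tr <- run_cohort(params$short_term[[paste0("hour", h)]], params,
                     age_offset = age_offset)
    acc <- accrue(tr, params$econ, include_cycle0 = include_cycle0)
    data.frame(hour = h, qalys = acc$qalys, costs = acc$costs,
               nmv = nmv(acc$qalys, acc$costs, params$econ$wtp))
  })
  do.call(rbind, rows)
}

#' Differences between adjacent delay strata
#'
#' For each adjacent hour pair `(h, h+1)` computes
#' `delta = value(h) - value(h+1)` for QALYs and costs, and the Net Monetary
#' Benefit `NMB = NMV(h) - NMV(h+1) = dQALY * wtp - dcost`.
#'
#' @param strata data.frame from [simulate_strata()].
#' @param wtp Willingness to pay, euros per QALY.
#' @return data.frame with one row per pair: `pair`, `d_qalys`, `d_costs`,
#'   `nmb`.
#' @export
nmb_between_strata <- function(strata, wtp) {
  strata <- strata[order(strata$hour), ]
  n <- nrow(strata)
  i <- seq_len(n - 1L)
  data.frame(
    pair = paste0("hour", strata$hour[i], "_vs_hour", strata$hour[i + 1L]),
    d_qalys = strata$qalys[i] - strata$qalys[i + 1L],
    d_costs = strata$costs[i] - strata$costs[i + 1L],
    nmb = strata$nmv[i] - strata$nmv[i + 1L]
  )
}

#' Median of the five adjacent-hour differences
#'
#' The per-hour effect of faster treatment is summarized, per simulation, as
#' the median of the five differences between the six delay hours.
#'
#' @param differences Numeric vector of exactly five values.
#' @return Their median (the middle order statistic).
#' @export
per_hour_median <- function(differences) {
  if (length(differences) != 5L) {
    stop("exactly five adjacent-hour differences are required", call. = FALSE)
  }
  stats::median(differences)
}

#' Convert a per-hour effect to a per-minute or per-10-minute effect
#'
#' Assumes constant differences between hours (linearity in delay):
#' `per_hour * minutes / 60`. Euro amounts should additionally be rounded to
#' the nearest integer euro, half away from zero, via `round_euro = TRUE`.
#'
#' @param per_hour_value Effect per hour of faster treatment.
#' @param minutes 1 or 10.
#' @param round_euro Round the result to whole euros (half away from zero)?
#' @return Converted value.
#' @export
#' @examples
#' convert_time_unit(18513, minutes = 1, round_euro = TRUE)  # 309
convert_time_unit <- function(per_hour_value, minutes = 1, round_euro = FALSE) {
  if (!minutes %in% c(1, 10)) stop("`minutes` must be 1 or 10", call. = FALSE)
  out <- per_hour_value * minutes / 60
  if (round_euro) out <- round_half_away(out)
  out
}

#' Convert a per-hour QALY effect to disability-free days per minute
#'
#' One QALY equals 365 disability-free days, so a per-hour QALY gain converts
#' to days per `minutes` of faster treatment as
#' `qalys * 365 * minutes / 60`, reported at one decimal.
#'
#' @param per_hour_qalys QALYs gained per hour of faster treatment.
#' @param minutes 1 or 10.
#' @param round_days Round to one decimal (the reporting convention)?
#' @return Disability-free days gained per `minutes` of faster treatment.
#' @export
#' @examples
#' qalys_to_disability_free_days(0.224)  # 1.4
qalys_to_disability_free_days <- function(per_hour_qalys, minutes = 1,
                                          round_days = TRUE) {
  out <- per_hour_qalys * 365 * minutes / 60
  if (round_days) round(out, 1) else out
}

#' Full baseline outcome summary
#'
#' Per-stratum discounted QALYs, costs and NMV; adjacent-pair differences and
#' NMB; the per-hour medians of the five differences; and their per-10-minute
#' and per-minute conversions (euros rounded to whole euros, QALY gains also
#' expressed as disability-free days).
#'
#' @param params A [parameter_set()].
#' @param include_cycle0 Passed to [accrue()].
#' @return List of class `outcome_summary`: `per_stratum`, `per_pair`,
#'   `per_hour` (named vector: d_costs, d_qalys, nmb), `per_10min`,
#'   `per_minute`, `disability_free_days` (per-minute and per-10-min),
#'   `wtp`.
#' @export
outcome_summary <- function(params, include_cycle0 = FALSE) {
  strata <- simulate_strata(params, include_cycle0 = include_cycle0)
  pairs <- nmb_between_strata(strata, params$econ$wtp)
  per_hour <- c(d_costs = per_hour_median(pairs$d_costs),
                d_qalys = per_hour_median(pairs$d_qalys),
                nmb = per_hour_median(pairs$nmb))
  conv <- function(minutes) {
    c(d_costs = convert_time_unit(per_hour[["d_costs"]], minutes, round_euro = TRUE),
      d_qalys = convert_time_unit(per_hour[["d_qalys"]], minutes),
      nmb = convert_time_unit(per_hour[["nmb"]], minutes, round_euro = TRUE))
  }
  structure(
    list(per_stratum = strata, per_pair = pairs, per_hour = per_hour,
         per_10min = conv(10), per_minute = conv(1),
         disability_free_days = c(
           per_minute = qalys_to_disability_free_days(per_hour[["d_qalys"]], 1),
           per_10min = qalys_to_disability_free_days(per_hour[["d_qalys"]], 10)
         ),
         wtp = params$econ$wtp),
    class = "outcome_summary"
  )
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary> (WTP", format(x$wtp, big.mark = ","), "EUR/QALY)\n")
  cat("Per delay stratum (discounted, 5-year):\n")
  print(transform(x$per_stratum,
                  qalys = round(qalys, 3), costs = round(costs),
                  nmv = round(nmv)), row.names = FALSE)
  cat("\nPer hour of faster treatment (median of five adjacent differences):\n")
  cat(sprintf("  dQALY %.3f | dcost %s EUR | NMB %s EUR\n",
              x$per_hour[["d_qalys"]],
              format(round(x$per_hour[["d_costs"]]), big.mark = ","),
              format(round(x$per_hour[["nmb"]]), big.mark = ",")))
  cat(sprintf("Per minute: NMB %s EUR, dcost %s EUR, %.1f disability-free days\n",
              format(x$per_minute[["nmb"]], big.mark = ","),
              format(x$per_minute[["d_costs"]], big.mark = ","),
              x$disability_free_days[["per_minute"]]))
  invisible(x)
}

#' Export an outcome summary to CSV
#'
#' One row per stratum and one per adjacent pair; columns unit-labeled.
#'
#' @param summary An [outcome_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(summary, path) {
  strat <- data.frame(row_type = "stratum", label = paste0("hour", summary$per_stratum$hour),
                      qalys_QALY = summary$per_stratum$qalys,
                      costs_EUR = summary$per_stratum$costs,
                      nmv_EUR = summary$per_stratum$nmv)
  pair <- data.frame(row_type = "pair", label = summary$per_pair$pair,
                     qalys_QALY = summary$per_pair$d_qalys,
                     costs_EUR = summary$per_pair$d_costs,
                     nmv_EUR = summary$per_pair$nmb)
  utils::write.csv(rbind(strat, pair), path, row.names = FALSE)
  invisible(path)
}
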