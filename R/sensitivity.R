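# Sensitivity analyses: one-way (+-10%, age +-4 years) tornado tables and the
# second-order Monte Carlo probabilistic sensitivity analysis with
# conventional cost-effectiveness sampling distributions
# (Dirichlet / normal / gamma / lognormal / beta).

# outcome used by the OWSA: baseline per-hour NMB (median of the five
# adjacent-hour differences)
baseline_nmb_per_hour <- function(params, age_offset = 0) {
  strata <- simulate_strata(params, age_offset = age_offset)
  pairs <- nmb_between_strata(strata, params$econ$wtp)
  per_hour_median(pairs$nmb)
}

# apply a multiplicative tweak to one named scalar/grouped parameter;
# returns the modified parameter set, or NULL with a reason when the tweak
# breaks validity
tweak_param <- function(params, spec, factor) {
  p <- params
  kind <- spec$kind
  if (kind == "utility") {
    p$econ$utility[spec$state] <- p$econ$utility[spec$state] * factor
  } else if (kind == "cost") {
    slot <- spec$slot
    p$econ[[slot]][spec$state] <- p$econ[[slot]][spec$state] * factor
    # keep the years-3+ <= year-2 invariant coherent when year 2 drops
    if (slot == "cost_year2") {
      p$econ$cost_year3plus[spec$state] <-
        min(p$econ$cost_year3plus[spec$state], p$econ[[slot]][spec$state])
    }
    if (slot == "cost_year3plus" &&
        p$econ$cost_year3plus[spec$state] > p$econ$cost_year2[spec$state]) {
      return(NULL)
    }
  } else if (kind == "hazard") {
    p$hazards[spec$state, ] <- p$hazards[spec$state, ] * factor
    if (length(validate_parameter_set(p))) return(NULL)
  } else if (kind == "recurrence") {
    pr <- pmin(1, pmax(0, p$recurrence$p_rec * factor))
    p$recurrence$p_rec <- pr
  } else {
    stop("unknown parameter kind: ", kind, call. = FALSE)
  }
  p
}

#' One-way sensitivity analysis
#'
#' Re-evaluates the per-hour Net Monetary Benefit after moving one input at a
#' time by ±10%: utilities (per state), annual costs (per state and year
#' category), per-state mortality hazard ratios (all five years jointly), and
#' the annual recurrence probabilities (whole vector, clamped to `[0, 1]`).
#' Cohort age is varied ±4 years and affects only the long-term stage (the
#' per-hour 90-day distributions are left untouched). Rows are sorted by
#' output range `|high - low|`, descending (tornado order). A variation that
#' breaks a structural invariant is flagged in the `note` column, not
#' silently skipped.
#'
#' @param params A [parameter_set()].
#' @param rel_change Relative perturbation (default 0.1).
#' @param age_delta Age perturbation in years (default 4).
#' @return data.frame: `parameter`, `low`, `high`, `range`, `note`; attribute
#'   `baseline` holds the unperturbed per-hour NMB.
#' @export
run_owsa <- function(params, rel_change = 0.1, age_delta = 4) {
  base_val <- baseline_nmb_per_hour(params)
  sts <- alive_states()
  specs <- list()
  for (s in sts) specs[[paste0("utility_", s)]] <- list(kind = "utility", state = s)
  for (slot in c("cost_year1", "cost_year2", "cost_year3plus")) {
    for (s in sts) specs[[paste0(slot, "_", s)]] <- list(kind = "cost", slot = slot, state = s)
  }
  for (s in sts) specs[[paste0("hr_", s)]] <- list(kind = "hazard", state = s)
  specs[["p_recurrence"]] <- list(kind = "recurrence")

  eval_tweak <- function(spec, factor) {
    p <- tweak_param(params, spec, factor)
    if (is.null(p)) return(NA_real_)
    baseline_nmb_per_hour(p)
  }
  rows <- lapply(names(specs), function(nm) {
    lo <- eval_tweak(specs[[nm]], 1 - rel_change)
    hi <- eval_tweak(specs[[nm]], 1 + rel_change)
    note <- if (anyNA(c(lo, hi))) "perturbation breaks validity" else ""
    data.frame(parameter = nm, low = lo, high = hi, note = note)
  })
  # age +-4 years, long-term model only
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "start_age",
    low = baseline_nmb_per_hour(params, age_offset = -age_delta),
    high = baseline_nmb_per_hour(params, age_offset = age_delta),
    note = ""
  )
  out <- do.call(rbind, rows)
  out$range <- abs(out$high - out$low)
  out <- out[order(-out$range), c("parameter", "low", "high", "range", "note")]
  rownames(out) <- NULL
  attr(out, "baseline") <- base_val
  out
}

# moment-matched gamma draw (mean m, sd s); degenerate at s = 0 or m = 0
rgamma_mm <- function(n, m, s) {
  if (s <= 0 || m <= 0) return(rep(m, n))
  shape <- (m / s)^2
  stats::rgamma(n, shape = shape, rate = shape / m)
}

# moment-matched beta draw (mean m, sd s), clamped to a feasible variance
rbeta_mm <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  if (m <= 0 || m >= 1) return(rep(m, n))
  v <- min(s^2, m * (1 - m) * 0.999)
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, m * k, (1 - m) * k)
}

#' Draw one parameter set for the PSA
#'
#' Conventional cost-effectiveness sampling distributions: per-hour mRS
#' distributions from `Dirichlet(counts)` (zero cells stay zero); utilities
#' from untruncated normals (negative values allowed); costs from
#' moment-matched gammas; hazard ratios from lognormals around the baseline;
#' recurrence probabilities from moment-matched betas. Hyperparameters come
#' from the `psa` annotations of the parameter set; any parameter without an
#' annotation stays at baseline. The draw passes
#' [validate_parameter_set()].
#'
#' @param params A [parameter_set()] with `psa` annotations and
#'   `short_term_counts`.
#' @param seed Optional seed (restores the caller's RNG stream).
#' @return A new [parameter_set()].
#' @export
draw_parameter_set <- function(params, seed = NULL) {
  if (is.null(params$psa)) stop("parameter set has no PSA annotations", call. = FALSE)
  draw <- function() {
    p <- params
    psa <- params$psa
    if (!is.null(params$short_term_counts)) {
      p$short_term <- sample_short_term(params$short_term_counts)
    }
    sts <- alive_states()
    if (!is.null(psa$utility_se)) {
      se <- rep_len(psa$utility_se, 5)
      p$econ$utility <- stats::setNames(
        stats::rnorm(5, params$econ$utility, se), sts)
    }
    if (!is.null(psa$cost_rel_se)) {
      rel <- rep_len(psa$cost_rel_se, 15)
      slots <- c("cost_year1", "cost_year2", "cost_year3plus")
      for (j in seq_along(slots)) {
        m <- params$econ[[slots[j]]]
        r <- rel[(j - 1) * 5 + 1:5]
        p$econ[[slots[j]]] <- stats::setNames(
          vapply(1:5, function(i) rgamma_mm(1, m[i], r[i] * m[i]), numeric(1)), sts)
      }
      # enforce the structural ordering of long-run costs against year 2
      p$econ$cost_year3plus <- pmin(p$econ$cost_year3plus, p$econ$cost_year2)
    }
    if (!is.null(psa$hr_log_se)) {
      sd_log <- matrix(rep_len(psa$hr_log_se, 25), 5, 5)
      hr <- exp(log(unclass(params$hazards)) + stats::rnorm(25, 0, sd_log))
      # preserve the ordinal severity ordering the model assumes
      hr <- apply(hr, 2L, cummax)
      p$hazards <- hazard_ratios(hr)
    }
    if (!is.null(psa$p_rec_se)) {
      se <- rep_len(psa$p_rec_se, 5)
      pr <- vapply(1:5, function(i) rbeta_mm(1, params$recurrence$p_rec[i], se[i]),
                   numeric(1))
      p$recurrence$p_rec <- stats::setNames(pr, paste0("year", 1:5))
    }
    p
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: for each draw the full short-term + long-term +
#' economic pipeline is evaluated, the five adjacent-hour differences in
#' costs, QALYs and NMV are formed, and the per-hour effect is the per-draw
#' median of the five differences; per-10-minute and per-minute values follow
#' by the linear time conversion. Summaries are the empirical median and
#' interquartile range across draws (quantile type 7, linear interpolation
#' between order statistics). Draws that fail validation are counted,
#' excluded and reported, never silently dropped.
#'
#' @param params A [parameter_set()] with PSA annotations.
#' @param n_draws Number of Monte Carlo draws (study default 10000).
#' @param seed RNG seed for the whole run.
#' @param include_cycle0 Passed to [accrue()].
#' @return List of class `psa_result`:
#'   `summary` (data.frame: outcome, unit, median, q25, q75),
#'   `draws` (data.frame of per-draw per-hour d_costs, d_qalys, nmb and the
#'   per-pair values), `n_draws`, `n_failed`, `seed`.
#' @export
run_psa <- function(params, n_draws = 10000L, seed = 1L, include_cycle0 = FALSE) {
  stopifnot(n_draws >= 1)
  wtp <- params$econ$wtp
  per_pair_cost <- matrix(NA_real_, n_draws, 5L)
  per_pair_qaly <- matrix(NA_real_, n_draws, 5L)
  per_pair_nmb <- matrix(NA_real_, n_draws, 5L)
  per_hour <- matrix(NA_real_, n_draws, 3L,
                     dimnames = list(NULL, c("d_costs", "d_qalys", "nmb")))
  n_failed <- 0L
  with_seed(seed, {
    for (i in seq_len(n_draws)) {
      p <- draw_parameter_set(params)
      if (length(validate_parameter_set(p))) {
        n_failed <- n_failed + 1L
        next
      }
      strata <- simulate_strata(p, include_cycle0 = include_cycle0)
      pairs <- nmb_between_strata(strata, wtp)
      per_pair_cost[i, ] <- pairs$d_costs
      per_pair_qaly[i, ] <- pairs$d_qalys
      per_pair_nmb[i, ] <- pairs$nmb
      per_hour[i, ] <- c(per_hour_median(pairs$d_costs),
                         per_hour_median(pairs$d_qalys),
                         per_hour_median(pairs$nmb))
    }
  })
  ok <- !is.na(per_hour[, 1])
  med_iqr <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)

  rows <- list()
  add_row <- function(outcome, unit, x) {
    q <- med_iqr(x)
    rows[[length(rows) + 1L]] <<- data.frame(
      outcome = outcome, unit = unit, median = q[1], q25 = q[2], q75 = q[3])
  }
  pair_labels <- paste0("hour", 1:5, "_vs_hour", 2:6)
  for (j in 1:5) {
    add_row(paste0(pair_labels[j], "_costs"), "EUR", per_pair_cost[ok, j])
    add_row(paste0(pair_labels[j], "_qalys"), "QALY", per_pair_qaly[ok, j])
    add_row(paste0(pair_labels[j], "_nmb"), "EUR", per_pair_nmb[ok, j])
  }
  add_row("per_hour_costs", "EUR", per_hour[ok, "d_costs"])
  add_row("per_hour_qalys", "QALY", per_hour[ok, "d_qalys"])
  add_row("per_hour_nmb", "EUR", per_hour[ok, "nmb"])
  add_row("per_10min_costs", "EUR", convert_time_unit(per_hour[ok, "d_costs"], 10))
  add_row("per_10min_days", "days", qalys_to_disability_free_days(per_hour[ok, "d_qalys"], 10, round_days = FALSE))
  add_row("per_10min_nmb", "EUR", convert_time_unit(per_hour[ok, "nmb"], 10))
  add_row("per_minute_costs", "EUR", convert_time_unit(per_hour[ok, "d_costs"], 1))
  add_row("per_minute_days", "days", qalys_to_disability_free_days(per_hour[ok, "d_qalys"], 1, round_days = FALSE))
  add_row("per_minute_nmb", "EUR", convert_time_unit(per_hour[ok, "nmb"], 1))

  draws <- data.frame(per_hour[ok, , drop = FALSE])
  colnames(per_pair_cost) <- paste0(pair_labels, "_costs")
  colnames(per_pair_qaly) <- paste0(pair_labels, "_qalys")
  colnames(per_pair_nmb) <- paste0(pair_labels, "_nmb")
  draws <- cbind(draws, per_pair_cost[ok, , drop = FALSE],
                 per_pair_qaly[ok, , drop = FALSE],
                 per_pair_nmb[ok, , drop = FALSE])

  structure(
    list(summary = do.call(rbind, rows), draws = draws,
         n_draws = n_draws, n_failed = n_failed, seed = seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws (", x$n_failed, "failed validation ), seed",
      x$seed, "\n")
  key <- x$summary[x$summary$outcome %in%
                     c("per_minute_costs", "per_minute_days", "per_minute_nmb"), ]
  print(transform(key, median = signif(median, 4), q25 = signif(q25, 4),
                  q75 = signif(q75, 4)), row.names = FALSE)
  invisible(x)
}

#' Export a PSA summary to CSV
#' @param psa A `psa_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  utils::write.csv(psa$summary, path, row.names = FALSE)
  invisible(path)
}
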