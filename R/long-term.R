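# Long-term stage: the annual-cycle Markov engine. Background mortality from
# the life table is scaled by state- and year-specific hazard ratios on the
# cumulative-hazard scale; survivors face an annual recurrence risk whose
# outcome is the control-arm distribution truncated to equal-or-worse states
# (death is never a recurrence outcome, to avoid double-counting
# stroke-related mortality already carried by the hazard ratios).

#' Annual death probability for a Markov state
#'
#' Mixes the male and female background probabilities
#' (`q_mix = sex_mix * q(age, M) + (1 - sex_mix) * q(age, F)`) and applies the
#' state/year hazard ratio on the cumulative-hazard scale:
#' `p = 1 - exp(log(1 - q_mix) * hr)`, i.e. `1 - (1 - q_mix)^hr`, clamped to
#' `[0, 1]`.
#'
#' @param age Integer age during the cycle.
#' @param sex_mix Fraction male.
#' @param state An alive state label.
#' @param t Year since the index stroke (1..5), selecting the hazard-ratio
#'   column.
#' @param lt A [life_table()].
#' @param hazards A [hazard_ratios()] matrix.
#' @return Death probability in `[0, 1]`.
#' @export
#' @examples
#' ps <- gen_parameter_set(synthetic_config())
#' annual_death_prob(69, 0.5, "MRS3", 1, ps$life_table, ps$hazards)
annual_death_prob <- function(age, sex_mix, state, t, lt, hazards) {
  if (!state %in% alive_states()) stop("`state` must be an alive state", call. = FALSE)
  if (!t %in% 1:5) stop("`t` must be a year 1..5", call. = FALSE)
  hr <- hazards[state, t]
  if (!is.finite(hr) || hr <= 0) stop("hazard ratio must be positive", call. = FALSE)
  q_mix <- sex_mix * lookup_qx(lt, age, "M") + (1 - sex_mix) * lookup_qx(lt, age, "F")
  if (q_mix >= 1) return(1)
  min(1, max(0, 1 - exp(log1p(-q_mix) * hr)))
}

#' Post-recurrence state distribution
#'
#' After a recurrent stroke the patient's mRS can only remain equal or worsen,
#' and death is not a recurrence outcome. The control-arm base distribution is
#' truncated to states at or above (i.e. at least as severe as) the current
#' state and renormalized.
#'
#' @param current Current alive state label.
#' @param base_dist Length-5 distribution over the alive states (sums to 1).
#' @return Named length-5 vector over the alive states: zero below `current`,
#'   renormalized mass at and above it.
#' @export
#' @examples
#' recurrence_redistribution("MRS3", c(0.3, 0.2, 0.2, 0.2, 0.1))
recurrence_redistribution <- function(current, base_dist) {
  sts <- alive_states()
  i <- match(current, sts)
  if (is.na(i)) stop("`current` must be an alive state", call. = FALSE)
  if (length(base_dist) != 5L || any(base_dist < 0) ||
      abs(sum(base_dist) - 1) > 1e-9) {
    stop("`base_dist` must be 5 non-negative values summing to 1", call. = FALSE)
  }
  out <- stats::setNames(numeric(5L), sts)
  tail_mass <- sum(base_dist[i:5])
  if (tail_mass <= 0) {
    stop("no post-recurrence outcome available at or above ", current, call. = FALSE)
  }
  out[i:5] <- base_dist[i:5] / tail_mass
  out
}

#' Build the transition matrix for one model year
#'
#' Within a cycle, death is resolved first; survivors either stay in their
#' state (probability `1 - p_rec(t)`) or suffer a recurrent stroke and move
#' according to [recurrence_redistribution()]. The `DEAD` row is the identity
#' (absorbing). The cohort ages deterministically: during year `t` its age is
#' `start_age + t - 1`.
#'
#' @param t Model year 1..5.
#' @param params A [parameter_set()].
#' @param age_offset Optional shift of the cohort start age (used by the
#'   one-way sensitivity analysis; affects only this long-term stage).
#' @return 6x6 row-stochastic matrix, rows/cols in state order.
#' @export
build_transition_matrix <- function(t, params, age_offset = 0) {
  sts <- mrs_states()
  m <- matrix(0, 6, 6, dimnames = list(sts, sts))
  age <- params$cohort$start_age + age_offset + t - 1
  p_rec <- params$recurrence$p_rec[t]
  base <- params$recurrence$base_dist
  for (s in alive_states()) {
    p_death <- annual_death_prob(age, params$cohort$sex_mix, s, t,
                                 params$life_table, params$hazards)
    survive <- 1 - p_death
    m[s, "DEAD"] <- p_death
    m[s, s] <- survive * (1 - p_rec)
    m[s, alive_states()] <- m[s, alive_states()] +
      survive * p_rec * recurrence_redistribution(s, base)
  }
  m["DEAD", "DEAD"] <- 1
  m
}

#' Run the cohort through the five-year Markov model
#'
#' Cycle 0 is the 90-day post-treatment distribution (the short-term outcome);
#' no long-term transition applies to it. Occupancy then propagates through
#' the year-specific transition matrices:
#' `occupancy(t) = occupancy(t-1) %*% matrix(t)`.
#'
#' @param start An [mrs_distribution()]: the 90-day state distribution.
#' @param params A [parameter_set()].
#' @param age_offset Passed to [build_transition_matrix()].
#' @return A `cohort_trace`: `(horizon + 1) x 6` matrix of state occupancy,
#'   rows `cycle0`..`cycle5`.
#' @export
run_cohort <- function(start, params, age_offset = 0) {
  start <- mrs_distribution(start)
  horizon <- params$cohort$horizon_years
  occ <- matrix(NA_real_, horizon + 1L, 6L,
                dimnames = list(paste0("cycle", 0:horizon), mrs_states()))
  occ[1, ] <- unclass(start)
  for (t in seq_len(horizon)) {
    m <- build_transition_matrix(t, params, age_offset = age_offset)
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% m
  }
  structure(occ, class = c("cohort_trace", "matrix"))
}

#' Microsimulation oracle for the cohort trace
#'
#' Simulates `n` individuals through the identical transition law by
#' individual-level sampling. Used as an independent check that the
#' matrix-propagation engine and the individual-level interpretation of the
#' model agree; not part of the analysis pipeline.
#'
#' @param start An [mrs_distribution()].
#' @param params A [parameter_set()].
#' @param n Number of simulated individuals.
#' @param seed RNG seed.
#' @return Occupancy matrix of empirical proportions, same shape as
#'   [run_cohort()] output.
#' @export
microsimulate_cohort <- function(start, params, n = 1e5, seed = 1L) {
  start <- mrs_distribution(start)
  horizon <- params$cohort$horizon_years
  sts <- mrs_states()
  with_seed(seed, {
    state <- sample.int(6L, n, replace = TRUE, prob = unclass(start))
    occ <- matrix(0, horizon + 1L, 6L,
                  dimnames = list(paste0("cycle", 0:horizon), sts))
    occ[1, ] <- tabulate(state, 6L) / n
    for (t in seq_len(horizon)) {
      m <- build_transition_matrix(t, params)
      new_state <- state
      for (s in which(tabulate(state, 6L) > 0)) {
        idx <- which(state == s)
        new_state[idx] <- sample.int(6L, length(idx), replace = TRUE, prob = m[s, ])
      }
      state <- new_state
      occ[t + 1L, ] <- tabulate(state, 6L) / n
    }
    structure(occ, class = c("cohort_trace", "matrix"))
  })
}

#' Export a set of cohort traces to CSV
#'
#' One row per (delay stratum, cycle), columns = the six states.
#'
#' @param traces Named list of `cohort_trace` matrices (names = strata).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    data.frame(stratum = nm, cycle = 0:(nrow(tr) - 1L),
               as.data.frame(unclass(tr), row.names = FALSE),
               check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
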