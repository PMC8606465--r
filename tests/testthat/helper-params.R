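# Shared fixtures: small hand-built parameter sets with controllable risk
# components, used across the module tests.

# flat life table with constant annual death probability q for both sexes
flat_life_table <- function(q = 0) {
  life_table(18:110, rep(q, 93), rep(q, 93))
}

# economic inputs with simple round numbers; zero rates unless asked for
simple_econ <- function(wtp = 80000, discount_qaly = 0, discount_cost = 0,
                        inflation = 0, price_year_factor = 1,
                        utility = c(0.9, 0.7, 0.5, 0.3, -0.1),
                        cost_year1 = c(10000, 15000, 25000, 40000, 55000)) {
  economic_inputs(
    utility = utility,
    cost_year1 = cost_year1,
    cost_year2 = cost_year1 / 2,
    cost_year3plus = cost_year1 / 2 * 0.8,
    wtp = wtp, discount_qaly = discount_qaly, discount_cost = discount_cost,
    inflation = inflation, price_year_factor = price_year_factor
  )
}

# parameter set whose mortality/recurrence risk is fully controllable:
# q = background death probability, hr = flat hazard ratio, p_rec = flat
# annual recurrence probability
toy_params <- function(q = 0, hr = 1, p_rec = 0,
                       base_dist = c(0.3, 0.2, 0.2, 0.2, 0.1),
                       econ = simple_econ(),
                       start = c(0.3, 0.2, 0.2, 0.15, 0.1, 0.05)) {
  st <- lapply(1:6, function(h) mrs_distribution(start))
  names(st) <- paste0("hour", 1:6)
  parameter_set(
    short_term = st,
    short_term_counts = lapply(st, function(p) unclass(p) * 100),
    life_table = flat_life_table(q),
    hazards = hazard_ratios(matrix(hr, 5, 5)),
    recurrence = recurrence_model(rep(p_rec, 5), base_dist),
    econ = econ,
    cohort = cohort_spec()
  )
}

# brute-force truncate-and-normalize oracle for the post-recurrence
# redistribution, written independently of the implementation
brute_redistribution <- function(current_index, base_dist) {
  keep <- rep(0, 5)
  for (j in seq_len(5)) if (j >= current_index) keep[j] <- base_dist[j]
  keep / sum(keep)
}
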