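#' @keywords internal
"_PACKAGE"

# Shared domain vocabulary: the six Markov states, delay strata, and the full
# model parameterization used by every downstream stage.

#' The six Markov health states
#'
#' Modified Rankin Scale (mRS) sub-scores define the states; mRS 0 and 1 are
#' merged into a single state at the type level because they are merged in the
#' model, so every table in the package is keyed on this six-level vector.
#' `DEAD` (mRS 6) is absorbing. Severity is ordinal:
#' `MRS0_1 < MRS2 < MRS3 < MRS4 < MRS5 < DEAD`.
#'
#' @return Character vector of the six state labels, in severity order.
#' @export
#' @examples
#' mrs_states()
mrs_states <- function() {
  c("MRS0_1", "MRS2", "MRS3", "MRS4", "MRS5", "DEAD")
}

#' Non-dead (alive) states in severity order
#' @return Character vector of the five alive state labels.
#' @export
alive_states <- function() {
  setdiff(mrs_states(), "DEAD")
}

# Delay strata: onset-to-groin-puncture hour bins 1..6, upper bound 360 min.
HOUR_STRATA <- 1:6

#' Construct a probability distribution over the six Markov states
#'
#' @param probs Numeric vector of length 6, named or in the order of
#'   [mrs_states()]. Must be non-negative and sum to 1 (tolerance `1e-12`).
#' @return Named numeric vector of class `mrs_distribution`.
#' @export
#' @examples
#' mrs_distribution(c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1))
mrs_distribution <- function(probs) {
  states <- mrs_states()
  if (!is.numeric(probs) || length(probs) != 6L) {
    stop("`probs` must be a numeric vector of length 6", call. = FALSE)
  }
  if (!is.null(names(probs))) {
    if (!setequal(names(probs), states)) {
      stop("`probs` names must be the six mRS states", call. = FALSE)
    }
    probs <- probs[states]
  } else {
    names(probs) <- states
  }
  if (any(probs < 0)) stop("state probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("state probabilities must sum to 1 (got ", format(sum(probs), digits = 15), ")",
         call. = FALSE)
  }
  structure(probs, class = "mrs_distribution")
}

#' Construct a life table
#'
#' Annual background death probabilities of the general population by integer
#' age and sex, anchored at a calendar start year (the simulation start).
#'
#' @param ages Integer vector of ages covered (must be contiguous).
#' @param qx_male,qx_female Annual death probabilities per age, in `[0, 1]`.
#' @param start_year Calendar year the table starts in (default 2021).
#' @return A `life_table` object.
#' @export
life_table <- function(ages, qx_male, qx_female, start_year = 2021L) {
  stopifnot(length(ages) == length(qx_male), length(ages) == length(qx_female))
  if (any(diff(ages) != 1L)) stop("`ages` must be contiguous integers", call. = FALSE)
  if (any(qx_male < 0 | qx_male > 1) || any(qx_female < 0 | qx_female > 1)) {
    stop("death probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(ages = as.integer(ages), qx_male = qx_male, qx_female = qx_female,
         start_year = as.integer(start_year)),
    class = "life_table"
  )
}

#' Look up an annual background death probability
#'
#' @param lt A [life_table()].
#' @param age Integer age in years.
#' @param sex `"M"` or `"F"`.
#' @return Annual death probability `q(age, sex)`.
#' @export
lookup_qx <- function(lt, age, sex = c("M", "F")) {
  sex <- match.arg(sex)
  i <- match(as.integer(age), lt$ages)
  if (is.na(i)) stop("age ", age, " outside life-table range", call. = FALSE)
  if (sex == "M") lt$qx_male[i] else lt$qx_female[i]
}

#' Construct mortality hazard ratios by state and year since stroke
#'
#' Excess all-cause mortality of stroke survivors relative to the general
#' population, as a hazard ratio per alive state and per year 1..5 after the
#' index stroke.
#'
#' @param hr Numeric 5x5 matrix, rows = alive states (severity order), columns
#'   = years 1..5 since stroke. All entries must be positive.
#' @return A `hazard_ratios` object (the matrix, dimnames enforced).
#' @export
hazard_ratios <- function(hr) {
  hr <- as.matrix(hr)
  if (!all(dim(hr) == c(5L, 5L))) stop("`hr` must be a 5x5 matrix", call. = FALSE)
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("hazard ratios must be finite and positive", call. = FALSE)
  }
  dimnames(hr) <- list(alive_states(), paste0("year", 1:5))
  structure(hr, class = c("hazard_ratios", "matrix"))
}

#' Construct the stroke-recurrence model
#'
#' @param p_rec Numeric vector of length 5: annual probability of a recurrent
#'   stroke in years 1..5 after the index stroke.
#' @param base_dist Numeric vector of length 5 over the alive states: the
#'   90-day functional-outcome distribution excluding death used to assign the
#'   post-recurrence state (before truncation to equal-or-worse states).
#'   Must sum to 1.
#' @return A `recurrence_model` object.
#' @export
recurrence_model <- function(p_rec, base_dist) {
  if (length(p_rec) != 5L || any(p_rec < 0 | p_rec > 1)) {
    stop("`p_rec` must be 5 probabilities in [0, 1]", call. = FALSE)
  }
  if (length(base_dist) != 5L || any(base_dist < 0) ||
      abs(sum(base_dist) - 1) > 1e-12) {
    stop("`base_dist` must be 5 non-negative values summing to 1", call. = FALSE)
  }
  names(p_rec) <- paste0("year", 1:5)
  names(base_dist) <- alive_states()
  structure(list(p_rec = p_rec, base_dist = base_dist), class = "recurrence_model")
}

#' Construct the economic inputs
#'
#' Utilities are annual QALY weights per state; negative values are allowed
#' (states perceived as worse than death) and never clamped. Costs are annual
#' euro amounts per state in three year categories: year 1 (anchored on 90-day
#' mRS), year 2 (anchored on 18-month mRS), and years 3+ (year-2 costs
#' excluding rehabilitation). `price_year_factor` adjusts historical reference
#' prices (2015) to the simulation start year (2021).
#'
#' @param utility Named numeric vector over the 5 alive states (DEAD accrues 0).
#' @param cost_year1,cost_year2,cost_year3plus Named numeric vectors over the
#'   5 alive states, euros per year. `cost_year3plus <= cost_year2` per state.
#' @param wtp Willingness to pay, euros per QALY (default 80000).
#' @param discount_qaly Annual QALY discount rate (default 0.015).
#' @param discount_cost Annual cost discount rate (default 0.04).
#' @param inflation Annual cost inflation rate (default 0.017).
#' @param price_year_factor Multiplier adjusting reference-year prices to the
#'   simulation start year (default 1).
#' @return An `economic_inputs` object.
#' @export
economic_inputs <- function(utility, cost_year1, cost_year2, cost_year3plus,
                            wtp = 80000, discount_qaly = 0.015,
                            discount_cost = 0.04, inflation = 0.017,
                            price_year_factor = 1) {
  as_alive <- function(x, what) {
    if (length(x) != 5L) stop("`", what, "` must have 5 entries (alive states)", call. = FALSE)
    if (!is.null(names(x))) x <- x[alive_states()] else names(x) <- alive_states()
    if (any(is.na(x))) stop("`", what, "` has missing/misnamed entries", call. = FALSE)
    x
  }
  utility <- as_alive(utility, "utility")
  cost_year1 <- as_alive(cost_year1, "cost_year1")
  cost_year2 <- as_alive(cost_year2, "cost_year2")
  cost_year3plus <- as_alive(cost_year3plus, "cost_year3plus")
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  for (r in c(discount_qaly, discount_cost, inflation)) {
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)", call. = FALSE)
  }
  if (any(cost_year3plus > cost_year2 + 1e-9)) {
    stop("`cost_year3plus` must not exceed `cost_year2` for any state", call. = FALSE)
  }
  structure(
    list(utility = utility, cost_year1 = cost_year1, cost_year2 = cost_year2,
         cost_year3plus = cost_year3plus, wtp = wtp,
         discount_qaly = discount_qaly, discount_cost = discount_cost,
         inflation = inflation, price_year_factor = price_year_factor),
    class = "economic_inputs"
  )
}

#' Construct the cohort specification
#'
#' @param start_age Age at the index stroke in years (default 69).
#' @param sex_mix Fraction male (default 0.5, an even split).
#' @param horizon_years Simulation horizon in years (default 5).
#' @param cycle_length_years Markov cycle length in years (default 1).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(start_age = 69L, sex_mix = 0.5, horizon_years = 5L,
                        cycle_length_years = 1L) {
  if (sex_mix < 0 || sex_mix > 1) stop("`sex_mix` must lie in [0, 1]", call. = FALSE)
  if (horizon_years < 1) stop("`horizon_years` must be >= 1", call. = FALSE)
  structure(
    list(start_age = as.integer(start_age), sex_mix = sex_mix,
         horizon_years = as.integer(horizon_years),
         cycle_length_years = as.integer(cycle_length_years)),
    class = "cohort_spec"
  )
}

#' Assemble a full parameter set
#'
#' Bundles every model input: the per-hour 90-day mRS distributions (with the
#' count vectors behind them, kept for Dirichlet sampling in the PSA), the
#' life table, the mortality hazard ratios, the recurrence model, the economic
#' inputs and the cohort specification, plus per-parameter sampling
#' annotations for the probabilistic sensitivity analysis.
#'
#' @param short_term Named list over `hour1`..`hour6`, each an
#'   [mrs_distribution()].
#' @param short_term_counts Optional named list of length-6 count vectors per
#'   hour (same keying), used for Dirichlet PSA draws.
#' @param life_table A [life_table()].
#' @param hazards A [hazard_ratios()] matrix.
#' @param recurrence A [recurrence_model()].
#' @param econ An [economic_inputs()].
#' @param cohort A [cohort_spec()].
#' @param psa Optional list of PSA hyperparameters (standard errors):
#'   `utility_se`, `cost_se` (relative), `hr_log_se`, `p_rec_se`.
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(short_term, life_table, hazards, recurrence, econ,
                          cohort = cohort_spec(), short_term_counts = NULL,
                          psa = NULL) {
  structure(
    list(short_term = short_term, short_term_counts = short_term_counts,
         life_table = life_table, hazards = hazards, recurrence = recurrence,
         econ = econ, cohort = cohort, psa = psa),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  short-term strata:", length(x$short_term),
      if (!is.null(x$short_term_counts)) "(with PSA counts)" else "", "\n")
  cat("  life table ages:", min(x$life_table$ages), "-", max(x$life_table$ages),
      " start year", x$life_table$start_year, "\n")
  cat("  cohort: age", x$cohort$start_age, ", sex mix", x$cohort$sex_mix,
      ", horizon", x$cohort$horizon_years, "y\n")
  cat("  WTP:", x$econ$wtp, "EUR/QALY; discount",
      x$econ$discount_qaly, "/", x$econ$discount_cost,
      "; inflation", x$econ$inflation, "\n")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and reports
#' violations as human-readable strings naming the offending field. The
#' function is total: it never raises on malformed input, it reports.
#'
#' @param params A [parameter_set()] (or anything; garbage is reported, not
#'   thrown).
#' @return Character vector of violation descriptions; empty if valid.
#' @export
#' @examples
#' ps <- gen_parameter_set(synthetic_config(seed = 1))
#' validate_parameter_set(ps)  # character(0)
validate_parameter_set <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  safe <- function(expr) tryCatch(expr, error = function(e) {
    add(paste("internal check failed:", conditionMessage(e)))
    NULL
  })

  if (!is.list(params)) return("parameter set is not a list")

  # short-term distributions
  st <- params$short_term
  if (!is.list(st) || length(st) != 6L) {
    add("short_term: must be a list of 6 hour strata")
  } else {
    for (h in seq_along(st)) {
      p <- st[[h]]
      nm <- names(st)[h]
      if (is.null(nm) || nm == "") nm <- paste0("hour", h)
      if (!is.numeric(p) || length(p) != 6L) {
        add(paste0("short_term ", nm, ": not a length-6 numeric distribution"))
        next
      }
      if (any(is.na(p)) || any(p < 0)) add(paste0("short_term ", nm, ": negative or missing probability"))
      else if (abs(sum(p) - 1) > 1e-12) add(paste0("short_term ", nm, ": probabilities sum to ",
                                                   format(sum(p), digits = 10), ", not 1"))
    }
  }

  # life table
  lt <- params$life_table
  if (!inherits(lt, "life_table")) {
    add("life_table: missing or wrong type")
  } else safe({
    if (any(lt$qx_male < 0 | lt$qx_male > 1) || any(lt$qx_female < 0 | lt$qx_female > 1)) {
      add("life_table: death probability outside [0, 1]")
    }
    over30 <- lt$ages > 30
    if (sum(over30) > 1) {
      if (any(diff(lt$qx_male[over30]) < -1e-12)) add("life_table: qx_male decreasing above age 30")
      if (any(diff(lt$qx_female[over30]) < -1e-12)) add("life_table: qx_female decreasing above age 30")
    }
  })

  # hazard ratios
  hr <- params$hazards
  if (is.null(hr) || !is.numeric(hr) || !all(dim(as.matrix(hr)) == c(5L, 5L))) {
    add("hazards: must be a 5x5 positive matrix")
  } else safe({
    if (any(!is.finite(hr)) || any(hr <= 0)) add("hazards: non-positive hazard ratio")
    for (t in 1:5) {
      if (any(diff(hr[, t]) < -1e-12)) {
        add(paste0("hazards: year ", t, " ratios not non-decreasing in mRS severity"))
        break
      }
    }
  })

  # recurrence
  rec <- params$recurrence
  if (!inherits(rec, "recurrence_model")) {
    add("recurrence: missing or wrong type")
  } else safe({
    if (any(rec$p_rec < 0 | rec$p_rec > 1)) add("recurrence: p_rec outside [0, 1]")
    if (any(rec$base_dist < 0) || abs(sum(rec$base_dist) - 1) > 1e-12) {
      add("recurrence: base_dist is not a distribution over the 5 alive states")
    }
  })

  # economics
  ec <- params$econ
  if (!inherits(ec, "economic_inputs")) {
    add("econ: missing or wrong type")
  } else safe({
    if (ec$wtp <= 0) add("econ: wtp must be positive")
    for (f in c("discount_qaly", "discount_cost", "inflation")) {
      if (ec[[f]] < 0 || ec[[f]] >= 1) add(paste0("econ: ", f, " outside [0, 1)"))
    }
    if (any(ec$cost_year3plus > ec$cost_year2 + 1e-9)) {
      add("econ: cost_year3plus exceeds cost_year2 for some state")
    }
  })

  # cohort
  co <- params$cohort
  if (!inherits(co, "cohort_spec")) {
    add("cohort: missing or wrong type")
  } else safe({
    if (co$sex_mix < 0 || co$sex_mix > 1) add("cohort: sex_mix outside [0, 1]")
    if (co$horizon_years < 1) add("cohort: horizon_years < 1")
    rng <- range(params$life_table$ages)
    if (inherits(params$life_table, "life_table") &&
        (co$start_age < rng[1] || co$start_age + co$horizon_years - 1 > rng[2])) {
      add("cohort: simulated ages fall outside the life-table range")
    }
  })

  v
}

# ---- serialization -----------------------------------------------------------

#' Write a parameter set to JSON (canonical) or YAML
#'
#' The on-disk schema mirrors the object: `short_term` (per-hour probability
#' vectors), `short_term_counts`, `life_table`, `hazards` (5x5, rows = alive
#' states), `recurrence`, `econ`, `cohort`, `psa`. All monetary values are in
#' euros, probabilities dimensionless, ages in integer years.
#'
#' @param params A [parameter_set()].
#' @param path Output file; extension `.yaml`/`.yml` selects YAML, anything
#'   else JSON.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  obj <- list(
    short_term = lapply(params$short_term, function(p) unclass(p)),
    short_term_counts = params$short_term_counts,
    life_table = list(
      ages = params$life_table$ages,
      qx_male = params$life_table$qx_male,
      qx_female = params$life_table$qx_female,
      start_year = params$life_table$start_year
    ),
    hazards = apply(unclass(params$hazards), 1L, identity, simplify = FALSE),
    recurrence = list(p_rec = unname(params$recurrence$p_rec),
                      base_dist = unname(params$recurrence$base_dist)),
    econ = lapply(unclass(params$econ), function(x) if (is.numeric(x)) unname(x) else x),
    cohort = unclass(params$cohort),
    psa = params$psa
  )
  # hazards serialized row-per-state for readability
  names(obj$hazards) <- alive_states()
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a parameter set from JSON or YAML
#'
#' @param path File written by [write_parameter_set()] (or hand-authored to
#'   the same schema).
#' @return A [parameter_set()].
#' @export
read_parameter_set <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  st <- lapply(obj$short_term, function(p) mrs_distribution(unlist(p)))
  counts <- if (!is.null(obj$short_term_counts)) {
    lapply(obj$short_term_counts, function(x) {
      x <- unlist(x); names(x) <- mrs_states(); x
    })
  }
  hz <- do.call(rbind, lapply(obj$hazards[alive_states()], unlist))
  ec <- obj$econ
  parameter_set(
    short_term = st,
    short_term_counts = counts,
    life_table = life_table(unlist(obj$life_table$ages),
                            unlist(obj$life_table$qx_male),
                            unlist(obj$life_table$qx_female),
                            obj$life_table$start_year),
    hazards = hazard_ratios(hz),
    recurrence = recurrence_model(unlist(obj$recurrence$p_rec),
                                  unlist(obj$recurrence$base_dist)),
    econ = economic_inputs(unlist(ec$utility), unlist(ec$cost_year1),
                           unlist(ec$cost_year2), unlist(ec$cost_year3plus),
                           wtp = ec$wtp, discount_qaly = ec$discount_qaly,
                           discount_cost = ec$discount_cost,
                           inflation = ec$inflation,
                           price_year_factor = ec$price_year_factor),
    cohort = cohort_spec(obj$cohort$start_age, obj$cohort$sex_mix,
                         obj$cohort$horizon_years, obj$cohort$cycle_length_years),
    psa = lapply(obj$psa, function(x) if (is.numeric(x)) unlist(x) else x)
  )
}

#' Read patient-level registry records from CSV
#'
#' Expected columns: `onset_to_groin_minutes`, `mrs90` (0..6),
#' `occlusion_location` (`ICA`, `M1`, `proxM2`, `other`), `age`,
#' `treated_in_trial_center` (logical). Missing values are empty fields.
#'
#' @param path CSV file with a header row.
#' @return A data.frame of registry records.
#' @export
read_registry_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  needed <- c("onset_to_groin_minutes", "mrs90", "occlusion_location", "age",
              "treated_in_trial_center")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("registry CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$treated_in_trial_center <- as.logical(df$treated_in_trial_center)
  df
}

#' Write registry records to CSV
#' @param records Registry data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

# round half away from zero; used for all printed euro amounts
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
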