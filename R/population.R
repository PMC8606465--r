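# Population-level extrapolation and banded external validation.

#' Yearly number of EVT-treated LVO patients
#'
#' Annualizes an inclusion count observed over a number of months:
#' `total_included * 12 / months`. A direct override is accepted (and is the
#' study default, 887/year) because the annualization formula and the
#' published headcount need not coincide; when both are available and
#' disagree by more than 1%, a warning surfaces both numbers.
#'
#' @param total_included Patients included over the observation window.
#' @param months Window length in months.
#' @param override If non-`NULL`, this value is returned (after the
#'   consistency warning). Default `NULL`.
#' @return Patients per year.
#' @export
#' @examples
#' yearly_evt_count(120, 12)            # 120
#' yearly_evt_count(3279, 43, override = 887)
yearly_evt_count <- function(total_included, months, override = NULL) {
  if (months <= 0) stop("`months` must be positive", call. = FALSE)
  formula_value <- total_included * 12 / months
  if (!is.null(override)) {
    if (abs(formula_value - override) / override > 0.01) {
      warning(sprintf(
        "override %.0f patients/year differs from the annualization %0.2f (= %s * 12 / %s)",
        override, formula_value, total_included, months))
    }
    return(override)
  }
  formula_value
}

#' Population-level effect of faster treatment
#'
#' Scales the per-patient adjacent-pair differences to the yearly treated
#' population: a prevalence-weighted average of the five hour-pair
#' differences, multiplied by the yearly patient count. Pair `(h, h+1)` is
#' weighted by the prevalence of the later hour `h+1` — the patients who
#' would be shifted one hour earlier. Weights are normalized to sum 1.
#'
#' @param per_pair data.frame from [nmb_between_strata()] (columns `d_qalys`,
#'   `d_costs`, `nmb`; 5 rows in hour order).
#' @param prevalence Non-negative weights per delay hour (length 6, hours
#'   1..6) or per pair (length 5). Need not be normalized.
#' @param n_yearly Yearly number of treated patients.
#' @return data.frame with rows `per_hour`, `per_10min`, `per_minute` and
#'   columns `d_qalys`, `d_costs`, `nmb` (population totals; euro rows of the
#'   sub-hour conversions rounded to whole euros).
#' @export
population_outcome <- function(per_pair, prevalence, n_yearly) {
  if (length(prevalence) == 6L) prevalence <- prevalence[2:6]
  if (length(prevalence) != 5L || any(prevalence < 0)) {
    stop("`prevalence` must be 5 (or 6) non-negative weights", call. = FALSE)
  }
  if (sum(prevalence) <= 0) stop("prevalence weights are all zero", call. = FALSE)
  w <- prevalence / sum(prevalence)
  per_hour <- c(d_qalys = sum(w * per_pair$d_qalys) * n_yearly,
                d_costs = sum(w * per_pair$d_costs) * n_yearly,
                nmb = sum(w * per_pair$nmb) * n_yearly)
  conv <- function(minutes) c(
    d_qalys = convert_time_unit(per_hour[["d_qalys"]], minutes),
    d_costs = convert_time_unit(per_hour[["d_costs"]], minutes, round_euro = TRUE),
    nmb = convert_time_unit(per_hour[["nmb"]], minutes, round_euro = TRUE))
  out <- rbind(per_hour = per_hour, per_10min = conv(10), per_minute = conv(1))
  as.data.frame(out)
}

#' Band a cohort trace into the three validation categories
#'
#' Good functional outcome (mRS <= 2: states `MRS0_1` + `MRS2`), poor but
#' alive (mRS 3--5), and death.
#'
#' @param trace A `cohort_trace`.
#' @param year Follow-up year 1..horizon.
#' @return Named numeric vector `mrs_le2`, `mrs_3_5`, `dead`, summing to the
#'   cycle's total occupancy.
#' @export
band_mrs <- function(trace, year) {
  horizon <- nrow(trace) - 1L
  if (year < 1 || year > horizon) stop("`year` outside the simulated horizon", call. = FALSE)
  occ <- trace[year + 1L, ]
  c(mrs_le2 = unname(occ["MRS0_1"] + occ["MRS2"]),
    mrs_3_5 = unname(occ["MRS3"] + occ["MRS4"] + occ["MRS5"]),
    dead = unname(occ["DEAD"]))
}

#' Compare banded simulated proportions with external reference values
#'
#' @param banded data.frame with columns `year`, `mrs_le2`, `mrs_3_5`, `dead`
#'   (simulated proportions), or a named list of banded vectors keyed by year.
#' @param reference data.frame with the same columns (user-supplied follow-up
#'   proportions, e.g. read with [read_reference_csv()]).
#' @return data.frame of per-band absolute differences (simulated minus
#'   reference), one row per common year. Years present in `reference` but
#'   not simulated raise an error.
#' @export
compare_to_reference <- function(banded, reference) {
  if (!is.data.frame(banded)) {
    banded <- do.call(rbind, lapply(names(banded), function(y) {
      data.frame(year = as.integer(y), t(banded[[y]]))
    }))
  }
  missing_years <- setdiff(reference$year, banded$year)
  if (length(missing_years)) {
    stop("reference year(s) not simulated: ", paste(missing_years, collapse = ", "),
         call. = FALSE)
  }
  ref <- reference[match(reference$year, reference$year), ]
  sim <- banded[match(reference$year, banded$year), ]
  data.frame(year = reference$year,
             mrs_le2 = sim$mrs_le2 - ref$mrs_le2,
             mrs_3_5 = sim$mrs_3_5 - ref$mrs_3_5,
             dead = sim$dead - ref$dead)
}

#' Read external reference proportions from CSV
#'
#' Long format: columns `year`, `band` (one of `mrs_le2`, `mrs_3_5`, `dead`),
#' `proportion`; or wide format with the three band columns directly.
#'
#' @param path CSV path.
#' @return Wide data.frame: `year`, `mrs_le2`, `mrs_3_5`, `dead`.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("band", "proportion") %in% names(df))) {
    wide <- stats::reshape(df, idvar = "year", timevar = "band",
                           direction = "wide")
    names(wide) <- sub("^proportion\\.", "", names(wide))
    rownames(wide) <- NULL
    return(wide[, c("year", "mrs_le2", "mrs_3_5", "dead")])
  }
  df[, c("year", "mrs_le2", "mrs_3_5", "dead")]
}
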