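# Short-term stage: per-hour empirical 90-day mRS distributions estimated from
# patient-level records, plus Dirichlet resampling for the PSA.

# hour bin of a minute value: half-open on the left, closed on the right, so
# hour h covers (60*(h-1), 60*h] and 360 min is the closed upper edge of hour 6
hour_of_minutes <- function(minutes) {
  as.integer(ceiling(minutes / 60))
}

#' Filter registry records by the study inclusion criteria
#'
#' Applies the six criteria in order: anterior-circulation LVO (occlusion in
#' ICA, M1 or proximal M2), treatment in a trial center, age >= 18, available
#' 90-day mRS, available onset-to-groin time, and onset-to-groin time <= 360
#' minutes (inclusive bound). Each excluded record is attributed to its first
#' failing criterion in that order.
#'
#' @param records Registry data.frame (see [read_registry_csv()]).
#' @return List with `included` (the retained data.frame) and `exclusions`
#'   (named integer vector of per-criterion counts, in criterion order).
#' @export
filter_registry <- function(records) {
  criteria <- list(
    anterior_lvo = function(d) !is.na(d$occlusion_location) &
      d$occlusion_location %in% c("ICA", "M1", "proxM2"),
    trial_center = function(d) !is.na(d$treated_in_trial_center) &
      d$treated_in_trial_center,
    age_ge_18 = function(d) !is.na(d$age) & d$age >= 18,
    mrs90_available = function(d) !is.na(d$mrs90),
    time_available = function(d) !is.na(d$onset_to_groin_minutes),
    time_le_360 = function(d) !is.na(d$onset_to_groin_minutes) &
      d$onset_to_groin_minutes <= 360
  )
  n <- nrow(records)
  excluded_by <- rep(NA_character_, n)
  for (nm in names(criteria)) {
    pass <- criteria[[nm]](records)
    hit <- is.na(excluded_by) & !pass
    excluded_by[hit] <- nm
  }
  counts <- vapply(names(criteria), function(nm) sum(excluded_by == nm, na.rm = TRUE),
                   integer(1))
  list(included = records[is.na(excluded_by), , drop = FALSE],
       exclusions = counts)
}

#' Estimate per-hour 90-day mRS distributions
#'
#' Bins included records into onset-to-groin hours 1..6 (hour `h` covers
#' minutes `(60*(h-1), 60*h]`), merges raw mRS 0 and 1 into the single
#' `MRS0_1` state on ingest, and returns the empirical relative frequencies of
#' the six states per hour together with the raw count vectors (kept for the
#' Dirichlet sampling of the PSA).
#'
#' @param records Included registry records (after [filter_registry()]).
#' @return Named list over `hour1`..`hour6`; each element has `dist` (an
#'   [mrs_distribution()]) and `counts` (named integer vector over states).
#' @export
estimate_mrs_by_hour <- function(records) {
  hour <- hour_of_minutes(records$onset_to_groin_minutes)
  merged <- ifelse(records$mrs90 <= 1, 1L, records$mrs90)  # 1..6 on merged scale
  out <- lapply(HOUR_STRATA, function(h) {
    idx <- hour == h
    if (!any(idx)) {
      stop("no records in delay hour ", h, "; cannot estimate its mRS distribution",
           call. = FALSE)
    }
    counts <- tabulate(merged[idx], nbins = 6L)
    names(counts) <- mrs_states()
    list(dist = mrs_distribution(counts / sum(counts)), counts = counts)
  })
  names(out) <- paste0("hour", HOUR_STRATA)
  out
}

# one Dirichlet(alpha) draw via gamma normalization; zero-alpha cells are
# structural zeros of the draw
rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) stop("degenerate Dirichlet draw: all components zero", call. = FALSE)
  g / sum(g)
}

#' Draw per-hour mRS distributions for the PSA
#'
#' One Dirichlet draw per delay hour, parameterized directly by the observed
#' count vectors (prior mass 0: the pure multinomial likelihood; zero-count
#' cells remain structurally zero in every draw rather than being invented).
#'
#' @param counts Named list over hours of length-6 non-negative count vectors;
#'   each hour's total must be positive.
#' @param seed Optional seed; if given, draws are reproducible and the
#'   caller's RNG stream is untouched.
#' @return Named list over hours of [mrs_distribution()] draws.
#' @export
sample_short_term <- function(counts, seed = NULL) {
  draw <- function() {
    lapply(counts, function(a) {
      if (sum(a) <= 0) stop("all-zero count vector for a delay hour", call. = FALSE)
      mrs_distribution(stats::setNames(rdirichlet1(a), mrs_states()))
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
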