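---
title: "Modelling the value of faster endovascular stroke treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the value of faster endovascular stroke treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtvalue)
```

## The question and the model

Endovascular treatment (EVT) of large-vessel-occlusion stroke is strongly
time-dependent: every hour between symptom onset and groin puncture shifts
the 90-day modified Rankin Scale (mRS) distribution toward worse outcomes.
This package quantifies what a minute of faster treatment is worth, in
quality-adjusted life years (QALYs), healthcare costs and Net Monetary
Value, over a five-year horizon.

The model has two stages.

**Short-term (0–90 days).** The 90-day mRS distribution per
onset-to-groin hour (six strata, upper bound 360 minutes) is estimated as
empirical relative frequencies from patient-level records. mRS 0 and 1 are
merged into one state *at the type level* — every table in the package is
keyed on the six-state vector `r paste(mrs_states(), collapse = ", ")` —
so inconsistent keying between merged and unmerged scales cannot arise.
The 90-day distribution is the cycle-0 occupancy of the long-term stage;
no transition, accrual or discounting applies to cycle 0 itself (acute
treatment costs enter through the year-1 cost anchor). An
`include_cycle0` switch adds one undiscounted year of accrual for users
who want the first 90 days inside the accrual; it defaults to off.

**Long-term (years 1–5).** An annual-cycle Markov chain. In year $t$ an
alive state $s$ dies with probability

$$p(s,t) = 1 - \bigl(1 - q_{\text{mix}}(a_0 + t - 1)\bigr)^{\,hr(s,t)},$$

where $q_{\text{mix}}$ mixes the male and female life-table probabilities
by the cohort's sex mix (0.5) and $hr(s,t)$ is the excess-mortality hazard
ratio of state $s$ in year $t$. Applying the ratio on the
cumulative-hazard scale is the standard actuarial convention and keeps the
result in $[0,1]$ for any positive ratio. We mix sexes *before* applying
the ratio; mixing after would differ only at second order, and the model
tracks no sex-specific occupancy to support it.

Survivors suffer a recurrent stroke with annual probability $p_{rec}(t)$.
The post-recurrence state is drawn from a control-arm 90-day outcome
distribution truncated to states at least as severe as the current one and
renormalized; death is excluded as a recurrence outcome because
stroke-related mortality is already inside the all-cause hazard ratios —
resolving death *first* within the cycle and applying recurrence to
survivors only is what keeps the two channels separate. The new state
takes effect at the next cycle boundary: the cycle of recurrence accrues
the pre-recurrence state's utility and cost, the usual annual-cycle
convention (the alternative is equally defensible; the data to distinguish
them do not exist). There is no half-cycle correction and no spontaneous
improvement.

## Economics

Utilities are annual QALY weights per state, never clamped — severe
disability can be worse than death, and the follow-up data this emulates
contain negative utilities. Costs come in three per-state anchors: year 1
(driven by the 90-day mRS: acute care and rehabilitation), year 2 (driven
by the 18-month mRS: ongoing care), and years 3+ (year-2 costs excluding
rehabilitation). Nominal costs are multiplied by a historical
price-adjustment factor (reference prices to simulation start year) and by
$(1+\text{inflation})^t$ with inflation 1.7 %/yr, then discounted at
4 %/yr; QALYs are discounted at 1.5 %/yr (the Dutch guideline pair). The
net cost factor is thus $(1.017/1.04)^t$ — inflation applies to nominal
costs before discounting.

With willingness to pay $W$ = €80,000/QALY:
$\mathrm{NMV} = \mathrm{QALY}\cdot W - \mathrm{cost}$ per stratum, and the
Net Monetary Benefit between adjacent delay hours is
$\mathrm{NMB}(h) = \mathrm{NMV}(h) - \mathrm{NMV}(h+1)$. The per-hour
effect of faster treatment is, per simulation, the **median of the five
adjacent-pair differences**; per-10-minute and per-minute values divide by
6 and 60 (an assumption of constant differences between hours). Euro
amounts are rounded to whole euros half away from zero, day-valued
outputs (disability-free days, QALY × 365) to one decimal — the rounding
that reproduces the published conversions exactly (e.g. €14,519/h → €242/min,
0.224 QALY/h → 1.4 days/min).

## Sensitivity analyses

**One-way (OWSA).** Each input moves ±10 %; cohort age moves ±4 years and
affects only the long-term stage (the observed 90-day distributions are
not age-adjusted, so age cannot touch them). Utilities and the three
annual cost anchors vary one scalar (state) at a time. Mortality hazard
ratios vary as a per-state multiplier across all five years, and
recurrence probabilities as one whole-vector multiplier, matching the
granularity at which such parameters are reported and keeping the tornado
table readable; a perturbation that breaks a structural invariant (e.g.
severity ordering of nearly-equal hazard rows) is flagged in the output,
never silently skipped.

**Probabilistic (PSA).** Second-order Monte Carlo with the conventional
cost-effectiveness families: per-hour mRS distributions ~
Dirichlet(observed counts) with prior mass 0 — zero-count cells stay
structurally zero rather than being invented; utilities ~ untruncated
normal (negative draws are legitimate); costs ~ moment-matched gamma;
hazard ratios ~ lognormal around the baseline, with the severity ordering
restored by a running maximum within each year; recurrence probabilities ~
moment-matched beta. The original distribution hyperparameters are not
public, so the families are this package's declared convention and the
synthetic annotations are stand-ins, flagged as such. Summaries are the
empirical median and 25th–75th percentiles across draws, computed with
linear interpolation between order statistics (R quantile type 7) so IQRs
are exactly reproducible. The study default is 10,000 draws;
`run_psa(n_draws = )` controls it, and the shipped acceptance script uses
2,000, which stabilizes the medians to well under the IQR width.

**Population scale.** Per-patient pair differences scale to the yearly
treated population (default 887 patients/year; the annualization
`3279 × 12/43 ≈ 915` disagrees with that published headcount, and
`yearly_evt_count()` surfaces both rather than choosing silently) by a
prevalence-weighted average over the five hour pairs. Pair $(h, h+1)$ is
weighted by the prevalence of hour $h+1$ — the patients currently treated
in the later hour are the ones a one-hour acceleration would move — with
weights normalized to sum 1. **External validation** bands a trace into
mRS ≤ 2 / mRS 3–5 / dead and tabulates signed differences against
user-supplied reference proportions; no test statistic is attached because
none is defined for this comparison.

## What the synthetic generator emulates — and what it does not

`gen_registry()` draws 90-day mRS from a proportional-odds model on the
merged six-level scale with linear predictor `ordinal_slope × hour`
(default slope 0.25/h). The source data publish per-hour empirical
distributions, not a generative law; proportional odds is the standard
ordinal model and gives a controllable monotone degradation for
parameter-recovery tests. Records satisfy the six inclusion criteria by
construction, and generators are pure functions of `(config, seed)`.

Default study conditions, chosen once:

* cohort: age 69, even sex split, 5-year horizon, 1-year cycles;
* registry size 480/hour (≈ 2,900 total, the registry's order of
  magnitude);
* utilities 0.85 / 0.70 / 0.55 / 0.25 / −0.10 (mRS 0–1 … 5): a mild
  gradient down to a worse-than-death state;
* year-1 costs €12k / €18k / €28k / €45k / €60k; year-2 costs a
  severity-dependent fraction 0.25 / 0.35 / 0.50 / 0.65 / 0.75 of year 1 —
  mild patients shed most first-year (acute + rehabilitation) costs while
  severely disabled patients keep incurring institutional care — and years
  3+ are year 2 minus a 15 % rehabilitation share. This severity-dependent
  persistence is what makes total 5-year costs nearly flat in treatment
  delay: the cheaper yearly care of milder survivors is offset by their
  longer survival, the central cost mechanism of the analysis;
* Gompertz life table $q = 1 - \exp(-a e^{b\,\text{age}} f_{\text{sex}})$
  with $a = 3\times10^{-5}$, $b = 0.09$, $f_M = 1.25$, $f_F = 0.8$:
  ≈ 1.5 %/yr for a 69-year-old man;
* hazard ratios 1.5–6.5 by severity in year 1, attenuating to 60 % of
  that by year 5; recurrence 4 % in year 1 declining to 1.6 %;
* price-year factor $1.017^6$ (six years of inflation between the cost
  reference year and the simulation start).

These are *plausible stand-ins*, not the original values, which are not
publicly available; nothing here claims to match the
Dutch life table, the published excess-mortality ratios or the trial's
cost levels numerically. Passing tests therefore demonstrate that the
machinery is correct (mass conservation, oracle agreement, parameter
recovery, directional reproduction of the published pattern: QALY gain
per hour > 0, cost IQR straddling zero, NMV declining in delay) — not
that the package reproduces the published euro amounts, which no public
input permits. The generator also omits known features of real registry
data: covariate effects on the time–outcome relation (age, occlusion
location, referral pathway), informative missingness, and
between-center heterogeneity.

## Numerical choices and degenerate inputs

* Probability mass is validated to 1e-12 at construction; traces conserve
  mass to better than 1e-10 over five cycles.
* Hour bins are left-open/right-closed so 360 min is the closed upper edge
  of hour 6; an empty hour stratum is an explicit error naming the hour.
* Dirichlet draws use the gamma construction; an all-zero count vector is
  an error, and a zero-count cell is a structural zero of every draw.
* `validate_parameter_set()` is total: arbitrary garbage yields a report,
  never an exception; each violation names the offending field.
* Degenerate PSA (all variances zero) reproduces the baseline exactly;
  `n_draws = 1` yields zero-width IQRs.
* Background mortality of exactly 1 maps to death probability 1 for any
  finite hazard ratio.

## Problem sizes used by the shipped checks

The test suite exercises the microsimulation cross-check at 100,000
individuals, short-term parameter recovery over 200 replicates of 500
records per hour, the redistribution brute-force oracle on 500
state-distribution combinations, and the directional PSA at 2,000 draws;
the acceptance script uses the same 2,000-draw PSA. These sizes make the
Monte Carlo error small against every tolerance tested while keeping a
full run of suite plus script within a few minutes on one CPU.

## Known limitations

Five-year horizon only (no lifetime extrapolation); healthcare-payer
perspective only (no societal costs); no covariate adjustment of the
short-term stage; no correlation structure between PSA parameters; no
EVPI or acceptability curves; recurrence severity distribution is
time-constant. The published baseline triplet (0.224 QALY/h, −€2,433/h,
NMB €14,519/h) is mutually inconsistent with the NMB identity
(0.224 × 80,000 + 2,433 = €20,353); this package computes the identity and
reports both discounted components rather than forcing agreement with any
single printed number.
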