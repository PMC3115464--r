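---
title: "Modelling medical cost trajectories around chronic-disease onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling medical cost trajectories around chronic-disease onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costtraj)
```

## The model

When an elderly person is diagnosed with a chronic disease, their monthly
medical spending follows a characteristic shape: a flat pre-diagnosis
plateau, a sharp spike in the diagnosis month, and an exponential decline
to a new, somewhat elevated plateau. costtraj models the mean cost per
month per capita as

$$C(m) = c + \bigl(\delta + (P - \delta)\, e^{-r m}\bigr)\, I(m \ge 0),$$

where $m$ is the month relative to onset and $I$ the indicator function.
The four parameters are directly interpretable:

* **$c$ (USD/month)** — the pre-diagnosis plateau, a dollar-denominated
  measure of the *initial comorbidity* of people who go on to develop the
  disease;
* **$P$ (USD)** — the *cost of onset*, the excess spending in the
  diagnosis month ($C(0) = c + P$);
* **$r$ (1/month)** — the *population recovery rate*, the exponential
  slope of the post-onset decline. It is a population-level quantity:
  individual patients need not recover clinically for the cohort's mean
  spending to fall;
* **$\delta$ (USD/month)** — the *acquired comorbidity*, the difference
  between the post-onset asymptote $c + \delta$ and the pre-onset
  plateau.

When the post-onset curve is flat ($P \approx \delta$), $r$ drops out of
the model and is unidentifiable; the degenerate step model
$C(m) = c + P\, I(m \ge 0)$ is used instead (see *Model selection*).

## From claims to profiles

The pipeline mirrors a claims-based epidemiological analysis of Medicare
Parts A/B records linked to a survey interview.

**Onset ascertainment.** A person's onset date for a disease is the date
of the earliest claim carrying a matching ICD-9 code as *primary*
diagnosis in one of four qualifying sources (inpatient, outpatient,
physician, skilled nursing facility), provided a second such claim exists
on a strictly later date at most 0.3 years later. We read 0.3 years as
$0.3 \times 365.25 = 109.575$ days, so integer day gaps up to 109 qualify.
Same-date claims never confirm each other, and if the earliest qualifying
claim is unconfirmed the person has no onset at all — a deliberate
feature of the rule, since the earliest record defines the candidate
onset date. Twelve diseases are shipped with their ICD-9 definitions
(`disease_definitions()`), from acute coronary heart disease (410.xx,
411.xx, 413.xx) to Alzheimer's disease (331.0, 290.1); breast and
prostate cancer are sex-restricted.

**Prevalence exclusion.** Anyone with a matching record — any diagnosis
position, any claim source — before the interview date is excluded. The
asymmetry with detection (primary-only, four sources) is intentional:
histories are reconstructed "combining all records", whereas the onset
date needs the stricter signal of a treated primary diagnosis. Whether
secondary diagnoses should mark a history is genuinely open; we default
to any-position and expose `any_position = FALSE` as a switch.

**Incident cohort.** Onsets within 5 years after the interview form the
cohort; this pairs with the exclusion window so every member has claims
history on both sides of onset.

**Profiles.** Costs are deflated to year-2000 dollars with the medical-care
CPI, summed per calendar month, and aligned on the onset month
($m = 0$), giving 41 monthly points from $-20$ to $+20$. Calendar-month
binning avoids day-count drift across the window. Right censoring is
handled at the person-month level: months strictly after the death month
leave the at-risk set, while the death month itself remains at risk
because partial-month outlays are real spending. Zero-cost months for
enrolled, living persons are real observations (per-capita semantics).
Each month's mean and standard error are computed over its at-risk
persons; months with fewer than two contributors are flagged (`se = NA`)
and excluded from weighted fits. Per-person survey weights are supported
but default to 1 — national population estimation is out of scope.

**Stratification.** Four variables, each partitioning the cohort:
Charlson comorbidity category (0 / 1 / 2 / >2, computed from all codes in
the 12 months before the interview with the published ICD-9 group
definitions, weights and hierarchy rules), the three-level ADL/IADL
disability index, age at diagnosis ($\le 80$ vs $> 80$, inclusive
boundary), and survival 2.5 years (913 days) after onset.

## Fitting

Profiles are fit by nonlinear least squares
(Levenberg–Marquardt, via minpack.lm) minimising
$\sum_i w_i (C_i - C(m_i))^2$. The default weighting is inverse-variance
($w_i = 1/\sigma_i^2$), consistent with the reported per-month standard
errors and the $\chi^2/df$ diagnostic; an unweighted mode is provided
because plain least squares is equally defensible, and the fitter falls
back to it automatically when a profile carries no usable variances
(e.g. noiseless data). Initialisation: $c_0$ is the pre-onset mean,
$P_0 = C(0) - c_0$, $\delta_0$ the post-onset tail mean minus $c_0$, and
$r$ is multi-started over $\{0.05, 0.2, 0.5, 1, 2\}$, keeping the best
converged fit. $r$ is unconstrained in sign; slightly negative estimates
are legitimate for diseases without population recovery. Parameter
covariances are the unscaled $(J^\top W J)^{-1}$ under inverse-variance
weighting (the weights already carry the variances) and the standard
residual-scaled form otherwise.

**Goodness of fit** is $\chi^2/df = df^{-1} \sum_i (C_i - C(m_i))^2 /
\sigma_i^2$ summed over the monthly points, with $df$ = points used minus
parameters ($41 - 4 = 37$ for a full profile). A two-month pooling of the
residual sum is available (`aggregate_months = 2`) but is a display
convention only; the monthly sum is the statistic that is calibrated
(mean near 1 for a well-specified fit), and the default.

**Model selection.** The step model replaces the full model when the fit
fails, or when $\hat{se}_r / |\hat r|$ exceeds a threshold (default 10).
The threshold is a documented choice: the underlying phenomenon is a
post-onset curve too flat to pin down a decay rate, and any cutoff on the
relative SE of $r$ encodes it; 10 marks estimates whose sign is not even
loosely determined while tolerating the noisy-but-meaningful estimates
seen in small strata.

## The population forecast

For a cohort at risk of one disease with disease-free survival $S(x)$
(hazard $h$, density $f = hS$, distribution $F = 1 - S$), the expected
per-capita cost at time $x$ is

$$C_{tot}(x) = c\,S(x) + (c + \delta)\,F(x) +
  (P - \delta) \int_0^x e^{-r(x-u)} f(u)\, du,$$

the three terms being still-healthy individuals, the acquired-comorbidity
plateau of those with onset, and the decaying treatment cost integrated
over onset times. The model assumes no other health event (including
death) during follow-up — death-inclusive forecasting is an explicit
non-goal here. Time is in months throughout, matching the units of $r$.
Three evaluation routes are provided: a closed form under constant hazard
(with the $r = h$ limit handled analytically), adaptive quadrature
(absolute tolerance $10^{-10}(c+P)$) for the general continuous case, and
an exact finite sum for tabulated survival functions such as Kaplan–Meier
estimates, whose density is a sum of point masses at the drop times.

## The synthetic-data generator

Real analyses of this kind use restricted linked survey–Medicare files.
The generator replaces them with a population whose every assumption is
explicit and whose truth is exported, so each pipeline stage is testable:

* per-person monthly costs follow the trajectory model around a true
  onset date, with the twelve shipped disease quadruples (e.g. ACHD:
  $c = 815$, $P = 29842$, $r = 1.15$, $\delta = 1005$) as generating
  truth and Gaussian noise on monthly totals truncated at zero — the
  simplest structure consistent with a least-squares analysis of means
  and SEs, since the claim-level cost distribution is not something the
  profile statistics constrain;
* onsets arise from competing per-month Bernoulli hazards (at most one
  tracked disease per person); the default hazard, 0.0012/month for
  every disease, is a power-driven design choice giving each disease
  cohort roughly 50–100 incident cases at the default 2,000 persons —
  real incidence rates differ by disease and would leave the rarer
  cancers with a handful of cases at this population size;
* post-onset death is a per-month Bernoulli hazard (default 0.01/month,
  about 26% dead within 2.5 years), which populates the survival strata
  naturally; persons without onset do not die within the window, a
  simplification that leaves pre-onset censoring untested;
* detection realism: a configurable fraction of cases carries a
  qualifying claim pair before the interview (prevalent contamination)
  and another fraction emits only one qualifying record; confirmation
  gaps are uniform on 7–60 days by default;
* Charlson conditions are planted as coded claims in the year before the
  interview, using representative codes chosen not to collide with the
  twelve disease definitions so that background comorbidity does not
  create spurious prevalent cases;
* claims are emitted in nominal dollars via the shipped medical-care CPI
  series, so the deflation step is exercised nontrivially. Each monthly
  total rides on a single background carrier claim dated the first of
  the month (inpatient stays are not split across months); detection and
  comorbidity claims are separate zero-paid records, keeping monthly
  aggregation exactly conservative.

What the generator does *not* emulate: skewed or heavy-tailed claim-level
cost distributions, end-of-life cost escalation, second onsets and
recurrences, period/cohort effects, seasonality, or realistic Medicare
file layouts. Passing tests therefore demonstrate that the pipeline
recovers the data-generating process it assumes, not that real claims
data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Convergence tolerances for the NLS are set to machine precision with a
  500-iteration cap; a noiseless profile is recovered to better than
  $10^{-6}$ relative across the admissible parameter space
  ($r \in [0.05, 3]$, $P \ne \delta$; property-tested).
* Ties on the earliest qualifying claim date are broken by claim id; the
  detected onset is invariant to records added after it.
* Degenerate profiles: months with $n < 2$ are flagged; profiles with
  fewer than 5 usable points (or lacking a pre-onset or two post-onset
  points) are rejected with an informative error; zero-variance months
  on noiseless data trigger the unweighted fallback.
* The $r = h$ branch of the closed-form forecast switches at
  $|r - h| < 10^{-9}$, continuous with the general branch to well below
  the quadrature tolerance.
* Default problem sizes in the test suite (up to 2,000 persons end to
  end, 200 replicate fits for calibration, 10,000 random record sets for
  the onset-rule oracle) were chosen to make the statistical checks
  sharp at interactive runtimes.

## Known limitations

The month binning uses calendar months, so onset day-of-month is ignored
(a claim three days before a mid-month onset still lands in $m = 0$).
The Charlson index is computed at the interview by default, not at
onset; a rolling 12-month window anchored at any index date is available
through `charlson_index()` directly. The forecast excludes mortality by
construction and should not be read as a Medicare budget projection.
Survey weights, multi-wave disability dynamics, and ICD-10 are out of
scope.

## A worked end-to-end run

```{r, eval = FALSE}
cfg <- sim_config(n_persons = 2000, seed = 1)
res <- run_pipeline(pipeline_config(simulation = cfg,
                                    strata = c("total", "survival"),
                                    out_dir = "out"))
res$estimates[res$estimates$stratum == "total",
              c("disease", "c", "P", "r", "delta", "chi2_per_df")]
plot_profiles(res$profiles, res$estimates)
```

The `estimates.csv` written by the run mirrors the structure of a
stratified results table (one row per disease and stratum, parameter
estimates with standard errors and $\chi^2/df$), and `forecast.csv`
tabulates $C_{tot}(x)$ with its three components for each disease under
its configured onset hazard.
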