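---
title: "Methods: a reduced kinetic model for virtual tamoxifen drug-holiday trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced kinetic model for virtual tamoxifen drug-holiday trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamoxtrial)
```

## The scientific question

Tamoxifen owes much of its anti-estrogenic effect to a secondary metabolite,
endoxifen, whose formation passes through the polymorphic enzyme CYP2D6.
Extensive metabolizers (EM) reach higher endoxifen steady-state trough
concentrations than intermediate (IM) or poor (PM) metabolizers on the same
20 mg/day dose. Because steady-state kinetics of the cascade take months to
develop, interruptions of intake ("drug holidays") and treatment starts both
leave patients below the effective endoxifen exposure for a long time, and a
fixed-dose combination of tamoxifen with a small oral endoxifen dose can
shorten that window dramatically. `tamoxtrial` implements a virtual clinical
trial quantifying these effects: 20 arms x 1000 virtual patients, crossing
phenotype (EM/IM), role (loading-dose case vs reference control) and drug
holidays of 0, 2, 4, 8 or 12 weeks.

## The kinetic model

The whole-body physiology behind the original analysis is deliberately
reduced here to the smallest linear structure that can reproduce the
trial-level observables: one central compartment per compound —
tamoxifen (TAM), N-desmethyltamoxifen (NDM), 4-hydroxytamoxifen (4OH),
endoxifen (END) — plus first-order oral depots for the two dosed compounds
(TAM and END). Writing amounts in mg, the state is

$$x = (a_\mathrm{TAM}, a_\mathrm{END}, A_\mathrm{TAM}, A_\mathrm{NDM},
A_\mathrm{4OH}, A_\mathrm{END})^\top, \qquad \dot x = K\,x + u(t),$$

where $u(t)$ is a train of instantaneous boluses into the depots and $K$ is
the 6x6 rate matrix assembled by `build_rate_matrix()`. The cascade follows
the standard tamoxifen pathway assignment: TAM&rarr;NDM and 4OH&rarr;END are
CYP3A4-mediated, TAM&rarr;4OH and NDM&rarr;END are CYP2D6-mediated. The
CYP2D6 genotype enters as a single activity multiplier $\theta$ on the two
CYP2D6-mediated formation clearances, with $\theta_{EM} = 1$ exactly and
$\theta_{EM} > \theta_{IM} > \theta_{PM} \ge 0$. Each of the two
endoxifen-forming branches therefore carries exactly one CYP2D6-gated step,
so endoxifen exposure from tamoxifen scales down smoothly with activity
while exposure from directly dosed endoxifen does not — the mechanism behind
genotype-specific fixed-dose combinations.

Assumptions worth stating explicitly:

* **Linearity.** All clearances are first order; there is no saturable
  metabolism, protein-binding state or drug–drug interaction. Consequently
  dose proportionality and superposition hold exactly, which the test suite
  exploits against closed-form (oral one-compartment Bateman curve) and
  numeric-ODE oracles.
* **Daily resolution.** Doses are instantaneous boluses once a day; troughs
  are sampled immediately before the next scheduled dose. No intra-day
  structure is analyzed.
* **Reduced disposition.** A single compartment per compound means no deep
  tissue reservoir. The consequences for post-holiday recovery times are
  analyzed below — this is the model's most important structural limitation.

Simulation between events uses the exact matrix-exponential propagator; for
an arm with daily dosing, the one-day propagator $e^{K}$ is computed once
per patient and the whole year is a sequence of matrix–vector products. An
independent path (`pk_simulate_ode()`) integrates the hand-written
right-hand side with `deSolve::lsoda` and event restarts; the two agree to
within $10^{-6}$ relative on randomized cases, and that agreement is part of
the acceptance suite.

## Virtual population

Inter-individual variability is multiplicative log-normal on all eight
clearances (one shared CV) and all four volumes (a second CV):
realized = typical $\times\,e^{\varepsilon}$,
$\varepsilon \sim N(-\sigma^2/2, \sigma^2)$, $\sigma^2 = \log(1+CV^2)$, so
the mean factor is exactly 1. Draws are independent across parameters and
patients; absorption constants and bioavailabilities are not varied; age and
body weight are not modeled (the typical set stands for the female reference
patient). The volume CV is fixed at 0.20, a conventional magnitude for
distribution volumes; the clearance CV is a calibration parameter pinned by
the published spread of the benchmark (its 25th percentile), and comes out
large — consistent with the wide endoxifen exposure distributions reported
clinically for CYP2D6 substrates.

What the generator deliberately does not emulate: parameter correlations
(no published information to constrain them), allele-level genotypes (only
the three phenotype classes), covariate effects, and stochastic per-patient
adherence (holidays are deterministic per arm). Passing tests therefore
demonstrate correct wiring of the declared variability model, not realism
of any particular correlation structure in real cohorts.

### Common random numbers

One population per phenotype is sampled from the run seed and shared by all
arms of that phenotype, and the benchmark cohort *is* the EM population.
This is a standard variance-reduction device for simulated trials: paired
comparisons (case vs control, holiday vs no holiday) are made on identical
patients, so arm contrasts are not polluted by resampling noise. It also
makes the EM reference arm approach the benchmark exactly, which keeps the
achievement rule below well defined. With independently redrawn populations
the median of an equalized arm lands a fraction of a percent above or below
the benchmark median by sampling luck alone, and near-asymptotic crossing
times become lottery tickets — a plausible origin for some irregularities
in the reference results discussed below.

## Trial design and crossing rules

Day 1 is the first dose day. The 6-month run-in is 168 days (24 weeks); a
holiday of $w$ weeks is exactly $7w$ dose-free days (169 through $168+7w$);
intake resumes on day $168 + 7w + 1$ and continues until 364 days of intake
are completed. Group A arms dose continuously for 364 days. Times to target
are counted with the first (or first post-holiday) dose day as day 1.

The target is the **benchmark endoxifen steady-state trough**: the median
over 1000 adherent EM patients of each patient's mean daily trough over the
final 28 simulated days (the 28-day window damps residual daily ripple; the
averaging window is a package choice). The asymmetric case/control rule is:

* **control** ("achieved"): first day $d$ with median trough
  $\ge (1-\epsilon) B$. An exact-equality reading is ill-posed — an
  equalized arm approaches its asymptote and never crosses it — so the
  package uses an achievement tolerance $\epsilon = 0.01$, the smallest
  round value that keeps the fitted half-lives well conditioned; the
  calibration absorbs $\epsilon$ into the kinetic parameters.
* **case** ("exceeded"): the day before the first day the median strictly
  exceeds $B$, taken literally with no smoothing of the median series.

Post-holiday control arms that have not achieved the benchmark by calendar
day 336 are censored in the summary table (reported "> limit"), mirroring
the reference convention; the acceptance script reports the un-truncated
crossing of the full simulated series instead, since the simulation itself
continues to the end of intake.

## Calibration

The source analysis publishes *outputs* (day counts, troughs, percentiles)
but none of the underlying kinetic parameters, so the shipped default set is
obtained by calibrating the reduced model against those outputs:

* **Free parameters:** the eight clearances, the endoxifen volume and
  bioavailability, $\theta_{IM}$, $\theta_{PM}$, and the clearance CV.
  Absorption constants, tamoxifen-side volumes and $F_{TAM}$ are fixed at
  literature-scale round values; they are structurally redundant with the
  free clearances for every anchored observable.
* **Anchors** (`anchor_targets()`): all sixteen attainable day-count cells,
  the three "exceeds 100 days" cells as one-sided bounds, the two 2-week
  holiday troughs (14.9 and 10.6 µg/L), the benchmark 25th percentile
  (13.8 µg/L), and the exposure-equalization premise of the fixed-dose
  combinations (the IM anchor carries a +2.5% margin so the equalized
  control arms cross their achievement threshold robustly).
* **Objective:** weighted sum of squared scaled residuals; day-count
  observables enter as continuous interpolated crossing times so the loss
  is smooth enough for derivative-free optimization.
* **Optimizer:** multistart Nelder-Mead on the log scale inside broad
  physiological bounds, polished from the best start; deterministic given
  the seed. A first pass fits the deterministic typical-patient trial to
  locate the kinetic geometry cheaply. Because the log-normal population
  with its mean-1 convention has strong composition effects at the fitted
  CV — the median trajectory of the mixture is not the typical patient's
  trajectory, and equalization margins shift by several percent — the
  sensitive subset ($\theta$'s, the NDM and END clearances, $ka_{END}$) is
  then re-optimized directly against full-population observables (n = 1000,
  the calibration seed, common random numbers, so the objective is
  deterministic), and finally the pure scale ($V_{END}$/$CL_{e,END}$
  jointly) is set against the EM trough anchor, which it hits exactly
  without touching the day-count geometry. The clearance CV is a blunter
  dial: moving it re-mixes the whole population and shifts near-asymptotic
  crossings by many days, so it is held at the value (0.80) where the
  day-count geometry survives; the benchmark 25th percentile then lands
  about 8% above its anchor, a compromise preferred over sacrificing
  several day-count cells, and reported as such by the release gate.

This circularity — calibrating on the same numbers the acceptance layer
checks — is intentional and declared: the paper-number layer verifies the
end-to-end wiring of schedule construction, trough extraction, benchmark
definition and the asymmetric crossing rule, not independent predictive
power. The calibration-independent properties (linearity, oracle agreement,
genotype ordering, holiday monotonicity, parameter recovery on synthetic
anchors) carry the scientific weight.

## A structural limitation, stated precisely

One reference cell cannot be reproduced by *any* linear time-invariant
reduction, regardless of parameter values. For a positive linear system, the
trajectory after a holiday equals the trajectory of a treatment-naive
patient plus the free decay of the retained state:
$y_{\text{holiday}}(t) = y_0(t) + y_{\text{free}}(t) \ge y_0(t)$.
A post-holiday control arm therefore reaches any threshold **no later** than
the from-zero control arm — yet the reference table reports the EM 2-week
holiday control at 126 days against 125 days for the from-zero EM control,
and censors the longer-holiday cells beyond day 336. Within this model
class the EM 2-week control recovery computes to roughly 100 days (the
crossing equations bound it near $t_0 - h\log_2\!\big(1/(1-2^{-14/h})\big)$
for slow half-life $h$, maximized around 100 days at the $h$ compatible with
the 125-day from-zero anchor), and the 4/8/12-week cells fall between that
value and 125 days — which still satisfies their published "exceeds 100
days" form. A whole-body model with a deep tissue reservoir decouples
accumulation from post-holiday recovery and can break the bound; a
one-compartment-per-compound surrogate cannot. The package reports its
honest computed value and flags the cell in the release gate rather than
bending other cells to chase it. (Under independently resampled populations
the reference's near-asymptotic EM crossings are noise-dominated, which
would also explain the pattern; see the common-random-numbers note above.)

The related self-inconsistency in the reference prose — a "54 day" speed-up
for IMs whose own endpoints differ by 64 days — is resolved by reporting
the computed difference only.

## Numerical choices

* Matrix exponentials via `Matrix::expm` (Ward's Padé); the rate matrix is
  lower triangular, and cohort propagation uses only its lower triangle.
* Percentiles use the default linear-interpolation convention (type 7) of
  `stats::quantile`; the median is the 50th percentile.
* Crossing detection on daily troughs; the calibration objective uses
  linear interpolation between days, the reported tables use whole days.
* Censoring is represented as "> limit" labels plus the numeric limit.
* Degenerate inputs: zero-CV populations collapse to the typical patient;
  zero-week holidays reproduce continuous protocols; `theta = 0` switches
  both CYP2D6 edges off exactly (and with it all endoxifen from tamoxifen).
* Seeds: every stochastic step takes an explicit integer seed; population
  draws restore the caller's RNG state.

## Problem sizes used by the tests

The unit tests run on compressed calendars (6-week run-in, 13-week intake)
and small cohorts (tens of patients), which exercise every code path in
seconds. The acceptance suite runs the full design once — 20 arms x 1000
patients x 364+ days plus the benchmark cohort, about half a minute — and a
50-patient replicate to bound Monte-Carlo movement of the day counts. The
parameter-recovery harness calibrates three free parameters on the
compressed calendar against anchors generated from a known set.

## Known limitations

* No deep-tissue compartment: post-holiday recovery of control arms is
  structurally tied to the from-zero accumulation time (see above).
* The population model is a two-CV log-normal without correlations; the
  fitted clearance CV absorbs all published spread into one dial.
* PM patients appear only through the equalization anchor; no PM arms are
  simulated in the trial proper.
* Times to target are medians of the arm; per-patient time-to-target
  distributions are out of scope.
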