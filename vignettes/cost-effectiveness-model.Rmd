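---
title: "A partitioned-survival cost-effectiveness model of third-line apatinib in metastatic gastric cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival cost-effectiveness model of third-line apatinib in metastatic gastric cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatinibCEA)
```

## The decision problem

Patients with metastatic gastric cancer who have failed two lines of
chemotherapy face a short life expectancy and, in China, a choice between
best supportive care and daily oral apatinib (850 mg), a VEGFR-2 inhibitor
that prolongs both progression-free survival (PFS) and overall survival
(OS) but is expensive. The payer question is whether a critical-illness
insurance scheme that reimburses 60% of medical charges should cover
apatinib, with or without the manufacturer's "3+X" patient assistance
programme (PAP), under which patients pay for the first three months of
drug and receive it free thereafter until progression. This package
implements the full decision model: survival extrapolation, a weekly
three-state cohort trace, discounted cost and QALY accrual, incremental
cost-effectiveness ratios (ICERs), deterministic and probabilistic
sensitivity analysis, and a five-year budget-impact projection.

## Model structure

The cohort model has three mutually exclusive states — progression-free,
progressed, and dead — with everyone entering progression-free. Although
the clinical course can be narrated as a Markov process, the model is
implemented as a *partitioned-survival* ("area under the curve") model:
state occupancy at the start of cycle $k$ (time $t_k$) is read directly
off the two survival functions,

$$\text{PFS}_k = S_{PFS}(t_k), \qquad
  \text{dead}_k = 1 - S_{OS}(t_k), \qquad
  \text{PD}_k = S_{OS}(t_k) - S_{PFS}(t_k),$$

which is the standard construction when only published PFS and OS curves
are available (no transition-level data exist to identify a true
transition matrix). If a hazard-ratio combination makes the PFS curve
cross above the OS curve, the progressed compartment is clamped at zero
(and PFS occupancy capped at $S_{OS}$) with a warning; this preserves row
conservation, which is enforced to $10^{-9}$ at every cycle.

Cycles are one week long ("short life expectancy" makes weekly resolution
worthwhile), a year is exactly 52 weeks, and the horizon is 10 years = 520
cycles, effectively lifetime for this population. Costs and QALYs are
discounted at 5%/year via $(1+r)^{-k/52}$.

### Discretisation

State membership is evaluated at cycle start, with no half-cycle
correction. This is a deliberate reproduction choice: the published
outcome table is matched almost exactly by cycle-start left sums
(discounted control disease-free life-years 0.173), whereas half-cycle
correction shifts every life-year total down by about half a week
(~0.0096 LY) and away from the published values. The cost of the choice
is a known upward discretisation bias of the same half-week relative to
the continuous-time integral of the survival curve — about 2% of
undiscounted life expectancy here. The test suite asserts the honest
sandwich bound (quadrature $\le$ left sum $\le$ quadrature + one cycle)
rather than pretending the bias away.

## Survival inputs

The control arm's PFS and OS are Weibull,
$S(t) = \exp(-\lambda t^\gamma)$ with $t$ in weeks, using published scale
and shape values (PFS: $\lambda = 0.04191$, $\gamma = 1.4165$; OS:
$\lambda = 0.02143$, $\gamma = 1.18716$), which imply median PFS ~8.1
weeks and median OS ~18.7 weeks — the short survival typical of
chemotherapy-refractory disease.

`fit_weibull()` reproduces the curve-fitting step for synthetic or
digitised Kaplan–Meier points: unweighted least squares of
$\ln(-\ln S)$ on $\ln t$, whose slope and intercept are the shape and log
scale. The estimation method behind the published parameters is not
reported; the complementary log-log regression is chosen because it is the
classical closed-form fit and makes the reported $r^2$ diagnostic
well-defined. Maximum-likelihood fitting of individual-level data is out
of scope. Points at survival exactly 0 or 1 are undefined on the cloglog
scale and dropped with a warning.

Apatinib's effect enters through pooled hazard ratios (PFS 0.34, OS 0.57)
applied as $S_{active}(t) = S_{ref}(t)^{HR}$ — for a Weibull this
multiplies the scale and keeps the shape. `pool_hazard_ratios()`
implements the fixed-effect inverse-variance meta-analysis on the log-HR
scale (via `metafor`); with only two source trials a random-effects model
is not identifiable, so fixed-effect is the minimal defensible choice.
The standard error of each log HR is derived from its printed 95% CI as
$(\ln hi - \ln lo)/(2 \times 1.96)$ unless an explicit SE is supplied.
The printed intervals deserve a caveat: the point estimates (0.34, 0.57)
sit at or below the lower ends of their intervals (0.27–0.595,
0.537–0.937, the latter labelled "96%"), which is internally inconsistent.
The base case uses the point estimates verbatim and the intervals only to
set sampling dispersion; see the PSA discussion below for the consequence.

## Costs and utilities

All charges are in US dollars; the payer reimburses
`coverage_fraction` (60%) of every charge. Per cycle the payer cost is

$$c_k = \text{cov} \times \big[\, \text{PFS}_k (d_k + s^{pfs}) +
  \text{PD}_k \, s + \Delta\text{dead}_k \, e \,\big] \times
  (1+r)^{-k/52},$$

where $d_k$ is the weekly drug charge (zero for control; zero after the
13th cycle under the 3+X programme, since 3 months = 13 weekly cycles),
$s$ = \$117.1 supportive care per cycle, and $e$ = \$1483.9 end-of-life
palliative care charged once at the cycle of incident death (the timing
matching a separate "death cost" row in the published breakdown).
$s^{pfs}$ is supportive care in the progression-free state: charged in the
control arm, and by default *not* alongside apatinib (the source is silent
on concomitant supportive care during active treatment); the flag
`pfs_supportive_with_drug` flips that convention.

The apatinib price input is "\$106.5 per 425 mg" with 850 mg taken daily.
Read literally (two 425 mg units/day) the weekly drug charge would be
\$1491 and the incremental cost of full-price apatinib ~\$16.7k — twice
the published \$7859. Read as \$106.5 per treatment-day, the weekly charge
is \$745.5 and the model reproduces the published totals (increment
\$7958, ICER \$40.7k vs published \$41.0k). The packaged configuration
therefore sets `drug_charge_basis: per_day`, with `per_unit` available for
users who prefer the literal reading; this back-calculation from the
published totals is the only evidence either way.

Utilities are 0.88 progression-free and 0.41 progressed, applied as
occupancy weights in the QALY sum. No adverse-event costs or disutilities
are modelled (the source trials reported similar severe-adverse-event
frequencies in both arms).

Base case, from `run_base_case()`: control 0.463 LYs / 0.271 QALYs /
\$2561; apatinib 0.729 LYs / 0.467 QALYs; incremental cost \$7958 at full
price (ICER \$40,691/QALY) and \$4436 with 3+X PAP (ICER \$22,683/QALY),
against a willingness-to-pay threshold of \$22,200/QALY (three times 2015
Chinese per-capita GDP).

## Sensitivity analysis

**One-way (tornado).** Each parameter moves to its declared bounds with
everything else at base, and the 3+X-vs-control ICER is recomputed
(`one_way_sensitivity()`). Cost and utility bounds are the published
ranges; hazard-ratio bounds are their 95% CIs; the coverage fraction,
published without a range, uses ±25% of base (0.45–0.75), the convention
the source states for unranged parameters. Entries are sorted by
descending span with alphabetical tie-breaks. In this implementation the
OS hazard ratio, apatinib price and coverage fraction dominate; the
end-of-life cost is immaterial.

**Probabilistic (PSA).** `run_psa()` draws joint parameter samples and
reruns the full model per draw: triangular distributions for the three
cost parameters (low/mode/high = low/median/high of the published range —
note the apatinib-price triangle has its mode at the upper bound, so most
draws price the drug *below* base), beta for utilities and the coverage
proportion (method of moments, mean = base value, SD = range/4), and
lognormal for the hazard ratios (median at the point estimate, SD of the
log equal to the CI-derived SE). Parameters are sampled independently; a
parameter whose distribution cannot be resolved (zero-width range,
infeasible beta moments) is held at base with a message. All draws are
reproducible from one integer seed.

`ceac()` converts the draws to cost-effectiveness acceptability curves:
at each willingness-to-pay, the fraction of draws in which the strategy's
net monetary benefit ($WTP \times QALYs - cost$) exceeds the
comparator's. At \$22,200/QALY this model gives roughly a 78% probability
that 3+X apatinib is cost-effective and ~7% at full price — more
favourable than the ~65%/~0% of the original report. The discrepancy
traces to the hazard-ratio intervals noted above: centring the lognormals
on the point estimates (as here) makes effect draws systematically
stronger than centring them on the intervals' midpoints (which would give
~47%); the original analysis also sampled survival-curve parameters whose
standard errors were never published, adding dispersion this
implementation cannot reproduce. The base case and tornado are unaffected
by this choice.

## Budget impact

`project_budget()` is a deliberately simple eligible-pool projection for
a one-million-person region: incidence 215.5 gastric-cancer cases per
million per year (the source prints "21.55 per 1,000,000" in one place
and "~215 cases per million" in another; the latter is consistent with
national incidence statistics and is adopted), two-thirds advanced, an
assumed 70% reaching third-line treatment, and uptake 80% in fiscal year
1 then 100%. Each treated patient costs the payer the per-patient
incremental cost of 3+X apatinib over control from the cohort engine
(~\$4.4k). That yields ~\$0.36M in year 1 plateauing at ~\$0.45M/year,
inside the \$0.34–0.45M band of the original report, whose own figures
are mutually inconsistent and whose eligibility funnel is unstated — the
funnel fractions are therefore exposed as configuration, not asserted as
facts. Budget streams are conventionally undiscounted and no dynamic
prevalence pool or market-share competition is modelled.

## Synthetic data

Because no patient-level data are deposited, `simulate_cohort()`,
`km_estimate()` and `simulate_trial_hr()` generate the two kinds of
inputs the survival machinery consumes: (i) censored event times drawn
from a Weibull curve (inverse-transform via `rweibull`, independent
exponential censoring) summarised into Kaplan–Meier points
(`survival::survfit`, deaths before censorings at ties) on a 2-weekly
grid truncated at the 95th percentile of observed times — mimicking
points read off a published curve while avoiding the unstable tail; and
(ii) trial-level log hazard ratios drawn normal around a true value with
the large-sample SE $\sqrt{1/d_1 + 1/d_2}$. These emulate sampling noise
and administrative censoring but not digitisation error, informative
censoring, or non-proportional hazards, so recovery tests certify the
fitting and pooling code, not the published curves themselves. Recovery
is within ~15% of the generating parameters at $n = 500$ and ~5% at
$n = 5000$.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite quick while leaving
Monte-Carlo margins wide: 520-cycle traces everywhere, 1000 PSA draws for
headline probabilities, 25–40 draws in plumbing tests, $n = 500/5000$ in
recovery tests. Known limitations: the discretisation bias discussed
above; independence of all PSA draws (no correlation structure is
published); utilities sampled independently can very rarely invert
$u_{pfs} > u_{pd}$; and every monetary result inherits the per-day price
interpretation, which is a reconstruction, not a sourced fact.
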