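---
title: "Modelling headache care pathways and the value of eConsult triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling headache care pathways and the value of eConsult triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients presenting to primary care with headaches who need a specialist
opinion face very long neurology waitlists — in Alberta, observed waits of
12–18 months. An asynchronous eConsult service changes the shape of that
queue: instead of booking a 30–45 minute in-person appointment for every
referral, a consenting patient completes a structured intake whose generated
report a specialist reviews in about ten minutes. Most reviews end in an
approved treatment plan without any in-person visit, so the same specialist
workforce resolves far more referrals per day. `headsim` is a discrete event
simulation (DES) of these pathways with a health-economic layer, built to
estimate what the eConsult step does to specialist-assessment wait times,
costs, quality-adjusted life-years (QALYs), and net monetary benefit (NMB),
at an early stage of the technology's development when direct evidence is
scarce.

## Model structure

Patients arrive at primary care in continuous time with exponential
interarrival times. Each is assigned a headache type (migraine, tension-type,
cluster, or secondary headache) and a baseline severity expressed as monthly
headache days (MHD). Every patient enters *not effectively managed* (NEM).

* **Non-referred patients** (primary headaches are referred with probability
  0.02; secondary headaches always) become *effectively managed* (EM) at
  primary care with probability `p_effective_primary_care`, otherwise they
  remain NEM and generate recurring primary-care and emergency-department
  visits as Poisson processes until the horizon.
* **Referred patients** join a single first-come-first-served specialist
  waitlist served by `n_neurologists x frac_headache_neurologists` parallel
  specialists during working hours (weekdays, 8:00–16:00, with
  `frac_headache_visits` of the workday available to this patient stream).
  Service times are gamma distributed.
* **Under the standard of care (SOC)** the queued episode is an in-person
  assessment; completing it makes the patient EM.
* **Under the intervention (LASOO_SOC)** a referred patient consents to the
  eConsult with probability 0.75. A consenter's queued episode is the
  specialist *review* of the intake report — much shorter than an
  appointment. The review's outcome is approval (EM without an in-person
  visit), a request for more information (a fixed delay, then one re-review,
  which cannot ask again), or a request for an in-person visit (a new
  in-person episode joins the waitlist). Non-consenters follow the SOC
  branch.

Becoming EM multiplies MHD — and, proportionally, the missed-workday accrual
— by `1 - effectiveness`, and stops further NEM revisits. MHD is otherwise
constant: the only MHD dynamic in the model is the treatment effect.

Two structural choices deserve emphasis:

* **No priority between episode kinds.** Reviews and in-person visits share
  one FIFO queue ordered by arrival. This is deliberately conservative: in
  practice eConsult turnarounds are days, not months, which would require
  specialists to fit reviews outside booked clinic time. Keeping both
  strategies on identical work calendars isolates the capacity effect of the
  technology itself from any assumption about extra specialist effort. The
  intervention helps *because short reviews drain the same queue faster*,
  not because reviews jump it.
* **The work-hours calendar.** Queueing runs on a "work clock" that
  accumulates only during service windows; calendar time maps to the clock
  by a closed-form conversion, so an out-of-hours referral is first
  serviceable at the next window opening. A service episode that does not
  finish inside a window pauses and resumes next morning.

## Parameters

The configuration (YAML, `inst/extdata/base_params.yaml`) is the single
source of truth; every field is validated at load time (probabilities in
[0, 1] and summing to one, a utility map non-increasing in MHD, positive
gamma parameters, and so on). Values stated directly in the published model
description are set exactly: referral rates 2%/100%, consent 75%, about 100
neurologists of whom half assess headaches, 15 patients per specialist-day
with half the visits being headache assessments, weekday 8–16h working
hours, 30–45 minute appointments, a 1.5% annual discount rate, a
willingness-to-pay of CAD 50,000/QALY (USD conversion 0.7048), a horizon of
1,826.25 days, and 50 replications. The full supplementary parameter table
of the source analysis is not available to this package, so the remaining
values are assumptions chosen once from the ranges the publication's text
points to, flagged `assumed` in the configuration's provenance block:

* *Headache type mix* (55/32/5/8%): a clinic-style distribution keeping
  secondary headaches under 10% of presentations.
* *MHD distributions*: gamma per type (means 12/8/15/10 days/month,
  truncated at 30.4375), giving a population mean near 10.4.
* *Service times*: gamma with mean 37.5 min and shape 68, placing roughly
  90% of appointments inside the stated 30–45 minute range; eConsult reviews
  gamma with mean 10 min (shape 25), consistent with reported eConsult
  review effort and with the intake report arriving pre-structured.
* *eConsult outcomes*: approve 90%, more information 5%, in-person 5%
  ("very rarely" in the source's wording); the re-review delay is 7 days.
* *Effective management at primary care*: 30% of non-referred patients
  (most stay NEM, per the source's description).
* *NEM revisits*: 4 PCP visits and 0.5 ED visits per patient-year.
* *Costs (CAD)*: PCP visit 85, ED visit 580, specialist visit 250, eConsult
  review fee 68, effective treatment 1,200/year (a mix of inexpensive acute
  and prophylactic regimens; the model deliberately does not represent
  specific drugs).
* *Productivity*: missed workdays accrue at `0.5 x MHD / 30.4375` per
  calendar day (capped by 250 workdays/year) at a daily wage of CAD 250.
* *Utilities*: a piecewise-linear map from MHD knots (0.90 at 0 MHD down to
  0.51 at 30.4 MHD), interpolated linearly and clamped with a warning
  outside its domain; utilities are type-independent.
* *Calibration target*: 548 days (18 months), the upper end of the observed
  Alberta range, with a 10-day tolerance; the Alberta headache population
  used for scaling is 3.0 million patients over the 5-year span.

## Calibration

The arrival rate is the calibration variable: all else fixed, it is tuned
until the SOC mean wait matches the target. The objective at each candidate
rate is the mean over `reps_per_eval` replications run with *the same seeds
at every candidate* (common random numbers), which makes the objective
smooth and the whole search deterministic given a seed; the search is
geometric bracketing (with a monotonicity check: the averaged wait must not
decrease as the rate rises beyond three combined standard errors) followed
by bisection. The fitted base-case rate, 5,704.8 patients/day, puts the
in-person queue well above capacity — the regime the observed waits imply —
so the waitlist grows over the horizon and mean waits are dominated by
queueing, not service time. On an M/M/1 toy configuration the procedure
recovers the analytically inverted arrival rate within 5%.

## Economics

All costs are in CAD. Discounting is continuous, `(1 + r)^(-t/365.25)`, with
exact closed-form integrals for accruals; an annual-step variant is
available via `discount_method` (the continuous form avoids period-boundary
artifacts in a continuous-time DES). Visit costs are charged at event times;
recurring NEM visit costs use the expected discount factor of a uniformly
placed visit over the NEM window (the order-statistics property of the
Poisson process), which is an exact conditional expectation given the visit
count and removes needless Monte-Carlo noise. Treatment cost accrues from
the start of effective management to the horizon. Productivity losses are
missed workdays times the daily wage and are discounted by default
(`discount_productivity = FALSE` turns that off; the source analysis does
not state its choice, and treating them as costs argues for discounting).
QALYs integrate the MHD-dependent utility over each patient's time in the
model. The societal perspective includes productivity losses in the total;
the healthcare perspective reports but excludes them. Identities the test
suite enforces exactly: cost decomposition sums to the total, healthcare =
societal − productivity per patient, `iNMB = WTP x dQALY − dCost`, and zero
discounting reproduces undiscounted sums.

## Replication design and randomness

Each replication draws every patient attribute — arrival, type, MHD,
referral/consent/outcome uniforms, in-person and review service times, and
the uniforms behind revisit counts — from a single stream seeded *before*
any strategy-dependent branching. Both strategies replay the identical
attribute block, so they are coupled patient-by-patient (common random
numbers): with consent 0 the intervention arm is bitwise-identical to SOC,
and estimated differences have far smaller variance than independent runs
(a property the suite tests directly). Revisit counts on windows that
depend on the strategy use the Poisson quantile function on per-patient
uniforms, preserving the coupling monotonically. Replication `k` of either
strategy uses seed `(base_seed + 1000003 k) mod (2^31 - 1) + 1`.

Waits are censored at the horizon: a patient still unresolved contributes
the elapsed wait from referral, and censored counts are always reported.
This matches continuous patient entry over a fixed horizon — each patient
spends a different time in the model — and avoids survivorship bias toward
the fast-served; the complete-case alternative is one filter away in the
per-patient table.

## Validation against queueing theory

The fixture generator includes toy configurations that collapse the pathway
to an M/M/c queue (everyone referred, nobody consents, exponential service,
24/7 calendar). On c in {1, 2, 4} and utilization in {0.5, 0.75, 0.9}, the
simulated post-warm-up mean queue wait must fall within the Monte-Carlo 95%
confidence interval of the Erlang-C closed form, and the time-averaged
queue length must satisfy Little's law. These oracles pin the engine's
queueing core independently of any health-economic content.

## Problem sizes

A calibrated base-case replication simulates roughly 10.4 million patient
arrivals over the 5 years (about one million referrals through the queue);
one replication simulates and summarizes in tens of seconds. The shipped analysis scripts use
10 paired replications for the base case, 5 per scenario, and 3 per
threshold grid point; the test suite and the acceptance script use smaller
replication counts (1–3) chosen as a deliberate precision/runtime trade-off
— with common random numbers the *differences* between strategies are
estimated far more precisely than the strategy levels themselves, and the
reported Monte-Carlo standard errors make the residual noise visible.

## What the synthetic configuration does and does not show

The generator's defaults emulate the published study's stated conditions
plus documented assumptions for its supplementary-only values. Passing
tests therefore demonstrate the *mechanics* — queue physics, censoring,
economic identities, calibration, monotone responses, and the direction of
the intervention's effect under every scenario — not the calibration of
Alberta's real system: with the true supplementary parameter values the
printed magnitudes (e.g. per-patient total cost, proportion EM at horizon)
would shift. Real headache care also has features the model deliberately
omits, following the source analysis: no-shows, triage priority for
eConsult-reviewed patients, over-the-counter medication costs, treatment
nonadherence, type-dependent utilities, and any implementation cost of the
eConsult platform itself (its absence favours the intervention). Results
should be read as an early-stage assessment of mechanism and direction, not
as a fitted forecast.

## Known limitations

* The overloaded-queue regime means wait-time results depend on the horizon
  (waits grow over time); the 5-year horizon is itself a modelling choice
  tied to holding capacity fixed.
* Secondary headaches reaching specialists are treated like primary ones for
  queueing and treatment-effect purposes; only their referral rate differs.
* The intake questionnaire's diagnostic quality is not modelled; the
  eConsult outcome mix is a flat categorical distribution.
* The more-information pathway is a single re-review after a fixed delay; no
  repeated loops.
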