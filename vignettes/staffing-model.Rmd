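---
title: "The psocap staffing model: assumptions, calibration, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The psocap staffing model: assumptions, calibration, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(psocap)
```

`psocap` implements the CAPO staffing framework for psychosocial oncology
(PSO) disciplines as a deterministic demand–capacity model. This vignette is
the package's account of that model: what it assumes, which parameters matter
and why they hold their default values, the numerical conventions, where the
design was genuinely open, and what the validation machinery does and does not
establish.

## The model in one pass

For one 1.0 FTE position, capacity is computed in a fixed order:

$$
H_{\mathrm{net}} = H_{\mathrm{gross}} - \sum_k D_k,\qquad
H_{\mathrm{DPC}} = f_{\mathrm{DPC}}\, H_{\mathrm{net}}
$$

Group work and the carryover caseload are treated as fixed commitments and
subtracted first, because both are obligations the position inherits before
any new individual referral is booked:

$$
R = H_{\mathrm{DPC}} - H_{\mathrm{groups}} - H_{\mathrm{carryover}}
$$

The remainder is split between counseling/psychotherapy and instrumental
(advocacy/navigation) work by the hour fractions $f_c$ and $1-f_c$, and
patient counts are floors — fractional patients are not served:

$$
n_c = \left\lfloor \frac{f_c R}{h_c} \right\rfloor,\qquad
n_i = \left\lfloor \frac{(1-f_c)R}{h_i} \right\rfloor
$$

New-patient capacity is $n_g + n_c + n_i$ (group enrollment plus the two
individual streams); the unique caseload adds carryover patients; direct
patient-care contacts (DPCCs) sum the per-stream visit counts. Demand-side,
expected referrals are `round(cases x rate)` and the staffing ratio is
`round2(referrals / capacity)`. Program totals scale the per-FTE figures by
the 2-decimal ratio, because that is the number a planning table prints and a
budget approves.

## Parameters and defaults

The packaged profiles (`default_profile()`) describe a generalist social
worker in an outpatient tertiary cancer center.

| parameter | default | units | rationale |
|---|---|---|---|
| weekly hours / weeks | 37.5 / 52 | h, wk | standard Canadian hospital full-time position |
| vacation, stat, sick, education | 20, 11, 10, 5 | days | typical tertiary-center collective-agreement allowances |
| daily breaks | 0 | h | paid breaks counted as work; unpaid lunch sits outside the 7.5 h day |
| DPC fraction | 0.75 (alt 0.70) | — | outpatient/academic programs carry heavier indirect loads than the 80/20 hospital norm |
| groups | 3 x (8 h prep + 7 sess x 2 h), 8 patients | — | closed therapeutic groups repeated through the year |
| carryover | 60 (75/25) or 56 (70/30), 4 h / 4 contacts | patients | ≈20% of prior-year caseload; 1 h per appointment |
| counseling | 70% of remaining hours, 6.5 h / 6 visits | — | 1.5 h assessment + five 1 h follow-ups; six visits is an average |
| instrumental | 30%, 3 h / 3 visits | — | assessment plus two follow-ups for complex practical concerns |
| referral rate | 0.35 | — | minimum prevalence of distress warranting specialized care; 1.0 models automatic-referral clinics |

With these values the model yields, per 1.0 FTE: net 1605 h, DPC 1203.75 h,
and the published capacity figures —

```{r}
glance(compute_capacity(default_profile("capo2022_sw_tertiary_75_25")))
glance(compute_capacity(default_profile("capo2022_sw_tertiary_70_30")))
```

### How the defaults were calibrated

The framework's published materials state the headline inputs (35% referral
rate, 75/25 and 70/30 splits, three groups of eight, 20% carryover at 4 h per
patient, six counseling visits on average) and the outputs (209/60/269/1251
per FTE at 75/25; 196/56/252/1175 at 70/30), but not every intermediate
worksheet value. The remaining parameters — the exact leave-day counts behind
net hours, group preparation and session time, and the per-patient hour costs
— were calibrated so that the model reproduces *both* published panels
simultaneously under the exact 70/30 hour split. That system is tightly
over-determined and admits essentially one clean solution: net 1605 h, 66
group hours, counseling at 6.5 h over 6 visits, instrumental at 3 h over 3
visits. (A flat 6 h counseling cost, for instance, cannot reproduce both
panels with any whole-hour instrumental cost.) The contact decomposition of
the 1251 total — 168 group + 240 carryover + 576 counseling + 267
instrumental — pins the visit counts uniquely.

## Numerical conventions

* **Half-up rounding.** Planning tables round half away from zero
  (`round_half_up()`); base R's banker's rounding would print 8.37 FTE as
  8.37 but 2251.53 unique cases as 2252 only by accident of parity. A
  6-decimal pre-round absorbs binary representation error in decimal products
  (`7.10 * 1175` is stored a hair under 8342.5 but must round to 8343).
* **Guarded floors.** Patient-count floors treat values within 5e-10 of an
  integer as that integer, so `0.2 x 280` yields 56 carryover patients, not
  55.
* **Full-precision hours.** Hours are never rounded mid-pipeline; only
  patient and contact counts are integers. Unallocated remainder hours are
  reported as `slack_hours` (bounded by $h_c + h_i$, one floor remainder per
  stream), never dropped silently.
* **Degenerate inputs.** Calendars whose deductions reach gross hours,
  profiles whose fixed commitments exceed DPC hours, and zero capacity at
  positive demand are errors that name the shortfall, not NaNs.

## Design choices that were genuinely open

* **Order of subtraction.** Groups and carryover are deducted before the
  intervention split. They are prior commitments — the group calendar is
  scheduled and carryover patients already exist — while the counseling/
  instrumental split governs only genuinely free hours. The published totals
  are consistent with this ordering.
* **Carryover modes.** The 20%-of-prior-caseload rule and the explicit counts
  in the published worksheets cannot be reconciled exactly (20% of no printed
  caseload figure equals 60), so `carryover_policy()` supports both; the
  packaged defaults use the explicit counts (60 / 56) with the 20% rate and a
  consistent base (300 / 280) retained as provenance.
* **Split sweeps co-scale carryover.** `sweep_parameter()` over
  `split.dpc_fraction` rescales the carryover volume by the DPC ratio: in
  steady state the prior-year caseload is proportional to direct-care hours,
  and that coupling is exactly what relates the published 75/25 panel
  (carryover 60) to the 70/30 panel (56). Sweeping the split with carryover
  frozen would understate the alternative panel's capacity (193 vs 196).
* **Group work is not a capacity drain.** Removing group work frees hours for
  individual care, but *total* new-patient capacity falls: a group serves 8
  patients per facilitated hour, so group time is denser per patient (66 h
  for 24 patients, ~2.75 h each) than individual care (~4.8 h per patient).
  The tests assert this direction rather than the intuitive-but-wrong
  opposite.
* **Published-table inconsistencies are flagged, not imitated.** One cell of
  the 75/25 panel (6000 cases, program unique cases) prints 2704 where every
  consistent rounding rule gives 2703; the 70/30 panel's FTE ratios beyond
  the 2000-case row are not `round2(referrals/capacity)` (e.g. 5.40 printed
  vs 5.36 computed), though its program totals are consistent with the
  printed ratios. `compare_with_published()` reports these cells; the model
  keeps its single consistent rule. Whether the 70/30 deviations stem from a
  different capacity figure or ad-hoc rounding is not determinable, so the
  package does not guess.
* **Units.** Hours and days only; minutes are not modelled. Appointment
  length does not vary by modality (in-person, telephone, virtual).

## The stochastic validator

`simulate_year()` checks the deterministic formula against a stochastic
referral stream rather than trusting the algebra:

* Arrivals are a homogeneous Poisson count with annual mean
  `expected_referrals()`. Quarter-to-quarter fluctuations are assumed to
  balance out over a fiscal year, so a stationary process is the faithful
  null model; no seasonality is imposed.
* Each referral is counseling or instrumental with probabilities proportional
  to `hour_fraction / hours_per_patient` — the patients-per-hour weighting
  under which the expected share of service *hours* per stream equals the
  profile's 70/30 mix.
* Patients are served first-come-first-served against `fte x` the
  intervention hours the deterministic model commits (counseling plus
  instrumental `hours_used`, i.e. net of groups, carryover, and floor slack);
  a referral is served only if its full per-patient hours fit. Unserved
  demand is counted, not queued into the next year — carryover is already a
  profile parameter, and queueing it again would double-count.
* Group and carryover commitments are honored deterministically; the group
  enrollment enters as the fte-scaled annual figure so replicate means are
  unbiased.

Under saturation the replicate mean of new patients served converges to
`fte x new_patient_capacity` (law of large numbers); at 500 replicates the
agreement test passes within three standard errors of the replicate
distribution. Reports are bit-identical for a fixed seed, and the caller's
RNG stream is left untouched.

```{r}
sim <- simulate_year(default_profile(), demand_spec(2000), fte = 3.35,
  seed = 20220101, replicates = 200)
glance(sim)
```

## Synthetic workload logs

`generate_contact_log()` emits a fiscal year of per-contact records shaped
like a workload-measurement export (patient, contact type, duration, ISO
date, provider, open/closed status), with per-block counts equal to the
capacity result scaled by FTE; `aggregate_contact_log()` inverts it. The
carryover counting rule is the framework's: a case counts as carryover only
if it opened in a prior fiscal year *and* receives at least one contact in
the focal year — open files never seen again are excluded. The fiscal year
start is configurable (April 1 default, January 1 supported).

What the generator emulates is the *accounting structure* of real workload
data, which is exactly what the aggregation and round-trip tests need. It
does not emulate referral seasonality, within-patient variation in visit
counts or session lengths, no-shows, or multi-provider sharing of a patient —
so passing round-trip tests validate the bookkeeping, not any behavioral
model of a clinic.

## Problem sizes and limitations

Every computation here is desk-scale: the deterministic model is a handful of
arithmetic operations, the test suite's property checks run tens of
randomized profiles, and the simulation tests use up to 500 replicates of a
~700-arrival year — seconds on one CPU.

Limitations worth keeping in view:

* The model is a generalist-practice average. Specialized clinics (stem-cell
  transplant, head and neck, palliative) need higher per-patient time and may
  use a 100% referral rate; both are profile parameters, but no per-diagnosis
  acuity weighting exists.
* No within-year scheduling or queueing: the model balances annual volumes,
  not waiting times.
* Carryover is a planning figure, not a patient-level projection.
* Credentialing and scope-of-practice (which discipline may deliver
  psychotherapy where) are carried only as free-text `notes` metadata.
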