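# psocap

Demand–capacity planning for psychosocial oncology (PSO) and supportive-care
programs, implementing the Canadian Association of Psychosocial Oncology
(CAPO) staffing framework as a reusable, parameterized engine.

Cancer programs rarely have a transparent way to answer "how many social
workers (or psychologists, dietitians, spiritual care practitioners, ...) does
a program seeing *N* new cancer cases a year need?" `psocap` answers it the
way the CAPO framework does: start from the actual paid hours of one
full-time-equivalent (FTE) position, account explicitly for how those hours
are spent, and divide projected referral demand by the resulting per-FTE
caseload capacity. It is written for program administrators, PSO clinical
leads, and health-services researchers who need staffing ratios they can
defend line by line.

## The model

For one 1.0 FTE position in one discipline:

1. **Net hours** — gross paid hours (`weekly_hours x weeks_per_year`) minus
   vacation, statutory holidays, designated sick and education days, and
   daily breaks on worked days. Disability and unpaid leaves are excluded by
   design. Default calendar: 37.5 h/wk x 52 wk − 46 days x 7.5 h = **1605 h**.
2. **DPC/IPC split** — net hours divide into direct patient care (DPC) and
   indirect patient care (IPC); tertiary outpatient programs typically run
   75/25 or 70/30.
3. **Fixed commitments** — therapeutic group work
   (`groups x (prep + sessions x facilitation)` hours) and the carryover
   caseload from the previous fiscal year (≈20% of the prior caseload, 4 h and
   4 one-hour contacts per patient) come off the DPC hours first.
4. **Intervention mix** — remaining DPC hours split 70/30 between
   counseling/psychotherapy (6.5 h, 6 visits per patient) and complex
   instrumental/advocacy work (3 h, 3 visits). Patient counts are floors;
   remainders are reported as slack.
5. **Demand → FTE** — expected referrals = `round(new_cases x referral_rate)`
   (minimum planning rate 35%, the prevalence of distress warranting
   specialized care); `FTE = round2(referrals / per-FTE capacity)`; program
   totals scale the per-FTE caseload and contact counts by that ratio.

All rounding is half-up (`round_half_up()`), the convention of the published
planning tables.

## Worked example

```r
library(psocap)

p <- default_profile("capo2022_sw_tertiary_75_25")
compute_capacity(p)
#> <psocap_capacity> social work, tertiary center, 75% DPC, per 1.0 FTE/yr
#>   net hours 1605.00 = DPC 1203.75 + IPC 401.25
#>   groups      :  66.00 h,  24 patients,  168 contacts
#>   carryover   : 240.00 h,  60 patients,  240 contacts
#>   counseling  : 624.00 h,  96 patients,  576 contacts
#>   instrumental: 267.00 h,  89 patients,  267 contacts
#>   new patients 209 | total unique 269 | DPCCs 1251 | slack 6.75 h
```

One social worker at 75% DPC who runs three therapeutic groups a year can
take **209 new patients**, carries **60 patients** over from last year
(**269 unique patients** total), and delivers **1251 direct-patient-care
contacts** (DPCCs). Staffing a 4000-case tertiary center:

```r
fte_plan(p, demand_spec(4000, referral_rate = 0.35))
#> <psocap_plan> social work, tertiary center (75% DPC)
#>   4000 new cases @ 35% -> 1400 referrals / 209 per FTE = 6.70 FTE
#>   program totals: 1802 unique cases, 8382 DPCCs
```

Planning tables, sensitivity sweeps, a stochastic validator of the
deterministic formula, and synthetic workload logs:

```r
build_table(seq(2000, 6000, 1000), p)            # staffing-ratio table, columns a-i
sweep_parameter(p, "split.dpc_fraction", c(0.75, 0.70))  # FTE 3.35 vs 3.57 @ 2000 cases
simulate_year(p, demand_spec(2000), fte = 3.35)  # Poisson referral stream, FCFS service
log <- generate_contact_log(p, fte = 1, seed = 42)
aggregate_contact_log(log)                       # recovers 269 patients / 1251 contacts
```

Profiles round-trip through YAML/JSON (`read_profile()` / `write_profile()`;
JSON-Schema in `inst/extdata/profile-schema.json`), and a command-line front
end ships in `inst/cli/psocap`.

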