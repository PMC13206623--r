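test_that("split_dpc is an exact linear split with no rounding", {
  expect_equal(
    split_dpc(1000, care_split(0.80)),
    c(dpc_hours = 800, ipc_hours = 200)
  )
  expect_equal(
    split_dpc(1000, care_split(1.00)),
    c(dpc_hours = 1000, ipc_hours = 0)
  )
  # default net hours at 75%: fractional hours carried forward
  sp <- split_dpc(1605, default_profile()$split)
  expect_equal(sp[["dpc_hours"]], 1203.75)
  expect_equal(sum(sp), 1605)
})

test_that("group_block computes provider hours, enrollment, and per-attendance contacts", {
  expect_equal(
    group_block(group_program()),
    c(hours = 0, unique_patients = 0, contacts = 0)
  )
  g <- group_block(default_profile()$groups)
  expect_equal(g[["unique_patients"]], 24) # 3 groups x 8 participants
  expect_equal(g[["contacts"]], 168) # every attendee per session counts
  expect_equal(g[["hours"]], 3 * (8 + 7 * 2))
})

test_that("carryover_block supports explicit counts and rate-of-base", {
  expect_equal(
    carryover_block(carryover_policy("explicit_count",
      explicit_count = 60,
      hours_per_patient = 4, contacts_per_patient = 4
    )),
    c(patients = 60, hours = 240, contacts = 240)
  )
  expect_equal(
    carryover_block(carryover_policy("explicit_count", explicit_count = 0)),
    c(patients = 0, hours = 0, contacts = 0)
  )
  expect_equal(
    carryover_block(carryover_policy("rate_of_base",
      rate = 0.20,
      base_caseload = 300
    )),
    c(patients = 60, hours = 240, contacts = 240)
  )
  # non-integer products floor to whole patients
  expect_equal(
    carryover_block(carryover_policy("rate_of_base",
      rate = 0.20,
      base_caseload = 299
    ))[["patients"]],
    59
  )
})

test_that("allocate_interventions floors patients and accounts every hour", {
  zero <- allocate_interventions(0, default_profile()$mix)
  expect_equal(zero$counseling[["unique_patients"]], 0)
  expect_equal(zero$instrumental[["unique_patients"]], 0)

  exact <- allocate_interventions(600, intervention_mix(1.0, 6, 6, 3, 3))
  expect_equal(
    exact$counseling,
    c(hours_available = 600, unique_patients = 100, hours_used = 600, contacts = 600)
  )
  expect_equal(exact$instrumental[["unique_patients"]], 0)

  # remaining hours of the packaged 75/25 default: 1203.75 - 66 - 240 = 897.75
  iv <- allocate_interventions(897.75, default_profile()$mix)
  expect_equal(iv$counseling[["unique_patients"]], 96)
  expect_equal(iv$instrumental[["unique_patients"]], 89)
  expect_equal(iv$counseling[["contacts"]], 576)
  expect_equal(iv$instrumental[["contacts"]], 267)
})

test_that("compute_capacity reproduces the published worked example on both defaults", {
  cap <- compute_capacity(default_profile("capo2022_sw_tertiary_75_25"))
  expect_equal(cap$new_patient_capacity, 209)
  expect_equal(cap$carryover_block[["patients"]], 60)
  expect_equal(cap$total_unique_caseload, 269)
  expect_equal(cap$total_dpcc, 1251)
  # the contact decomposition behind the 1251 total
  expect_equal(
    tidy(cap)$contacts,
    c(168, 240, 576, 267)
  )

  cap70 <- compute_capacity(default_profile("capo2022_sw_tertiary_70_30"))
  expect_equal(cap70$new_patient_capacity, 196)
  expect_equal(cap70$total_unique_caseload, 252)
  expect_equal(cap70$total_dpcc, 1175)
})

test_that("dropping group work frees hours for more individual patients", {
  p <- default_profile()
  p_nogroups <- p
  p_nogroups$groups <- group_program(0, 0, 0, 0, 0)
  cap <- compute_capacity(p)
  cap0 <- compute_capacity(p_nogroups)
  individual <- function(x) {
    x$counseling_block[["unique_patients"]] +
      x$instrumental_block[["unique_patients"]]
  }
  expect_gt(individual(cap0), individual(cap))
  expect_equal(cap0$group_block[["unique_patients"]], 0)
  # note: *total* new-patient capacity is lower without groups under the
  # default profile — a group serves 8 patients per session hour, so group
  # time is denser per patient than individual care (66 h for 24 patients
  # vs about 4.8 h per individual patient)
  expect_lt(cap0$new_patient_capacity, cap$new_patient_capacity)
})

test_that("infeasible profiles error with the shortfall named", {
  p <- default_profile()
  p$carryover <- carryover_policy("explicit_count",
    explicit_count = 5000,
    hours_per_patient = 4, contacts_per_patient = 4
  )
  expect_error(compute_capacity(p), "exceed DPC hours",
    class = "psocap_infeasible_profile"
  )
})

test_that("capacity ledger identities hold on randomized profiles", {
  set.seed(7113)
  for (i in 1:20) {
    p <- random_profile()
    cap <- compute_capacity(p)
    net <- cap$hours_ledger$net_available_hours
    expect_equal(cap$dpc_hours + cap$ipc_hours, net)
    expect_equal(
      cap$new_patient_capacity,
      cap$group_block[["unique_patients"]] +
        cap$counseling_block[["unique_patients"]] +
        cap$instrumental_block[["unique_patients"]]
    )
    expect_equal(
      cap$total_unique_caseload,
      cap$new_patient_capacity + cap$carryover_block[["patients"]]
    )
    expect_equal(
      cap$total_dpcc,
      cap$group_block[["contacts"]] + cap$carryover_block[["contacts"]] +
        cap$counseling_block[["contacts"]] +
        cap$instrumental_block[["contacts"]]
    )
    expect_equal(
      cap$slack_hours,
      cap$dpc_hours - cap$group_block[["hours"]] -
        cap$carryover_block[["hours"]] -
        cap$counseling_block[["hours_used"]] -
        cap$instrumental_block[["hours_used"]]
    )
    expect_gte(cap$slack_hours, 0)
    # one floor remainder per stream: slack < h_counseling + h_instrumental
    expect_lt(
      cap$slack_hours,
      p$mix$counseling_hours_per_patient + p$mix$instrumental_hours_per_patient
    )
  }
})

test_that("floored patient counts match a one-at-a-time brute-force oracle", {
  brute_force_patients <- function(available, hours_per_patient) {
    served <- 0
    used <- 0
    while (used + hours_per_patient <= available) {
      served <- served + 1
      used <- used + hours_per_patient
    }
    served
  }
  set.seed(90210)
  for (i in 1:20) {
    p <- random_profile()
    cap <- compute_capacity(p)
    expect_equal(
      cap$counseling_block[["unique_patients"]],
      brute_force_patients(
        cap$counseling_block[["hours_available"]],
        p$mix$counseling_hours_per_patient
      )
    )
    expect_equal(
      cap$instrumental_block[["unique_patients"]],
      brute_force_patients(
        cap$instrumental_block[["hours_available"]],
        p$mix$instrumental_hours_per_patient
      )
    )
  }
})

test_that("capacity is monotone in the planning levers", {
  p <- default_profile()
  newcap <- function(prof) compute_capacity(prof)$new_patient_capacity
  p_lower_dpc <- p
  p_lower_dpc$split <- care_split(0.70)
  expect_lte(newcap(p_lower_dpc), newcap(p))
  p_slower <- p
  p_slower$mix <- intervention_mix(0.70, 12, 6, 3, 3)
  expect_lt(newcap(p_slower), newcap(p))
  p_longer <- p
  p_longer$calendar <- work_calendar(40, 52,
    vacation_days = 20,
    statutory_holiday_days = 11, sick_days = 10, education_days = 5,
    hours_per_workday = 8
  )
  expect_gte(newcap(p_longer), newcap(p))
})
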