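test_that("a generated log aggregates back to the generating capacity", {
  p <- default_profile()
  log <- generate_contact_log(p, fte = 1, seed = 42)
  expect_equal(nrow(log), 1251)
  expect_true(all(log$duration > 0))

  fy0 <- as.Date("2025-04-01")
  expect_true(all(log$date >= fy0 & log$date < fy0 + 366))

  agg <- aggregate_contact_log(log)
  expect_equal(agg$unique_patients, 269)
  expect_equal(agg$total_contacts, 1251)
  expect_equal(agg$carryover_cases, 60)
  expect_equal(agg$contacts_group_session, 168)
  expect_equal(agg$contacts_carryover_followup, 240)
  # 96 counseling + 89 instrumental assessments
  expect_equal(agg$contacts_assessment, 185)
  expect_equal(agg$contacts_counseling_followup, 96 * 5)
  expect_equal(agg$contacts_instrumental, 89 * 2)
})

test_that("log volume is linear in FTE by construction", {
  p <- default_profile()
  a1 <- aggregate_contact_log(generate_contact_log(p, fte = 1, seed = 7))
  a2 <- aggregate_contact_log(generate_contact_log(p, fte = 2, seed = 7))
  for (col in names(a1)) {
    expect_equal(a2[[col]], 2 * a1[[col]])
  }
})

test_that("round-trip holds across seeds and randomized profiles", {
  set.seed(5150)
  for (i in 1:5) {
    p <- random_profile()
    cap <- compute_capacity(p)
    seed <- sample.int(10000, 1)
    agg <- aggregate_contact_log(generate_contact_log(p, fte = 1, seed = seed))
    expect_equal(agg$unique_patients, cap$total_unique_caseload)
    expect_equal(agg$total_contacts, cap$total_dpcc)
    expect_equal(agg$carryover_cases, cap$carryover_block[["patients"]])
  }
})

test_that("generation is deterministic per seed and rejects fte <= 0", {
  p <- default_profile()
  expect_identical(
    generate_contact_log(p, fte = 1, seed = 3),
    generate_contact_log(p, fte = 1, seed = 3)
  )
  expect_error(generate_contact_log(p, fte = 0), "fte",
    class = "psocap_validation_error"
  )
})

test_that("assessments precede follow-up contacts within each patient", {
  log <- generate_contact_log(default_profile(), fte = 1, seed = 13)
  firsts <- log |>
    dplyr::group_by(patient_id) |>
    dplyr::slice_min(date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  individual <- firsts[grepl("^(CNS|INS)", firsts$patient_id), ]
  expect_true(all(individual$contact_type == "assessment"))
})

test_that("empty logs aggregate to zero", {
  agg <- aggregate_contact_log(generate_contact_log(
    staffing_profile(
      discipline = "social work", setting = "tertiary",
      calendar = work_calendar(37.5, 52, hours_per_workday = 7.5),
      split = care_split(0.8),
      groups = group_program(),
      carryover = carryover_policy("explicit_count", explicit_count = 0),
      mix = intervention_mix(
        counseling_hours_fraction = 1,
        counseling_hours_per_patient = 1e9
      )
    ),
    fte = 1, seed = 1
  ))
  expect_equal(agg$unique_patients, 0)
  expect_equal(agg$total_contacts, 0)
  expect_equal(agg$carryover_cases, 0)
})

test_that("carryover counts only prior-year cases seen again in the focal year", {
  fy0 <- as.Date("2025-04-01")
  log <- tibble::tibble(
    patient_id = c("A", "A", "B", "C", "C"),
    contact_type = c(
      "assessment", "counseling_followup", # A: opened and seen pre-FY only
      "carryover_followup", # B: continuing file seen in FY
      "assessment", "counseling_followup" # C: new case within FY
    ),
    duration = 1,
    date = as.Date(c(
      "2025-02-10", "2025-03-20", # A: both before Apr 1
      "2025-06-01", # B: inside FY
      "2025-05-05", "2025-06-05" # C: inside FY
    )),
    provider_id = "PSO-01",
    case_status = c("open", "open", "open", "open", "open")
  )
  agg <- aggregate_contact_log(log, fiscal_year_start = fy0)
  expect_equal(agg$carryover_cases, 1) # only B
  expect_equal(agg$unique_patients, 2) # B and C have focal-year contacts
  # a patient with pre-FY history AND a focal-year contact is carryover too
  log2 <- dplyr::bind_rows(log, tibble::tibble(
    patient_id = "A", contact_type = "counseling_followup", duration = 1,
    date = as.Date("2025-07-01"), provider_id = "PSO-01", case_status = "open"
  ))
  expect_equal(aggregate_contact_log(log2, fiscal_year_start = fy0)$carryover_cases, 2)
})

test_that("malformed records raise row-level validation errors", {
  log <- generate_contact_log(default_profile(), fte = 1, seed = 2)
  bad <- log
  bad$duration[5] <- -1
  expect_error(aggregate_contact_log(bad), "Row 5",
    class = "psocap_validation_error"
  )
  bad2 <- log
  bad2$contact_type[3] <- "espresso"
  expect_error(aggregate_contact_log(bad2), "Row 3",
    class = "psocap_validation_error"
  )
})

test_that("contact logs round-trip through CSV", {
  log <- generate_contact_log(default_profile(), fte = 1, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_contact_log(log, f)
  back <- read_contact_log(f)
  expect_equal(as.data.frame(back), as.data.frame(log))
  expect_equal(
    aggregate_contact_log(back),
    aggregate_contact_log(log)
  )
})
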