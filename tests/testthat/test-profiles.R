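test_that("constructors enforce field bounds with informative errors", {
  expect_error(care_split(1.3), "dpc_fraction", class = "psocap_validation_error")
  expect_error(care_split(0), "dpc_fraction", class = "psocap_validation_error")
  expect_error(
    work_calendar(weekly_hours = -1),
    "weekly_hours",
    class = "psocap_validation_error"
  )
  expect_error(
    intervention_mix(counseling_hours_fraction = 1.1),
    "counseling_hours_fraction",
    class = "psocap_validation_error"
  )
  expect_error(
    carryover_policy("rate_of_base", rate = 0.2),
    "base_caseload",
    class = "psocap_config_error"
  )
  expect_error(
    carryover_policy(rate = 1),
    "rate",
    class = "psocap_validation_error"
  )
})

test_that("packaged defaults are registered, validate, and reproduce printed capacity", {
  expect_setequal(
    default_profile_names(),
    c("capo2022_sw_tertiary_75_25", "capo2022_sw_tertiary_70_30")
  )
  expect_error(default_profile("nonexistent"),
    "capo2022_sw_tertiary_75_25",
    class = "psocap_lookup_error"
  )

  p75 <- default_profile("capo2022_sw_tertiary_75_25")
  expect_identical(p75$split$dpc_fraction, 0.75)
  expect_identical(p75$groups$groups_per_year, 3)
  expect_identical(p75$carryover$hours_per_patient, 4)
  cap75 <- compute_capacity(p75)
  expect_identical(
    c(
      cap75$new_patient_capacity, cap75$carryover_block[["patients"]],
      cap75$total_unique_caseload, cap75$total_dpcc
    ),
    c(209, 60, 269, 1251)
  )

  cap70 <- compute_capacity(default_profile("capo2022_sw_tertiary_70_30"))
  expect_identical(
    c(
      cap70$new_patient_capacity, cap70$carryover_block[["patients"]],
      cap70$total_unique_caseload, cap70$total_dpcc
    ),
    c(196, 56, 252, 1175)
  )
})

test_that("the two defaults differ only in the split and split-dependent fields", {
  a <- default_profile("capo2022_sw_tertiary_75_25")
  b <- default_profile("capo2022_sw_tertiary_70_30")
  expect_identical(a$calendar, b$calendar)
  expect_identical(a$groups, b$groups)
  expect_identical(a$mix, b$mix)
  expect_identical(a$discipline, b$discipline)
  expect_false(a$split$dpc_fraction == b$split$dpc_fraction)
  # carryover differs only in count/base, not in the per-patient policy
  expect_identical(a$carryover$hours_per_patient, b$carryover$hours_per_patient)
  expect_identical(
    a$carryover$contacts_per_patient,
    b$carryover$contacts_per_patient
  )
  expect_identical(a$carryover$rate, b$carryover$rate)
  expect_false(a$carryover$explicit_count == b$carryover$explicit_count)
})

test_that("profiles round-trip losslessly through YAML and JSON", {
  p <- default_profile()
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_profile(p, f)
    expect_equal(read_profile(f), p)
  }
  # round-trip identity at the file level (modulo key order): rewrite of a
  # reread file is byte-identical
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_profile(p, f1)
  write_profile(read_profile(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("round-trip holds for randomized valid profiles", {
  set.seed(4021)
  for (i in 1:15) {
    p <- random_profile()
    f <- withr::local_tempfile(fileext = sample(c(".yaml", ".json"), 1))
    write_profile(p, f)
    expect_equal(read_profile(f), p)
  }
})

test_that("strict schema: unknown, missing and out-of-range fields are rejected", {
  p <- default_profile()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_profile(p, f)

  x <- yaml::read_yaml(f)
  x$surprise <- 1
  f_extra <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f_extra)
  expect_error(read_profile(f_extra), "surprise", class = "psocap_schema_error")

  x <- yaml::read_yaml(f)
  x$calendar$weekly_hours <- NULL
  f_missing <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f_missing)
  expect_error(read_profile(f_missing), "weekly_hours",
    class = "psocap_schema_error"
  )

  x <- yaml::read_yaml(f)
  x$split$dpc_fraction <- 1.3
  f_range <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f_range)
  expect_error(read_profile(f_range), "dpc_fraction",
    class = "psocap_validation_error"
  )

  x <- yaml::read_yaml(f)
  x$schema_version <- 99
  f_ver <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f_ver)
  expect_error(read_profile(f_ver), "schema_version",
    class = "psocap_schema_error"
  )

  expect_error(read_profile(tempfile(fileext = ".yaml")),
    "not found",
    class = "psocap_config_error"
  )
})
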