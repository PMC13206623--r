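capo2022_sw_tertiary <- function(dpc_fraction, carryover_count, carryover_base) {
  staffing_profile(
    discipline = "social work",
    setting = "tertiary",
    calendar = work_calendar(
      weekly_hours = 37.5,
      weeks_per_year = 52,
      vacation_days = 20,
      statutory_holiday_days = 11,
      sick_days = 10,
      education_days = 5,
      daily_break_hours = 0,
      hours_per_workday = 7.5
    ),
    split = care_split(dpc_fraction),
    groups = group_program(
      groups_per_year = 3,
      sessions_per_group = 7,
      participants_per_group = 8,
      prep_hours_per_group = 8,
      facilitation_hours_per_session = 2
    ),
    carryover = carryover_policy(
      mode = "explicit_count",
      explicit_count = carryover_count,
      rate = 0.20,
      base_caseload = carryover_base,
      hours_per_patient = 4,
      contacts_per_patient = 4
    ),
    mix = intervention_mix(
      counseling_hours_fraction = 0.70,
      counseling_hours_per_patient = 6.5,
      counseling_contacts_per_patient = 6,
      instrumental_hours_per_patient = 3,
      instrumental_contacts_per_patient = 3
    ),
    notes = paste(
      "CAPO 2022 staffing-framework defaults for a generalist social worker in",
      "an outpatient tertiary cancer center. Counseling time is a 1.5 h",
      "assessment plus five 1 h follow-ups (six visits per patient on average);",
      "instrumental/advocacy cases take an assessment plus two follow-ups at",
      "1 h each. The carryover count is the explicit framework figure; the 20%",
      "rate and prior-year base are retained as provenance."
    )
  )
}

profile_registry <- function() {
  list(
    capo2022_sw_tertiary_75_25 = function() capo2022_sw_tertiary(0.75, 60, 300),
    capo2022_sw_tertiary_70_30 = function() capo2022_sw_tertiary(0.70, 56, 280)
  )
}

#' Packaged default staffing profiles
#'
#' Returns one of the packaged CAPO-2022 social-work tertiary-center profiles.
#' `"capo2022_sw_tertiary_75_25"` (75% DPC / 25% IPC, three therapeutic groups)
#' reproduces the published per-FTE capacity of 209 new patients, 60 carryover,
#' 269 total unique patients and 1251 direct-patient-care contacts;
#' `"capo2022_sw_tertiary_70_30"` (70% DPC / 30% IPC) reproduces 196 / 56 /
#' 252 / 1175. The two differ only in the DPC fraction and the
#' split-dependent carryover figures.
#'
#' @param name Registered profile name; see [default_profile_names()].
#' @return A [staffing_profile()] object.
#' @examples
#' p <- default_profile("capo2022_sw_tertiary_75_25")
#' compute_capacity(p)
#' @export
default_profile <- function(name = "capo2022_sw_tertiary_75_25") {
  check_string(name, "name")
  reg <- profile_registry()
  if (!name %in% names(reg)) {
    abort(
      sprintf(
        "Unknown default profile \"%s\". Registered names: %s.",
        name, paste(names(reg), collapse = ", ")
      ),
      class = "psocap_lookup_error"
    )
  }
  reg[[name]]()
}

#' @rdname default_profile
#' @export
default_profile_names <- function() {
  names(profile_registry())
}
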