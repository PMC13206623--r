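PROFILE_SCHEMA_VERSION <- 1L

#' Work-hours calendar of one full-time position
#'
#' Describes the paid-hours structure of a 1.0 FTE position for one fiscal
#' year: gross weekly hours and the categories of paid time that are *not*
#' available for work (vacation, statutory holidays, designated sick days,
#' education days, daily breaks). Short- and long-term disability and unpaid
#' leaves are deliberately not fields: they fall outside the predictable time
#' off of an average employee and are never deducted.
#'
#' @param weekly_hours Paid hours per week (> 0).
#' @param weeks_per_year Paid weeks per year (> 0).
#' @param vacation_days Vacation days per year (>= 0).
#' @param statutory_holiday_days Statutory holidays per year (>= 0).
#' @param sick_days Designated sick days per year (>= 0).
#' @param education_days Education days per year (>= 0).
#' @param daily_break_hours Paid break hours deducted per *worked* day (>= 0).
#'   Use 0 when breaks are counted as work time (the packaged default: the
#'   unpaid lunch already sits outside the 7.5-hour day).
#' @param hours_per_workday Length of one workday in hours (> 0). Days-per-week
#'   is derived as `weekly_hours / hours_per_workday` and may be fractional for
#'   part-time calendars.
#' @return A `psocap_calendar` object (named list).
#' @seealso [net_annual_hours()]
#' @examples
#' work_calendar(
#'   weekly_hours = 37.5, weeks_per_year = 52, vacation_days = 20,
#'   statutory_holiday_days = 11, sick_days = 10, education_days = 5,
#'   daily_break_hours = 0, hours_per_workday = 7.5
#' )
#' @export
work_calendar <- function(weekly_hours = 37.5,
                          weeks_per_year = 52,
                          vacation_days = 0,
                          statutory_holiday_days = 0,
                          sick_days = 0,
                          education_days = 0,
                          daily_break_hours = 0,
                          hours_per_workday = 7.5) {
  check_number(weekly_hours, "weekly_hours", lower = 0, closed_lower = FALSE)
  check_number(weeks_per_year, "weeks_per_year", lower = 0, closed_lower = FALSE)
  check_number(vacation_days, "vacation_days", lower = 0)
  check_number(statutory_holiday_days, "statutory_holiday_days", lower = 0)
  check_number(sick_days, "sick_days", lower = 0)
  check_number(education_days, "education_days", lower = 0)
  check_number(daily_break_hours, "daily_break_hours", lower = 0)
  check_number(hours_per_workday, "hours_per_workday", lower = 0, closed_lower = FALSE)
  cal <- structure(
    list(
      weekly_hours = weekly_hours,
      weeks_per_year = weeks_per_year,
      vacation_days = vacation_days,
      statutory_holiday_days = statutory_holiday_days,
      sick_days = sick_days,
      education_days = education_days,
      daily_break_hours = daily_break_hours,
      hours_per_workday = hours_per_workday
    ),
    class = "psocap_calendar"
  )
  # fail early on infeasible calendars (total deductions >= gross paid hours)
  net_annual_hours(cal)
  cal
}

#' Direct vs indirect patient-care split
#'
#' Direct patient care (DPC) covers everything required to deliver the service
#' to a patient: chart review, sessions, documentation, advocacy,
#' consultations. Indirect patient care (IPC) covers meetings, rounds, workload
#' data entry, program development, teaching, research. The IPC fraction is
#' always the complement `1 - dpc_fraction`.
#'
#' @param dpc_fraction Proportion of net work hours spent on DPC, in (0, 1].
#'   Hospital settings commonly use 0.80; outpatient or academic programs with
#'   heavier indirect responsibilities use 0.75 or 0.70.
#' @return A `psocap_split` object.
#' @export
care_split <- function(dpc_fraction) {
  check_number(dpc_fraction, "dpc_fraction",
    lower = 0, upper = 1,
    closed_lower = FALSE
  )
  structure(list(dpc_fraction = dpc_fraction), class = "psocap_split")
}

#' Therapeutic group-work program
#'
#' Closed therapeutic groups run over multiple weekly sessions and repeat
#' during the fiscal year. The provider's time cost is preparation per group
#' plus facilitation per session; every attendee at every session counts as
#' one direct-patient-care contact for workload measurement.
#'
#' @param groups_per_year Groups run per fiscal year (>= 0). With 0 groups all
#'   group outputs are zero and the freed hours absorb more individual patients.
#' @param sessions_per_group Sessions per group (>= 0).
#' @param participants_per_group Patients enrolled per group (>= 0).
#' @param prep_hours_per_group Preparation hours per group (>= 0).
#' @param facilitation_hours_per_session Facilitation hours per session (>= 0).
#' @return A `psocap_groups` object.
#' @export
group_program <- function(groups_per_year = 0,
                          sessions_per_group = 0,
                          participants_per_group = 0,
                          prep_hours_per_group = 0,
                          facilitation_hours_per_session = 0) {
  check_number(groups_per_year, "groups_per_year", lower = 0)
  check_number(sessions_per_group, "sessions_per_group", lower = 0)
  check_number(participants_per_group, "participants_per_group", lower = 0)
  check_number(prep_hours_per_group, "prep_hours_per_group", lower = 0)
  check_number(
    facilitation_hours_per_session,
    "facilitation_hours_per_session",
    lower = 0
  )
  structure(
    list(
      groups_per_year = groups_per_year,
      sessions_per_group = sessions_per_group,
      participants_per_group = participants_per_group,
      prep_hours_per_group = prep_hours_per_group,
      facilitation_hours_per_session = facilitation_hours_per_session
    ),
    class = "psocap_groups"
  )
}

#' Carryover caseload policy
#'
#' Patients whose files opened in a prior fiscal year and who receive at least
#' one contact in the new fiscal year form the carryover caseload. The
#' framework's planning rule is that carryover amounts to about 20% of the
#' prior-year caseload, each carryover patient requiring 4 hours of service at
#' 1 hour per appointment. Two modes are supported: an explicit patient count
#' (authoritative for the packaged defaults) or a rate applied to a stated
#' prior-year base caseload, `floor(rate * base_caseload)`.
#'
#' @param mode `"explicit_count"` or `"rate_of_base"`.
#' @param explicit_count Carryover patients (>= 0); consulted only in
#'   `explicit_count` mode.
#' @param rate Proportion in \[0, 1); consulted only in `rate_of_base` mode.
#'   Retained as provenance on the packaged defaults (0.20).
#' @param base_caseload Prior-year total caseload the rate applies to (>= 0);
#'   required in `rate_of_base` mode.
#' @param hours_per_patient Service hours per carryover patient (> 0).
#' @param contacts_per_patient Contacts per carryover patient (> 0). At 1 hour
#'   per appointment, 4 hours imply 4 contacts.
#' @return A `psocap_carryover` object.
#' @export
carryover_policy <- function(mode = c("explicit_count", "rate_of_base"),
                             explicit_count = 0,
                             rate = 0,
                             base_caseload = NA_real_,
                             hours_per_patient = 4,
                             contacts_per_patient = 4) {
  mode <- match.arg(mode)
  check_number(explicit_count, "explicit_count", lower = 0)
  check_number(rate, "rate", lower = 0, upper = 1, closed_upper = FALSE)
  if (mode == "rate_of_base") {
    if (is.na(base_caseload)) {
      abort("`base_caseload` is required when mode = \"rate_of_base\".",
        class = "psocap_config_error"
      )
    }
    check_number(base_caseload, "base_caseload", lower = 0)
  } else if (!is.na(base_caseload)) {
    check_number(base_caseload, "base_caseload", lower = 0)
  }
  check_number(hours_per_patient, "hours_per_patient",
    lower = 0,
    closed_lower = FALSE
  )
  check_number(contacts_per_patient, "contacts_per_patient",
    lower = 0,
    closed_lower = FALSE
  )
  structure(
    list(
      mode = mode,
      explicit_count = explicit_count,
      rate = rate,
      base_caseload = base_caseload,
      hours_per_patient = hours_per_patient,
      contacts_per_patient = contacts_per_patient
    ),
    class = "psocap_carryover"
  )
}

#' Intervention time mix: counseling vs instrumental work
#'
#' After group work and carryover commitments, the remaining direct-care hours
#' are split between counseling/psychotherapy and complex instrumental
#' concerns (advocacy and navigation for medication coverage, finances,
#' equipment, travel). Each stream has a per-patient time cost and visit
#' count; the instrumental hour share is always `1 - counseling_hours_fraction`.
#'
#' @param counseling_hours_fraction Share of remaining DPC hours allocated to
#'   counseling/psychotherapy, in \[0, 1\].
#' @param counseling_hours_per_patient Hours per counseling patient (> 0). The
#'   packaged default is 6.5: a 1.5-hour assessment plus five 1-hour follow-ups,
#'   an average of six visits per patient.
#' @param counseling_contacts_per_patient Visits per counseling patient (> 0).
#' @param instrumental_hours_per_patient Hours per instrumental patient (> 0);
#'   default profile uses 3 (assessment plus two follow-ups at 1 hour each).
#' @param instrumental_contacts_per_patient Visits per instrumental patient
#'   (> 0).
#' @return A `psocap_mix` object.
#' @export
intervention_mix <- function(counseling_hours_fraction = 0.70,
                             counseling_hours_per_patient = 6.5,
                             counseling_contacts_per_patient = 6,
                             instrumental_hours_per_patient = 3,
                             instrumental_contacts_per_patient = 3) {
  check_number(
    counseling_hours_fraction, "counseling_hours_fraction",
    lower = 0, upper = 1
  )
  check_number(counseling_hours_per_patient, "counseling_hours_per_patient",
    lower = 0,
    closed_lower = FALSE
  )
  check_number(
    counseling_contacts_per_patient, "counseling_contacts_per_patient",
    lower = 0,
    closed_lower = FALSE
  )
  check_number(instrumental_hours_per_patient, "instrumental_hours_per_patient",
    lower = 0,
    closed_lower = FALSE
  )
  check_number(
    instrumental_contacts_per_patient, "instrumental_contacts_per_patient",
    lower = 0,
    closed_lower = FALSE
  )
  structure(
    list(
      counseling_hours_fraction = counseling_hours_fraction,
      counseling_hours_per_patient = counseling_hours_per_patient,
      counseling_contacts_per_patient = counseling_contacts_per_patient,
      instrumental_hours_per_patient = instrumental_hours_per_patient,
      instrumental_contacts_per_patient = instrumental_contacts_per_patient
    ),
    class = "psocap_mix"
  )
}

#' Assemble a complete discipline staffing profile
#'
#' Bundles every parameter the capacity model consumes for one discipline in
#' one setting: the work calendar, the DPC/IPC split, the group-work program,
#' the carryover policy, and the intervention mix, plus free-text metadata
#' (setting, hiring/scope notes).
#'
#' @param discipline Discipline label, e.g. `"social work"`.
#' @param setting One of `"tertiary"`, `"regional"`, `"community"`, `"other"`.
#' @param calendar A [work_calendar()].
#' @param split A [care_split()].
#' @param groups A [group_program()].
#' @param carryover A [carryover_policy()].
#' @param mix An [intervention_mix()].
#' @param notes Free-text metadata (program setting, scope of practice,
#'   credentialing context). Not used in any computation.
#' @return A `psocap_profile` object.
#' @seealso [default_profile()], [read_profile()], [compute_capacity()]
#' @export
staffing_profile <- function(discipline,
                             setting = c("tertiary", "regional", "community", "other"),
                             calendar,
                             split,
                             groups = group_program(),
                             carryover = carryover_policy(),
                             mix = intervention_mix(),
                             notes = "") {
  check_string(discipline, "discipline")
  setting <- match.arg(setting)
  stopifnot(
    inherits(calendar, "psocap_calendar"),
    inherits(split, "psocap_split"),
    inherits(groups, "psocap_groups"),
    inherits(carryover, "psocap_carryover"),
    inherits(mix, "psocap_mix")
  )
  check_string(notes, "notes")
  structure(
    list(
      schema_version = PROFILE_SCHEMA_VERSION,
      discipline = discipline,
      setting = setting,
      calendar = calendar,
      split = split,
      groups = groups,
      carryover = carryover,
      mix = mix,
      notes = notes
    ),
    class = "psocap_profile"
  )
}

#' @export
print.psocap_profile <- function(x, ...) {
  cat(sprintf(
    "<psocap_profile> %s (%s center), schema v%d\n",
    x$discipline, x$setting, x$schema_version
  ))
  cat(sprintf(
    "  calendar : %.1f h/wk x %g wk; %g vac + %g stat + %g sick + %g edu days\n",
    x$calendar$weekly_hours, x$calendar$weeks_per_year, x$calendar$vacation_days,
    x$calendar$statutory_holiday_days, x$calendar$sick_days,
    x$calendar$education_days
  ))
  cat(sprintf(
    "  split    : %.0f%% DPC / %.0f%% IPC\n",
    100 * x$split$dpc_fraction, 100 * (1 - x$split$dpc_fraction)
  ))
  cat(sprintf(
    "  groups   : %g/yr x %g sessions x %g participants\n",
    x$groups$groups_per_year, x$groups$sessions_per_group,
    x$groups$participants_per_group
  ))
  co <- if (x$carryover$mode == "explicit_count") {
    sprintf("%g patients (explicit)", x$carryover$explicit_count)
  } else {
    sprintf(
      "%.0f%% of %g prior-year cases", 100 * x$carryover$rate,
      x$carryover$base_caseload
    )
  }
  cat(sprintf(
    "  carryover: %s @ %g h / %g contacts each\n", co,
    x$carryover$hours_per_patient, x$carryover$contacts_per_patient
  ))
  cat(sprintf(
    "  mix      : %.0f%% counseling (%g h, %g visits) / %.0f%% instrumental (%g h, %g visits)\n",
    100 * x$mix$counseling_hours_fraction, x$mix$counseling_hours_per_patient,
    x$mix$counseling_contacts_per_patient,
    100 * (1 - x$mix$counseling_hours_fraction),
    x$mix$instrumental_hours_per_patient, x$mix$instrumental_contacts_per_patient
  ))
  invisible(x)
}
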