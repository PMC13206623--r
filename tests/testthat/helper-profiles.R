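# Randomized-but-valid generators for property-style tests. Values live on a
# coarse grid (multiples of 0.25 h / whole days / 0.05 fractions) so that
# serialized round-trips are representation-exact and feasibility is easy to
# keep.

random_calendar <- function() {
  hours_per_workday <- sample(c(7, 7.5, 8), 1)
  days_per_week <- sample(3:5, 1)
  work_calendar(
    weekly_hours = hours_per_workday * days_per_week,
    weeks_per_year = 52,
    vacation_days = sample(0:25, 1),
    statutory_holiday_days = sample(0:12, 1),
    sick_days = sample(0:12, 1),
    education_days = sample(0:6, 1),
    daily_break_hours = sample(c(0, 0.25, 0.5), 1),
    hours_per_workday = hours_per_workday
  )
}

random_profile <- function(max_tries = 50) {
  for (i in seq_len(max_tries)) {
    prof <- try(
      staffing_profile(
        discipline = "social work",
        setting = sample(c("tertiary", "regional", "community"), 1),
        calendar = random_calendar(),
        split = care_split(sample(seq(0.55, 0.9, by = 0.05), 1)),
        groups = group_program(
          groups_per_year = sample(0:4, 1),
          sessions_per_group = sample(4:8, 1),
          participants_per_group = sample(6:10, 1),
          prep_hours_per_group = sample(c(4, 6, 8), 1),
          facilitation_hours_per_session = sample(c(1, 1.5, 2), 1)
        ),
        carryover = carryover_policy(
          mode = sample(c("explicit_count", "rate_of_base"), 1),
          explicit_count = sample(20:70, 1),
          rate = sample(c(0.1, 0.15, 0.2, 0.25), 1),
          base_caseload = sample(150:350, 1),
          hours_per_patient = sample(c(2, 3, 4), 1),
          contacts_per_patient = sample(2:4, 1)
        ),
        mix = intervention_mix(
          counseling_hours_fraction = sample(seq(0.5, 0.9, by = 0.05), 1),
          counseling_hours_per_patient = sample(c(5, 6, 6.5, 8), 1),
          counseling_contacts_per_patient = sample(4:7, 1),
          instrumental_hours_per_patient = sample(c(2, 3, 4), 1),
          instrumental_contacts_per_patient = sample(2:4, 1)
        ),
        notes = "randomized test profile"
      ),
      silent = TRUE
    )
    if (inherits(prof, "try-error")) next
    feasible <- !inherits(try(compute_capacity(prof), silent = TRUE), "try-error")
    if (feasible) {
      return(prof)
    }
  }
  stop("could not generate a feasible random profile")
}

# Independent oracle for net annual hours: walk one fiscal year day by day.
# Builds the roster of paid days, assigns leave days, and sums worked hours.
# Only supports whole-number day counts and whole days-per-week (the default
# calendars and the random generator satisfy both).
enumerate_net_hours <- function(cal) {
  days_per_week <- cal$weekly_hours / cal$hours_per_workday
  stopifnot(days_per_week == round(days_per_week))
  paid_days <- cal$weeks_per_year * days_per_week
  stopifnot(paid_days == round(paid_days))
  roster <- rep("work", paid_days)
  off <- c(
    rep("vacation", cal$vacation_days),
    rep("stat", cal$statutory_holiday_days),
    rep("sick", cal$sick_days),
    rep("edu", cal$education_days)
  )
  stopifnot(length(off) <= paid_days)
  roster[seq_along(off)] <- off # which days are off does not change the total
  total <- 0
  for (day in roster) {
    if (day == "work") {
      total <- total + cal$hours_per_workday - cal$daily_break_hours
    }
  }
  total
}
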