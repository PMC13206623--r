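#' Split net hours into direct and indirect patient care
#'
#' Linear split of net annual hours by the DPC fraction. No rounding happens
#' here; fractional hours are carried forward at full precision.
#'
#' @param net_hours Net annual available hours (> 0).
#' @param split A [care_split()].
#' @return Named numeric vector `c(dpc_hours =, ipc_hours =)`; the two sum to
#'   `net_hours` exactly.
#' @examples
#' split_dpc(1000, care_split(0.80)) # 800 DPC, 200 IPC
#' @export
split_dpc <- function(net_hours, split) {
  check_number(net_hours, "net_hours", lower = 0, closed_lower = FALSE)
  stopifnot(inherits(split, "psocap_split"))
  dpc <- net_hours * split$dpc_fraction
  c(dpc_hours = dpc, ipc_hours = net_hours - dpc)
}

#' Group-work time, patients and contacts
#'
#' Provider hours are `groups * (prep + sessions * facilitation)`. Unique
#' patients are `groups * participants`; every attendee at every session is one
#' direct-patient-care contact, so contacts are
#' `groups * sessions * participants`.
#'
#' @param groups A [group_program()].
#' @return Named numeric vector `c(hours =, unique_patients =, contacts =)`.
#' @examples
#' group_block(group_program(3, 7, 8, 8, 2)) # 66 h, 24 patients, 168 contacts
#' @export
group_block <- function(groups) {
  stopifnot(inherits(groups, "psocap_groups"))
  g <- groups
  c(
    hours = g$groups_per_year *
      (g$prep_hours_per_group +
        g$sessions_per_group * g$facilitation_hours_per_session),
    unique_patients = g$groups_per_year * g$participants_per_group,
    contacts = g$groups_per_year * g$sessions_per_group *
      g$participants_per_group
  )
}

#' Carryover caseload time, patients and contacts
#'
#' Patients come either from the explicit count or, in rate mode, from
#' `floor(rate * base_caseload)`. Hours and contacts scale linearly with the
#' per-patient policy figures (default 4 h / 4 one-hour appointments).
#'
#' @param policy A [carryover_policy()].
#' @return Named numeric vector `c(patients =, hours =, contacts =)`.
#' @examples
#' carryover_block(carryover_policy("explicit_count", explicit_count = 60))
#' carryover_block(carryover_policy("rate_of_base", rate = 0.2, base_caseload = 300))
#' @export
carryover_block <- function(policy) {
  stopifnot(inherits(policy, "psocap_carryover"))
  patients <- switch(policy$mode,
    explicit_count = policy$explicit_count,
    rate_of_base = {
      if (is.na(policy$base_caseload)) {
        abort("rate_of_base carryover requires `base_caseload`.",
          class = "psocap_config_error"
        )
      }
      guarded_floor(policy$rate * policy$base_caseload)
    }
  )
  c(
    patients = patients,
    hours = patients * policy$hours_per_patient,
    contacts = patients * policy$contacts_per_patient
  )
}

#' Allocate remaining direct-care hours to counseling and instrumental work
#'
#' The remaining hours are partitioned by the counseling hour fraction; within
#' each stream the patient count is the *floor* of available hours over hours
#' per patient (fractional patients are not served), hours used are
#' `patients * hours_per_patient`, and contacts are
#' `patients * contacts_per_patient`. Unused remainder hours surface later as
#' slack, never silently dropped.
#'
#' @param remaining_dpc_hours DPC hours left after group work and carryover
#'   (>= 0).
#' @param mix An [intervention_mix()].
#' @return List with elements `counseling` and `instrumental`, each a named
#'   vector `c(hours_available =, unique_patients =, hours_used =, contacts =)`.
#' @examples
#' allocate_interventions(600, intervention_mix(1, 6, 6, 3, 3))
#' @export
allocate_interventions <- function(remaining_dpc_hours, mix) {
  check_number(remaining_dpc_hours, "remaining_dpc_hours", lower = 0)
  stopifnot(inherits(mix, "psocap_mix"))
  stream <- function(avail, hours_pp, contacts_pp) {
    patients <- guarded_floor(avail / hours_pp)
    c(
      hours_available = avail,
      unique_patients = patients,
      hours_used = patients * hours_pp,
      contacts = patients * contacts_pp
    )
  }
  couns_avail <- remaining_dpc_hours * mix$counseling_hours_fraction
  list(
    counseling = stream(
      couns_avail,
      mix$counseling_hours_per_patient,
      mix$counseling_contacts_per_patient
    ),
    instrumental = stream(
      remaining_dpc_hours - couns_avail,
      mix$instrumental_hours_per_patient,
      mix$instrumental_contacts_per_patient
    )
  )
}

#' Annual capacity of one 1.0 FTE position
#'
#' Composes the full deterministic capacity model: net annual hours from the
#' calendar, the DPC/IPC split, subtraction of the fixed group-work and
#' carryover commitments from DPC hours, and the counseling/instrumental
#' allocation of the remainder. All hour arithmetic is carried at full
#' precision; only patient and contact counts are integers (floors).
#'
#' Ledger identities that hold for every valid profile:
#' \itemize{
#'   \item `dpc_hours + ipc_hours = net hours`
#'   \item `new_patient_capacity = group + counseling + instrumental uniques`
#'   \item `total_unique_caseload = new_patient_capacity + carryover patients`
#'   \item `total_dpcc = group + carryover + counseling + instrumental contacts`
#'   \item `slack_hours = dpc - (group + carryover + counseling used +
#'     instrumental used)`, with `0 <= slack < counseling_h/pt +
#'     instrumental_h/pt` (one floor remainder per stream).
#' }
#'
#' @param profile A [staffing_profile()].
#' @return A `psocap_capacity` object; see [tidy.psocap_capacity()] and
#'   [glance.psocap_capacity()].
#' @examples
#' compute_capacity(default_profile("capo2022_sw_tertiary_75_25"))
#' @export
compute_capacity <- function(profile) {
  stopifnot(inherits(profile, "psocap_profile"))
  ledger <- net_annual_hours(profile$calendar)
  sp <- split_dpc(ledger$net_available_hours, profile$split)
  grp <- group_block(profile$groups)
  co <- carryover_block(profile$carryover)
  remaining <- sp[["dpc_hours"]] - grp[["hours"]] - co[["hours"]]
  if (remaining < 0) {
    abort(
      sprintf(
        paste0(
          "Infeasible profile: group work (%g h) plus carryover (%g h) exceed ",
          "DPC hours (%g h) by %g h."
        ),
        grp[["hours"]], co[["hours"]], sp[["dpc_hours"]], -remaining
      ),
      class = "psocap_infeasible_profile"
    )
  }
  iv <- allocate_interventions(remaining, profile$mix)
  new_patients <- grp[["unique_patients"]] +
    iv$counseling[["unique_patients"]] + iv$instrumental[["unique_patients"]]
  structure(
    list(
      profile = profile,
      hours_ledger = ledger,
      dpc_hours = sp[["dpc_hours"]],
      ipc_hours = sp[["ipc_hours"]],
      group_block = grp,
      carryover_block = co,
      counseling_block = iv$counseling,
      instrumental_block = iv$instrumental,
      new_patient_capacity = new_patients,
      total_unique_caseload = new_patients + co[["patients"]],
      total_dpcc = grp[["contacts"]] + co[["contacts"]] +
        iv$counseling[["contacts"]] + iv$instrumental[["contacts"]],
      slack_hours = remaining - iv$counseling[["hours_used"]] -
        iv$instrumental[["hours_used"]]
    ),
    class = "psocap_capacity"
  )
}

#' @export
print.psocap_capacity <- function(x, ...) {
  p <- x$profile
  cat(sprintf(
    "<psocap_capacity> %s, %s center, %.0f%% DPC, per 1.0 FTE/yr\n",
    p$discipline, p$setting, 100 * p$split$dpc_fraction
  ))
  cat(sprintf(
    "  net hours %.2f = DPC %.2f + IPC %.2f\n",
    x$hours_ledger$net_available_hours, x$dpc_hours, x$ipc_hours
  ))
  cat(sprintf(
    "  groups      : %6.2f h, %3d patients, %4d contacts\n",
    x$group_block[["hours"]], x$group_block[["unique_patients"]],
    x$group_block[["contacts"]]
  ))
  cat(sprintf(
    "  carryover   : %6.2f h, %3d patients, %4d contacts\n",
    x$carryover_block[["hours"]], x$carryover_block[["patients"]],
    x$carryover_block[["contacts"]]
  ))
  cat(sprintf(
    "  counseling  : %6.2f h, %3d patients, %4d contacts\n",
    x$counseling_block[["hours_used"]], x$counseling_block[["unique_patients"]],
    x$counseling_block[["contacts"]]
  ))
  cat(sprintf(
    "  instrumental: %6.2f h, %3d patients, %4d contacts\n",
    x$instrumental_block[["hours_used"]],
    x$instrumental_block[["unique_patients"]],
    x$instrumental_block[["contacts"]]
  ))
  cat(sprintf(
    "  new patients %d | total unique %d | DPCCs %d | slack %.2f h\n",
    x$new_patient_capacity, x$total_unique_caseload, x$total_dpcc,
    x$slack_hours
  ))
  invisible(x)
}

#' Tidiers for capacity results
#'
#' `tidy()` returns one row per workload block (groups, carryover, counseling,
#' instrumental) with hours, unique patients and contacts; `glance()` returns
#' the one-row per-FTE summary.
#'
#' @param x A `psocap_capacity` from [compute_capacity()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.psocap_capacity <- function(x, ...) {
  tibble(
    block = c("groups", "carryover", "counseling", "instrumental"),
    hours = c(
      x$group_block[["hours"]], x$carryover_block[["hours"]],
      x$counseling_block[["hours_used"]], x$instrumental_block[["hours_used"]]
    ),
    unique_patients = c(
      x$group_block[["unique_patients"]], x$carryover_block[["patients"]],
      x$counseling_block[["unique_patients"]],
      x$instrumental_block[["unique_patients"]]
    ),
    contacts = c(
      x$group_block[["contacts"]], x$carryover_block[["contacts"]],
      x$counseling_block[["contacts"]], x$instrumental_block[["contacts"]]
    )
  )
}

#' @rdname tidy.psocap_capacity
#' @export
glance.psocap_capacity <- function(x, ...) {
  tibble(
    net_hours = x$hours_ledger$net_available_hours,
    dpc_hours = x$dpc_hours,
    ipc_hours = x$ipc_hours,
    new_patient_capacity = x$new_patient_capacity,
    carryover_patients = x$carryover_block[["patients"]],
    total_unique_caseload = x$total_unique_caseload,
    total_dpcc = x$total_dpcc,
    slack_hours = x$slack_hours
  )
}

#' Plot the direct-care hour allocation of a capacity result
#'
#' Stacked single-bar view of how the annual DPC hours of one FTE are committed
#' across groups, carryover, counseling, instrumental work and slack.
#'
#' @param object A `psocap_capacity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psocap_capacity <- function(object, ...) {
  d <- tidy(object)
  d <- bind_rows(d, tibble(
    block = "slack", hours = object$slack_hours,
    unique_patients = NA_real_, contacts = NA_real_
  ))
  d$block <- factor(d$block, levels = rev(c(
    "groups", "carryover",
    "counseling", "instrumental", "slack"
  )))
  ggplot2::ggplot(d, ggplot2::aes(x = "DPC hours", y = .data$hours, fill = .data$block)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "hours per 1.0 FTE per year", fill = NULL,
      title = sprintf(
        "Direct-patient-care hour allocation (%.0f%% DPC)",
        100 * object$profile$split$dpc_fraction
      )
    ) +
    ggplot2::theme_minimal()
}
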