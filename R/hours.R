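#' Net annual available work hours of one position
#'
#' Converts a [work_calendar()] into an annual hours ledger: gross paid hours
#' (`weekly_hours * weeks_per_year`) minus each category of paid-but-not-worked
#' time. Vacation, statutory holidays, sick days and education days are each
#' deducted as `days * hours_per_workday`; daily breaks are deducted only for
#' days actually worked (paid days minus all deducted days), since breaks are
#' not taken while on leave. Disability and unpaid leaves are never deducted —
#' they are not calendar fields.
#'
#' @param calendar A [work_calendar()].
#' @return A `psocap_hours_ledger`: list with `gross_paid_hours`, a
#'   `deductions` tibble (`label`, `hours`), and `net_available_hours`.
#'   Conservation holds exactly: net = gross - sum(deductions).
#' @examples
#' cal <- work_calendar(37.5, 52, vacation_days = 20)
#' net_annual_hours(cal) # 1950 gross - 150 vacation = 1800 net
#' @export
net_annual_hours <- function(calendar) {
  stopifnot(inherits(calendar, "psocap_calendar"))
  cal <- calendar
  gross <- cal$weekly_hours * cal$weeks_per_year
  days_per_week <- cal$weekly_hours / cal$hours_per_workday
  paid_days <- cal$weeks_per_year * days_per_week
  deducted_days <- cal$vacation_days + cal$statutory_holiday_days +
    cal$sick_days + cal$education_days
  worked_days <- paid_days - deducted_days
  if (worked_days < 0) {
    abort(
      sprintf(
        "Infeasible calendar: %g days deducted exceed %g paid days.",
        deducted_days, paid_days
      ),
      class = "psocap_infeasible_calendar"
    )
  }
  deductions <- tibble(
    label = c(
      "vacation", "statutory holidays", "sick days", "education days",
      "breaks and lunches"
    ),
    hours = c(
      cal$vacation_days * cal$hours_per_workday,
      cal$statutory_holiday_days * cal$hours_per_workday,
      cal$sick_days * cal$hours_per_workday,
      cal$education_days * cal$hours_per_workday,
      cal$daily_break_hours * worked_days
    )
  )
  net <- gross - sum(deductions$hours)
  if (net <= 0) {
    abort(
      sprintf(
        "Infeasible calendar: deductions (%g h) >= gross paid hours (%g h).",
        sum(deductions$hours), gross
      ),
      class = "psocap_infeasible_calendar"
    )
  }
  structure(
    list(
      gross_paid_hours = gross,
      deductions = deductions,
      net_available_hours = net,
      worked_days = worked_days
    ),
    class = "psocap_hours_ledger"
  )
}

#' @export
print.psocap_hours_ledger <- function(x, ...) {
  cat("<psocap_hours_ledger>\n")
  cat(sprintf("  gross paid hours : %10.2f\n", x$gross_paid_hours))
  for (i in seq_len(nrow(x$deductions))) {
    cat(sprintf(
      "  - %-18s %8.2f\n", x$deductions$label[i],
      x$deductions$hours[i]
    ))
  }
  cat(sprintf("  net available    : %10.2f h/yr\n", x$net_available_hours))
  invisible(x)
}

#' @describeIn net_annual_hours One row per ledger line (gross, each deduction,
#'   net), as a tibble.
#' @param x A `psocap_hours_ledger`.
#' @param ... Unused.
#' @export
tidy.psocap_hours_ledger <- function(x, ...) {
  bind_rows(
    tibble(label = "gross paid hours", hours = x$gross_paid_hours, kind = "gross"),
    mutate(x$deductions, kind = "deduction"),
    tibble(label = "net available hours", hours = x$net_available_hours, kind = "net")
  )
}

#' @describeIn net_annual_hours One-row summary (gross, total deductions, net,
#'   worked days).
#' @export
glance.psocap_hours_ledger <- function(x, ...) {
  tibble(
    gross_paid_hours = x$gross_paid_hours,
    total_deductions = sum(x$deductions$hours),
    net_available_hours = x$net_available_hours,
    worked_days = x$worked_days
  )
}
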