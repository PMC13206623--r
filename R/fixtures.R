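CONTACT_TYPES <- c(
  "assessment", "counseling_followup", "instrumental",
  "group_session", "carryover_followup"
)

#' Generate a synthetic workload-measurement contact log
#'
#' Emits one fiscal year of per-contact records with the structure a workload
#' measurement system would export: patient id, contact type, duration, date,
#' provider id, case status. Aggregate counts equal the profile's deterministic
#' capacity scaled by `fte` (per block, patients rounded half-up), so
#' [aggregate_contact_log()] round-trips to the capacity result.
#'
#' Per-patient structure: counseling patients get one assessment (1.5 h by the
#' packaged default mix) followed by 1-hour counseling follow-ups; instrumental
#' patients one assessment plus 1-hour instrumental contacts; carryover
#' patients 1-hour carryover follow-ups (their files opened in the prior fiscal
#' year, so their case status is `open`); group participants one
#' `group_session` record per session, with the session's facilitation length
#' as duration. Dates are drawn uniformly within the fiscal year and sorted
#' within each patient so the assessment comes first. Deterministic per seed;
#' the caller's RNG state is left untouched.
#'
#' @param profile A [staffing_profile()].
#' @param fte Positions generating the workload (> 0).
#' @param seed Integer seed.
#' @param fiscal_year_start First day of the fiscal year (`Date` or
#'   `"YYYY-MM-DD"`); default April 1, the common Canadian fiscal year start.
#' @return Tibble of contact records: `patient_id`, `contact_type`,
#'   `duration`, `date`, `provider_id`, `case_status`.
#' @examples
#' log <- generate_contact_log(default_profile(), fte = 1, seed = 42)
#' nrow(log) # 1251 contacts
#' @export
generate_contact_log <- function(profile, fte = 1, seed = 1,
                                 fiscal_year_start = "2025-04-01") {
  stopifnot(inherits(profile, "psocap_profile"))
  check_number(fte, "fte", lower = 0, closed_lower = FALSE)
  fy0 <- as.Date(fiscal_year_start)
  fy1 <- seq(fy0, by = "1 year", length.out = 2)[2] - 1
  cap <- compute_capacity(profile)
  mix <- profile$mix

  n_couns <- round_half_up(fte * cap$counseling_block[["unique_patients"]])
  n_instr <- round_half_up(fte * cap$instrumental_block[["unique_patients"]])
  n_carry <- round_half_up(fte * cap$carryover_block[["patients"]])
  n_group <- round_half_up(fte * cap$group_block[["unique_patients"]])
  providers <- sprintf("PSO-%02d", seq_len(max(1, ceiling(fte))))

  patient_block <- function(prefix, n, contacts_per_patient, durations,
                            types, status) {
    if (n == 0 || contacts_per_patient == 0) {
      return(NULL)
    }
    ids <- sprintf("%s-%04d", prefix, seq_len(n))
    tibble(
      patient_id = rep(ids, each = contacts_per_patient),
      contact_type = rep(types, times = n),
      duration = rep(durations, times = n),
      case_status = status
    )
  }

  # a longer assessment followed by 1-h follow-ups where the per-patient hours
  # allow it; otherwise hours spread evenly over the visits
  visit_durations <- function(hours, contacts) {
    if (hours - (contacts - 1) > 0) {
      c(hours - (contacts - 1), rep(1, contacts - 1))
    } else {
      rep(hours / contacts, contacts)
    }
  }
  couns <- patient_block(
    "CNS", n_couns, mix$counseling_contacts_per_patient,
    durations = visit_durations(
      mix$counseling_hours_per_patient,
      mix$counseling_contacts_per_patient
    ),
    types = c(
      "assessment",
      rep("counseling_followup", mix$counseling_contacts_per_patient - 1)
    ),
    status = "closed"
  )
  instr <- patient_block(
    "INS", n_instr, mix$instrumental_contacts_per_patient,
    durations = visit_durations(
      mix$instrumental_hours_per_patient,
      mix$instrumental_contacts_per_patient
    ),
    types = c(
      "assessment",
      rep("instrumental", mix$instrumental_contacts_per_patient - 1)
    ),
    status = "closed"
  )
  carry <- patient_block(
    "CRY", n_carry, profile$carryover$contacts_per_patient,
    durations = rep(
      profile$carryover$hours_per_patient /
        profile$carryover$contacts_per_patient,
      profile$carryover$contacts_per_patient
    ),
    types = rep("carryover_followup", profile$carryover$contacts_per_patient),
    status = "open"
  )
  grp <- patient_block(
    "GRP", n_group, profile$groups$sessions_per_group,
    durations = rep(
      profile$groups$facilitation_hours_per_session,
      profile$groups$sessions_per_group
    ),
    types = rep("group_session", profile$groups$sessions_per_group),
    status = "closed"
  )

  records <- bind_rows(couns, instr, carry, grp)
  if (nrow(records) == 0) {
    return(empty_contact_log())
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    },
    add = TRUE
  )
  set.seed(seed)

  n_days <- as.integer(fy1 - fy0) + 1L
  records$date <- fy0 + (sample.int(n_days, nrow(records), replace = TRUE) - 1L)
  # assessment precedes follow-ups: dates sort within patient, first row first
  records <- records |>
    group_by(.data$patient_id) |>
    mutate(date = sort(.data$date)) |>
    dplyr::ungroup()
  records$provider_id <- providers[
    (match(records$patient_id, unique(records$patient_id)) - 1L) %%
      length(providers) + 1L
  ]
  select(
    records, "patient_id", "contact_type", "duration", "date",
    "provider_id", "case_status"
  )
}

empty_contact_log <- function() {
  tibble(
    patient_id = character(),
    contact_type = character(),
    duration = numeric(),
    date = as.Date(character()),
    provider_id = character(),
    case_status = character()
  )
}

validate_contact_log <- function(records) {
  required <- names(empty_contact_log())
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort(sprintf(
      "Contact log is missing column(s): %s.",
      paste(missing, collapse = ", ")
    ), class = "psocap_validation_error")
  }
  bad_type <- which(!records$contact_type %in% CONTACT_TYPES)
  if (length(bad_type)) {
    abort(sprintf(
      "Row %d: unknown contact_type \"%s\".",
      bad_type[1], records$contact_type[bad_type[1]]
    ), class = "psocap_validation_error")
  }
  bad_dur <- which(!(is.finite(records$duration) & records$duration > 0))
  if (length(bad_dur)) {
    abort(sprintf("Row %d: duration must be > 0.", bad_dur[1]),
      class = "psocap_validation_error"
    )
  }
  bad_status <- which(!records$case_status %in% c("open", "closed"))
  if (length(bad_status)) {
    abort(sprintf(
      "Row %d: case_status must be \"open\" or \"closed\".",
      bad_status[1]
    ), class = "psocap_validation_error")
  }
  bad_date <- which(is.na(as.Date(records$date)))
  if (length(bad_date)) {
    abort(sprintf("Row %d: invalid date.", bad_date[1]),
      class = "psocap_validation_error"
    )
  }
  invisible(records)
}

#' Aggregate a contact log into an observed capacity summary
#'
#' Counts unique patients, contacts by type, and carryover-eligible cases.
#' The carryover counting rule: a case counts as carryover only if it was
#' opened in a prior fiscal year *and* receives at least one contact in the
#' focal fiscal year. A log row is attributed to a prior-year opening either
#' by an actual contact dated before `fiscal_year_start` or by the
#' `carryover_followup` contact type (how single-year exports mark continuing
#' files). Open cases with no focal-year contact are not carryover.
#'
#' @param records Contact-record tibble as produced by
#'   [generate_contact_log()] or [read_contact_log()].
#' @param fiscal_year_start First day of the focal fiscal year; default the
#'   earliest April 1 at or before the earliest record.
#' @return One-row tibble: `unique_patients`, `total_contacts`,
#'   `carryover_cases`, and per-type contact counts
#'   (`contacts_<type>`).
#' @examples
#' log <- generate_contact_log(default_profile(), fte = 1, seed = 42)
#' aggregate_contact_log(log)
#' @export
aggregate_contact_log <- function(records, fiscal_year_start = NULL) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    out <- tibble(
      unique_patients = 0L, total_contacts = 0L, carryover_cases = 0L
    )
    for (tp in CONTACT_TYPES) out[[paste0("contacts_", tp)]] <- 0L
    return(out)
  }
  validate_contact_log(records)
  records$date <- as.Date(records$date)
  if (is.null(fiscal_year_start)) {
    d0 <- min(records$date)
    fy0 <- as.Date(sprintf(
      "%d-04-01",
      as.integer(format(d0, "%Y")) - (format(d0, "%m-%d") < "04-01")
    ))
  } else {
    fy0 <- as.Date(fiscal_year_start)
  }
  fy1 <- seq(fy0, by = "1 year", length.out = 2)[2]
  in_year <- records$date >= fy0 & records$date < fy1
  focal <- records[in_year, ]

  prior_opened <- unique(records$patient_id[
    records$date < fy0 | records$contact_type == "carryover_followup"
  ])
  carryover_cases <- length(intersect(prior_opened, unique(focal$patient_id)))

  out <- tibble(
    unique_patients = n_distinct(focal$patient_id),
    total_contacts = nrow(focal),
    carryover_cases = carryover_cases
  )
  counts <- table(factor(focal$contact_type, levels = CONTACT_TYPES))
  for (tp in CONTACT_TYPES) {
    out[[paste0("contacts_", tp)]] <- as.integer(counts[[tp]])
  }
  out
}

#' Read and write contact logs as CSV
#'
#' Plain-CSV interchange with workload-measurement exports: header row,
#' ISO-8601 dates, one record per contact. Reading validates every row.
#'
#' @param path CSV file path.
#' @return `read_contact_log()`: a validated contact-record tibble;
#'   `write_contact_log()`: the records, invisibly.
#' @export
read_contact_log <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      contact_type = readr::col_character(),
      duration = readr::col_double(),
      date = readr::col_date(),
      provider_id = readr::col_character(),
      case_status = readr::col_character()
    )
  )
  validate_contact_log(records)
  records
}

#' @rdname read_contact_log
#' @param records Contact-record tibble.
#' @export
write_contact_log <- function(records, path) {
  validate_contact_log(as_tibble(records))
  readr::write_csv(records, path)
  invisible(records)
}
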