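# Flat field lists drive both serialization and strict schema validation.
profile_schema_fields <- function() {
  list(
    top = c(
      "schema_version", "discipline", "setting", "calendar", "split",
      "groups", "carryover", "mix", "notes"
    ),
    calendar = c(
      "weekly_hours", "weeks_per_year", "vacation_days",
      "statutory_holiday_days", "sick_days", "education_days",
      "daily_break_hours", "hours_per_workday"
    ),
    split = "dpc_fraction",
    groups = c(
      "groups_per_year", "sessions_per_group", "participants_per_group",
      "prep_hours_per_group", "facilitation_hours_per_session"
    ),
    carryover = c(
      "mode", "explicit_count", "rate", "base_caseload",
      "hours_per_patient", "contacts_per_patient"
    ),
    mix = c(
      "counseling_hours_fraction", "counseling_hours_per_patient",
      "counseling_contacts_per_patient", "instrumental_hours_per_patient",
      "instrumental_contacts_per_patient"
    )
  )
}

check_keys <- function(x, expected, where) {
  nm <- names(x)
  missing <- setdiff(expected, nm)
  extra <- setdiff(nm, expected)
  if (length(missing)) {
    abort(sprintf(
      "Profile %s is missing field(s): %s.", where,
      paste(missing, collapse = ", ")
    ), class = "psocap_schema_error")
  }
  if (length(extra)) {
    abort(sprintf(
      "Profile %s has unknown field(s): %s.", where,
      paste(extra, collapse = ", ")
    ), class = "psocap_schema_error")
  }
  invisible(x)
}

profile_to_list <- function(profile) {
  stopifnot(inherits(profile, "psocap_profile"))
  sub <- function(obj) lapply(unclass(obj), identity)
  list(
    schema_version = profile$schema_version,
    discipline = profile$discipline,
    setting = profile$setting,
    calendar = sub(profile$calendar),
    split = sub(profile$split),
    groups = sub(profile$groups),
    carryover = sub(profile$carryover),
    mix = sub(profile$mix),
    notes = profile$notes
  )
}

profile_from_list <- function(x) {
  fields <- profile_schema_fields()
  check_keys(x, fields$top, "document")
  if (!identical(as.integer(x$schema_version), PROFILE_SCHEMA_VERSION)) {
    abort(
      sprintf(
        "Unsupported schema_version %s (this build reads version %d).",
        format(x$schema_version), PROFILE_SCHEMA_VERSION
      ),
      class = "psocap_schema_error"
    )
  }
  for (section in c("calendar", "split", "groups", "carryover", "mix")) {
    if (!is.list(x[[section]])) {
      abort(sprintf("Profile section `%s` must be a mapping.", section),
        class = "psocap_schema_error"
      )
    }
    check_keys(x[[section]], fields[[section]], sprintf("section `%s`", section))
  }
  base <- if (is.null(x$carryover$base_caseload)) NA_real_ else x$carryover$base_caseload
  staffing_profile(
    discipline = x$discipline,
    setting = x$setting,
    calendar = do.call(work_calendar, x$calendar),
    split = do.call(care_split, x$split),
    groups = do.call(group_program, x$groups),
    carryover = carryover_policy(
      mode = x$carryover$mode,
      explicit_count = x$carryover$explicit_count,
      rate = x$carryover$rate,
      base_caseload = base,
      hours_per_patient = x$carryover$hours_per_patient,
      contacts_per_patient = x$carryover$contacts_per_patient
    ),
    mix = do.call(intervention_mix, x$mix),
    notes = x$notes
  )
}

guess_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("yaml", "json")))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml = ,
    yaml = "yaml",
    json = "json",
    abort(sprintf(
      "Cannot infer format from extension \"%s\"; pass `format`.", ext
    ), class = "psocap_config_error")
  )
}

#' Read and write staffing profiles as config files
#'
#' Profiles round-trip losslessly through YAML (primary) or JSON (equivalent
#' schema). Reading is strict: unknown keys, missing fields, an unsupported
#' `schema_version`, or out-of-range values are errors that name the offending
#' field. The JSON-Schema document for the format ships with the package:
#' `system.file("extdata", "profile-schema.json", package = "psocap")`.
#'
#' @param path File path; extension `.yaml`/`.yml` or `.json` selects the
#'   format unless `format` is given.
#' @param format `"yaml"` or `"json"`; default inferred from the extension.
#' @return `read_profile()` a validated [staffing_profile()];
#'   `write_profile()` the input profile, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_profile(default_profile(), f)
#' identical_fields <- all.equal(read_profile(f), default_profile())
#' @export
read_profile <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Profile file not found: %s", path),
      class = "psocap_config_error"
    )
  }
  fmt <- guess_format(path, format)
  x <- switch(fmt,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
  if (!is.list(x)) {
    abort("Profile file does not contain a mapping at top level.",
      class = "psocap_schema_error"
    )
  }
  profile_from_list(x)
}

#' @rdname read_profile
#' @param profile A [staffing_profile()] to serialize.
#' @export
write_profile <- function(profile, path, format = NULL) {
  stopifnot(inherits(profile, "psocap_profile"))
  fmt <- guess_format(path, format)
  x <- profile_to_list(profile)
  if (fmt == "yaml") {
    # drop NA base_caseload from explicit-count profiles? No: keep full schema,
    # YAML serializes NA as .na which read_yaml restores.
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(
      x, path,
      auto_unbox = TRUE, digits = NA, null = "null",
      na = "null", pretty = TRUE
    )
  }
  invisible(profile)
}
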