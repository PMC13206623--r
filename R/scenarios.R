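# Registry of sweepable numeric profile fields. `monotone` documents the
# direction of the capacity contract: +1 capacity non-decreasing in the field,
# -1 non-increasing, 0 no monotone contract.
sweepable_registry <- function() {
  tibble(
    parameter = c(
      "calendar.weekly_hours",
      "calendar.vacation_days",
      "calendar.statutory_holiday_days",
      "calendar.sick_days",
      "calendar.education_days",
      "calendar.daily_break_hours",
      "split.dpc_fraction",
      "groups.groups_per_year",
      "carryover.explicit_count",
      "carryover.hours_per_patient",
      "mix.counseling_hours_fraction",
      "mix.counseling_hours_per_patient",
      "mix.instrumental_hours_per_patient"
    ),
    monotone_capacity = c(1, -1, -1, -1, -1, -1, 1, 0, -1, -1, 0, -1, -1)
  )
}

#' Sweepable profile parameters
#'
#' Names accepted by [sweep_parameter()], as `section.field` paths into a
#' [staffing_profile()], with the documented monotonicity of new-patient
#' capacity in each (`1` non-decreasing, `-1` non-increasing, `0` none).
#'
#' @return Tibble with columns `parameter` and `monotone_capacity`.
#' @export
sweepable_parameters <- function() {
  sweepable_registry()
}

set_profile_field <- function(profile, parameter, value) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  section <- parts[1]
  field <- parts[2]
  if (parameter == "split.dpc_fraction") {
    # steady-state coupling: the carryover caseload is a share of the prior
    # year's caseload, which scales with direct-care hours, so a split sweep
    # rescales the carryover volume by the DPC ratio. This is what ties the
    # published 75/25 and 70/30 panels together (60 -> 56 carryover).
    ratio <- value / profile$split$dpc_fraction
    co <- unclass(profile$carryover)
    co$explicit_count <- round_half_up(co$explicit_count * ratio)
    if (!is.na(co$base_caseload)) {
      co$base_caseload <- co$base_caseload * ratio
    }
    profile$carryover <- do.call(carryover_policy, co[c(
      "mode", "explicit_count", "rate", "base_caseload", "hours_per_patient",
      "contacts_per_patient"
    )])
  }
  sub <- unclass(profile[[section]])
  sub[[field]] <- value
  rebuilt <- switch(section,
    calendar = do.call(work_calendar, sub),
    split = do.call(care_split, sub),
    groups = do.call(group_program, sub),
    carryover = do.call(carryover_policy, sub[c(
      "mode", "explicit_count", "rate", "base_caseload", "hours_per_patient",
      "contacts_per_patient"
    )]),
    mix = do.call(intervention_mix, sub)
  )
  profile[[section]] <- rebuilt
  profile
}

#' Sensitivity sweep over one profile parameter
#'
#' Recomputes per-FTE capacity and the FTE requirement for a reference demand
#' at each value of one numeric profile field. A pure function: the input
#' profile is never modified.
#'
#' Sweeping `split.dpc_fraction` also rescales the carryover volume (explicit
#' count and rate base) by the DPC ratio: the carryover caseload is a share of
#' the prior year's caseload, which in steady state is proportional to
#' direct-care hours. This coupling is what relates the published 75/25 and
#' 70/30 panels (carryover 60 vs 56).
#'
#' @param profile A [staffing_profile()].
#' @param parameter A `section.field` path from [sweepable_parameters()],
#'   e.g. `"split.dpc_fraction"`.
#' @param values Numeric vector of settings, each valid for the field.
#' @param cases Reference annual new-case volume for the FTE curve
#'   (default 2000).
#' @param referral_rate Referral rate for the FTE curve (default 0.35).
#' @return A `psocap_sweep`: tibble with one row per value (`parameter`,
#'   `value`, `new_patient_capacity`, `total_unique_caseload`, `total_dpcc`,
#'   `fte_required`), plus reference-demand attributes.
#' @examples
#' sweep_parameter(default_profile(), "split.dpc_fraction", c(0.75, 0.70))
#' @export
sweep_parameter <- function(profile, parameter, values, cases = 2000,
                            referral_rate = 0.35) {
  stopifnot(inherits(profile, "psocap_profile"))
  check_string(parameter, "parameter")
  reg <- sweepable_registry()
  if (!parameter %in% reg$parameter) {
    abort(
      sprintf(
        "Unknown sweep parameter \"%s\". Sweepable fields: %s.",
        parameter, paste(reg$parameter, collapse = ", ")
      ),
      class = "psocap_lookup_error"
    )
  }
  stopifnot(is.numeric(values), length(values) >= 1)
  referrals <- expected_referrals(demand_spec(cases, referral_rate))
  rows <- map(values, function(v) {
    cap <- compute_capacity(set_profile_field(profile, parameter, v))
    tibble(
      parameter = parameter,
      value = v,
      new_patient_capacity = cap$new_patient_capacity,
      total_unique_caseload = cap$total_unique_caseload,
      total_dpcc = cap$total_dpcc,
      fte_required = fte_required(referrals, cap)
    )
  }) |> list_rbind()
  structure(
    rows,
    class = c("psocap_sweep", class(rows)),
    cases = cases,
    referral_rate = referral_rate
  )
}

#' Plot a sensitivity sweep
#'
#' FTE requirement and per-FTE new-patient capacity against the swept
#' parameter value.
#'
#' @param object A `psocap_sweep` from [sweep_parameter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psocap_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object),
    c("new_patient_capacity", "fte_required"),
    names_to = "metric", values_to = "y"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = object$parameter[1],
      y = NULL,
      title = sprintf(
        "Sensitivity of capacity and FTE requirement (%g cases @ %.0f%%)",
        attr(object, "cases"), 100 * attr(object, "referral_rate")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Stochastic referral-stream validation of the capacity model
#'
#' Simulates `replicates` fiscal years. Referral arrivals are a homogeneous
#' Poisson count with annual mean [expected_referrals()] (quarter-to-quarter
#' fluctuations are assumed to balance out, so a stationary process is the
#' appropriate null model). Each referral is counseling or instrumental, with
#' stream probabilities proportional to `hour_fraction / hours_per_patient` so
#' that the expected share of service *hours* per stream equals the profile's
#' mix fractions. Patients are served first-come-first-served against
#' `fte x` the intervention hours the deterministic model commits (counseling
#' plus instrumental `hours_used`, i.e. net of group work, carryover, and
#' floor slack); a referral is served only if its full per-patient hours fit.
#' Group and carryover commitments are honored deterministically.
#'
#' `mean_patients_served` counts *new* patients (group participants plus served
#' individual referrals) and converges, as replicates grow, to
#' `fte x new_patient_capacity` whenever demand is at or above capacity — the
#' law-of-large-numbers check that validates the deterministic formula.
#'
#' @param profile A [staffing_profile()].
#' @param demand A [demand_spec()].
#' @param fte Staffed FTE (> 0).
#' @param seed Integer seed; identical seeds give identical reports.
#' @param replicates Number of simulated years (>= 1); default 500.
#' @return A `psocap_simulation`: list with `seed`, `replicates`,
#'   `mean_patients_served`, `mean_dpc_hours_used`, `utilization`,
#'   `p_demand_unmet` (share of replicates with at least one unserved
#'   referral), and a `replicates_detail` tibble (one row per replicate).
#' @examples
#' sim <- simulate_year(default_profile(), demand_spec(2000), fte = 3.35,
#'   seed = 1, replicates = 50
#' )
#' sim$mean_patients_served # near 3.35 * 209 = 700.15
#' @export
simulate_year <- function(profile, demand, fte, seed = 20220101,
                          replicates = 500) {
  stopifnot(
    inherits(profile, "psocap_profile"),
    inherits(demand, "psocap_demand")
  )
  check_number(fte, "fte", lower = 0, closed_lower = FALSE)
  check_number(replicates, "replicates", lower = 1)
  cap <- compute_capacity(profile)
  mix <- profile$mix
  lambda <- expected_referrals(demand)

  # arrival-type probability: patients per hour weighting, so hour shares
  # match the mix fractions in expectation
  w_c <- mix$counseling_hours_fraction / mix$counseling_hours_per_patient
  w_i <- (1 - mix$counseling_hours_fraction) / mix$instrumental_hours_per_patient
  p_counseling <- if (w_c + w_i > 0) w_c / (w_c + w_i) else 0

  budget <- fte * (cap$counseling_block[["hours_used"]] +
    cap$instrumental_block[["hours_used"]])
  fixed_hours <- fte * (cap$group_block[["hours"]] +
    cap$carryover_block[["hours"]])
  # annualized group enrollment at this staffing level; kept fractional so
  # replicate means are unbiased against fte * new_patient_capacity
  group_served <- fte * cap$group_block[["unique_patients"]]
  dpc_total <- fte * cap$dpc_hours

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

  one_year <- function(rep_id) {
    n_arrivals <- rpois(1, lambda)
    if (n_arrivals > 0) {
      is_couns <- runif(n_arrivals) < p_counseling
      hours <- ifelse(
        is_couns,
        mix$counseling_hours_per_patient,
        mix$instrumental_hours_per_patient
      )
      fits <- cumsum(hours) <= budget
      served <- if (all(fits)) n_arrivals else which.min(fits) - 1L
      hours_used <- if (served > 0) sum(hours[seq_len(served)]) else 0
    } else {
      served <- 0L
      hours_used <- 0
    }
    tibble(
      replicate = rep_id,
      arrivals = n_arrivals,
      served_individual = served,
      unserved = n_arrivals - served,
      patients_served = group_served + served,
      dpc_hours_used = fixed_hours + hours_used
    )
  }
  detail <- map(seq_len(replicates), one_year) |> list_rbind()

  structure(
    list(
      seed = seed,
      replicates = replicates,
      fte = fte,
      mean_patients_served = mean(detail$patients_served),
      mean_dpc_hours_used = mean(detail$dpc_hours_used),
      utilization = mean(detail$dpc_hours_used) / dpc_total,
      p_demand_unmet = mean(detail$unserved > 0),
      replicates_detail = detail
    ),
    class = "psocap_simulation"
  )
}

#' @export
print.psocap_simulation <- function(x, ...) {
  cat(sprintf(
    "<psocap_simulation> %d replicates (seed %d), %.2f FTE\n",
    x$replicates, x$seed, x$fte
  ))
  cat(sprintf(
    "  mean new patients served : %.2f\n  mean DPC hours used      : %.1f\n",
    x$mean_patients_served, x$mean_dpc_hours_used
  ))
  cat(sprintf(
    "  utilization              : %.3f\n  P(demand unmet)          : %.3f\n",
    x$utilization, x$p_demand_unmet
  ))
  invisible(x)
}

#' @describeIn simulate_year One-row summary tibble of the report.
#' @param x A `psocap_simulation`.
#' @param ... Unused.
#' @export
glance.psocap_simulation <- function(x, ...) {
  tibble(
    seed = x$seed,
    replicates = x$replicates,
    fte = x$fte,
    mean_patients_served = x$mean_patients_served,
    mean_dpc_hours_used = x$mean_dpc_hours_used,
    utilization = x$utilization,
    p_demand_unmet = x$p_demand_unmet
  )
}

#' @describeIn simulate_year Replicate-level results, one row per simulated
#'   year.
#' @export
tidy.psocap_simulation <- function(x, ...) {
  x$replicates_detail
}

#' Plot the replicate distribution of served patients
#'
#' Histogram of new patients served per simulated year, with the deterministic
#' product `fte x new-patient capacity` as a reference line.
#'
#' @param object A `psocap_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psocap_simulation <- function(object, ...) {
  ggplot2::ggplot(
    object$replicates_detail,
    ggplot2::aes(x = .data$patients_served)
  ) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(
      xintercept = object$mean_patients_served,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "new patients served per year", y = "replicates",
      title = sprintf(
        "Referral-stream simulation (%d replicates, seed %d)",
        object$replicates, object$seed
      )
    ) +
    ggplot2::theme_minimal()
}
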