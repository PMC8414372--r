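#' Time-dependent sensitivity
#'
#' Proportion of clinical events preceded by at least one alarm inside the
#' prediction horizon: `S = n_predicted / n_events`. An event is
#' successfully predicted when at least one alarm is classified `on_time`
#' (see [classify_alarms()]). Case patients whose stay is shorter than
#' `tau + tau0` cannot fit the horizon inside the recording and are
#' excluded from both numerator and denominator when
#' `exclude_short_stays = TRUE` (the default); set it to `FALSE` to keep
#' every case, e.g. when taking `tau` to the whole-stay limit where the
#' event-level sensitivity coincides with the patient-level true-positive
#' rate.
#'
#' @param cohort An `ews_cohort`; only its case records are used.
#' @param scores Matching `ews_scores`.
#' @param config An [eval_config()] (`k`, `tau`, `tau0`).
#' @param exclude_short_stays Drop cases with `t_event < tau + tau0`.
#' @return A one-row tibble with `s`, `n_predicted`, `n_events`,
#'   `n_excluded` and an `exclusions` attribute (tibble of `patient_id`,
#'   `reason`). `s` is `NaN` (flagged by `n_events = 0`) when every case
#'   is excluded.
#' @export
time_dependent_sensitivity <- function(cohort, scores, config,
                                       exclude_short_stays = TRUE) {
  pat <- cohort_patients(cohort)
  cases <- pat[pat$group == "case", ]
  excl <- tibble::tibble(patient_id = character(), reason = character())
  if (exclude_short_stays) {
    short <- cases$t_end_h < config$tau + config$tau0
    excl <- tibble::tibble(
      patient_id = cases$patient_id[short],
      reason = sprintf("stay shorter than tau + tau0 = %g h",
                       config$tau + config$tau0)
    )
    cases <- cases[!short, ]
  }
  al <- classify_alarms(generate_alarms(scores, config$k), cohort, config)
  predicted <- al$patient_id[al$class == "on_time"]
  n_pred <- sum(cases$patient_id %in% predicted)
  out <- tibble::tibble(
    s = if (nrow(cases) > 0) n_pred / nrow(cases) else NaN,
    n_predicted = as.integer(n_pred),
    n_events = nrow(cases),
    n_excluded = nrow(excl)
  )
  structure(out, exclusions = excl)
}

#' Per-patient alarm burden
#'
#' Quantifies the alarm load of each recording at threshold `k`:
#'
#' * `r` -- alarms per hour, `n_alarms / t_recording`;
#' * `rho` -- proportion of score samples that trigger an alarm;
#' * `r0` -- false alarms per hour. For a case, false alarms are the
#'   early, late and post-event classes and the denominator is
#'   `t_recording - tau`, since no false alarm can occur inside the
#'   horizon by definition; for a control every alarm is false and the
#'   denominator is the whole recording;
#' * `rho0` -- proportion of score samples triggering a false alarm.
#'
#' A case recording not longer than `tau` has no valid `r0` denominator;
#' `r0` is `NaN` there and the row is flagged.
#'
#' @param cohort An `ews_cohort`.
#' @param scores Matching `ews_scores`.
#' @param config An [eval_config()] (`k`, `tau`, `tau0`).
#' @return A tibble with one row per scored patient: `patient_id`,
#'   `group`, `n_scores`, `n_alarms`, `n_false`, `t_recording_h`, `r`,
#'   `rho`, `r0`, `rho0`, `r0_undefined`.
#' @export
alarm_burden <- function(cohort, scores, config) {
  pat <- cohort_patients(cohort)
  al <- classify_alarms(generate_alarms(scores, config$k), cohort, config)
  false_classes <- c("early", "late", "post_event", "control_false")

  per_alarm <- al |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_alarms = dplyr::n(),
      n_false = sum(.data$class %in% false_classes),
      .groups = "drop"
    )
  per_score <- scores |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_scores = dplyr::n(), .groups = "drop")

  out <- pat |>
    dplyr::inner_join(per_score, by = "patient_id") |>
    dplyr::left_join(per_alarm, by = "patient_id") |>
    dplyr::mutate(
      n_alarms = dplyr::coalesce(.data$n_alarms, 0L),
      n_false = dplyr::coalesce(.data$n_false, 0L),
      t_recording_h = .data$t_end_h,
      r = .data$n_alarms / .data$t_recording_h,
      rho = .data$n_alarms / .data$n_scores,
      denom0 = dplyr::if_else(.data$group == "case",
                              .data$t_recording_h - config$tau,
                              .data$t_recording_h),
      r0 = dplyr::if_else(.data$denom0 > 0, .data$n_false / .data$denom0,
                          NaN),
      rho0 = .data$n_false / .data$n_scores,
      r0_undefined = .data$denom0 <= 0
    ) |>
    dplyr::select("patient_id", "group", "n_scores", "n_alarms", "n_false",
                  "t_recording_h", "r", "rho", "r0", "rho0", "r0_undefined")
  out
}

#' Alarm time profiles over case patients
#'
#' Pools the classified alarms of all case patients into the early /
#' on-time / late classes and counts missed events (case patients with no
#' on-time alarm), then normalizes two ways: `per_alarm` divides the three
#' alarm-class counts by the total number of alarms (a probability profile
#' of when alarms fire), and `per_event` divides every count by the number
#' of events (alarms of each class per event). Alarms at or after the
#' event (`post_event`) are false alarms but lie outside the three
#' pre-event classes; they are reported as their own row with `per_alarm`
#' `NA`.
#'
#' @param alarms An `ews_alarms` tibble from [classify_alarms()].
#' @param cohort The `ews_cohort` (roster of case patients, so that cases
#'   with zero alarms are counted as missed events).
#' @return A tibble with columns `class` (`early`, `on_time`, `late`,
#'   `post_event`, `missed_event`), `count`, `per_alarm`, `per_event`.
#' @export
time_profiles <- function(alarms, cohort) {
  pat <- cohort_patients(cohort)
  case_ids <- pat$patient_id[pat$group == "case"]
  if (length(case_ids) == 0) stop("no case patients", call. = FALSE)
  al <- tibble::as_tibble(alarms)
  al <- al[al$group == "case", ]

  n_events <- length(case_ids)
  counts <- c(
    early = sum(al$class == "early"),
    on_time = sum(al$class == "on_time"),
    late = sum(al$class == "late"),
    post_event = sum(al$class == "post_event")
  )
  missed <- sum(!case_ids %in% al$patient_id[al$class == "on_time"])
  n_alarms <- sum(counts[c("early", "on_time", "late")])

  tibble::tibble(
    class = c(names(counts), "missed_event"),
    count = unname(as.integer(c(counts, missed))),
    per_alarm = unname(c(
      if (n_alarms > 0) counts[c("early", "on_time", "late")] / n_alarms
      else rep(NaN, 3), NA, NA)),
    per_event = unname(c(counts, missed) / n_events)
  )
}

#' Relative change between two reported metric values
#'
#' `(to - from) / from`: positive for an improvement in a
#' higher-is-better metric, negative for a reduction. The companion
#' `relative_reduction()` returns `(from - to) / from`, the convention
#' used when quoting e.g. "a 50% reduction in false alarms".
#'
#' @param from,to Numeric vectors.
#' @return Numeric vector of relative changes.
#' @export
relative_change <- function(from, to) (to - from) / from

#' @rdname relative_change
#' @export
relative_reduction <- function(from, to) (from - to) / from
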