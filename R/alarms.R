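#' Generate instantaneous threshold alarms from a score series
#'
#' An alarm is an instantaneous notification raised at every score sample
#' whose total strictly exceeds the threshold `k`. No grouping or lockout
#' is applied: one score sample above threshold is one alarm.
#'
#' @param scores An `ews_scores` tibble (see [score_cohort()]).
#' @param k Integer threshold in 0--13.
#' @return A tibble with columns `patient_id`, `time_h`, `total`.
#' @export
generate_alarms <- function(scores, k) {
  stopifnot(is.numeric(k), length(k) == 1)
  scores |>
    tibble::as_tibble() |>
    dplyr::filter(.data$total > k) |>
    dplyr::select("patient_id", "time_h", "total")
}

alarm_classes <- function() {
  c("early", "on_time", "late", "post_event", "control_false")
}

#' Classify alarms against the prediction horizon and lead time
#'
#' For a case patient with event at `t_event` (its recording end), the
#' prediction horizon is the window `[t_min, t_max]` with
#' `t_max = t_event - tau0` and `t_min = t_max - tau`, and the lead time is
#' `(t_max, t_event)`. Alarms are labelled:
#'
#' * `early` -- before `t_min` (too far ahead to be actionable);
#' * `on_time` -- inside the closed horizon `[t_min, t_max]`;
#' * `late` -- inside the lead time, too close to the event for an
#'   intervention to take effect;
#' * `post_event` -- at or after `t_event` ("missed" alarms).
#'
#' Early, late and post-event alarms are all false alarms. Every alarm of
#' a control patient is labelled `control_false`.
#'
#' @param alarms Alarm tibble from [generate_alarms()].
#' @param cohort The `ews_cohort` the scores came from (supplies each
#'   patient's group and recording end).
#' @param config An [eval_config()].
#' @return An `ews_alarms` tibble with columns `patient_id`, `group`,
#'   `time_h`, `total`, `class` (factor), `t_min`, `t_max`, `t_event`
#'   (window columns are `NA` for controls). Case patients whose event
#'   time is smaller than `tau + tau0` (the window does not fit inside the
#'   stay) are listed in the `"unevaluable"` attribute.
#' @export
classify_alarms <- function(alarms, cohort, config) {
  pat <- cohort_patients(cohort)
  x <- dplyr::inner_join(tibble::as_tibble(alarms), pat, by = "patient_id")
  is_case <- x$group == "case"
  t_event <- ifelse(is_case, x$t_end_h, NA_real_)
  t_max <- t_event - config$tau0
  t_min <- t_max - config$tau

  cls <- dplyr::case_when(
    !is_case ~ "control_false",
    x$time_h >= t_event ~ "post_event",
    x$time_h > t_max ~ "late",
    x$time_h >= t_min ~ "on_time",
    TRUE ~ "early"
  )
  out <- tibble::tibble(
    patient_id = x$patient_id, group = x$group, time_h = x$time_h,
    total = x$total, class = factor(cls, levels = alarm_classes()),
    t_min = t_min, t_max = t_max, t_event = t_event
  ) |>
    dplyr::arrange(.data$patient_id, .data$time_h)

  unevaluable <- pat$patient_id[pat$group == "case" &
                                  pat$t_end_h < config$tau + config$tau0]
  structure(out, class = c("ews_alarms", class(out)),
            unevaluable = unevaluable)
}

#' Write classified alarms to CSV
#'
#' @param alarms An `ews_alarms` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alarms <- function(alarms, path) {
  readr::write_csv(tibble::as_tibble(alarms), path)
  invisible(path)
}
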