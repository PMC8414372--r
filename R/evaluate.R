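#' End-to-end evaluation of a cohort
#'
#' Runs the full pipeline for one configuration: screens the cohort for
#' scoreable records, computes the score series for the configured
#' variant (unless `scores` is supplied), then evaluates
#'
#' * patient-level: confusion counts and metrics at `config$k`, plus the
#'   full 14-threshold ROC/PRC sweep;
#' * event-level (when `config$tau > 0`): time-dependent sensitivity,
#'   bootstrapped false-positive ratio and derived metrics, the work-up to
#'   detection ratio;
#' * burden: per-patient alarm rates/proportions and pooled alarm time
#'   profiles.
#'
#' @param cohort An `ews_cohort`.
#' @param config An [eval_config()].
#' @param scores Optional precomputed `ews_scores`; by default computed
#'   from `config` (`t_mews`/`statistic`).
#' @param table Scoring table.
#' @param sweep Whether to run the threshold sweep (needs both groups).
#' @return An `ews_evaluation` object: list with elements `config`,
#'   `patient` (confusion + metrics), `sweep`, `sensitivity`, `bootstrap`,
#'   `bootstrap_metrics`, `wdr`, `burden`, `profiles`, `exclusions`.
#'   Supports `tidy()` and `glance()`.
#' @export
evaluate_cohort <- function(cohort, config = eval_config(), scores = NULL,
                            table = mews_table(), sweep = TRUE) {
  screened <- screen_scoreable(cohort)
  excl <- exclusions(screened)
  if (nrow(cohort_patients(screened)) == 0) {
    stop("no scoreable patients in the cohort", call. = FALSE)
  }
  if (is.null(scores)) {
    scores <- score_cohort(screened, variant = config_variant(config),
                           t_mews = config$t_mews, table = table)
  }
  pat_groups <- unique(cohort_patients(screened)$group)

  patient <- confusion_metrics(patient_confusion(screened, scores, config$k))
  sweep_res <- if (sweep && length(pat_groups) == 2) {
    threshold_sweep(screened, scores)
  }

  alarms <- classify_alarms(generate_alarms(scores, config$k),
                            screened, config)
  has_cases <- "case" %in% pat_groups
  has_controls <- "control" %in% pat_groups

  sens <- boot <- boot_mets <- wdr_res <- NULL
  if (config$tau > 0) {
    if (has_cases) {
      sens <- time_dependent_sensitivity(screened, scores, config)
      excl <- dplyr::bind_rows(excl, exclusions(sens))
    }
    if (has_controls) {
      boot <- bootstrap_fpr(screened, scores, config)
      excl <- dplyr::bind_rows(excl, exclusions(boot))
      if (!is.null(sens)) {
        boot_mets <- bootstrap_metrics(boot, sens$n_predicted, sens$n_events)
        wdr_res <- wdr(sens$n_predicted, boot)
      }
    }
  }

  burden <- alarm_burden(screened, scores, config)
  profiles <- if (has_cases) time_profiles(alarms, screened)

  structure(
    list(config = config, patient = patient, sweep = sweep_res,
         sensitivity = sens, bootstrap = boot,
         bootstrap_metrics = boot_mets, wdr = wdr_res, burden = burden,
         profiles = profiles, alarms = alarms,
         exclusions = excl),
    class = "ews_evaluation"
  )
}

#' @export
print.ews_evaluation <- function(x, ...) {
  cat("<ews_evaluation>\n")
  print(x$config)
  cat(sprintf("  patient-level: TPR %.3f, FPR %.3f, PPV %.3f, WDR %s\n",
              x$patient$tpr, x$patient$fpr, x$patient$ppv,
              format(round(x$patient$wdr, 2))))
  if (!is.null(x$sweep)) {
    cat(sprintf("  sweep: AUROC %.3f, AUPRC %.3f\n",
                x$sweep$auroc, x$sweep$auprc))
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  event-level: S = %.3f (%d/%d events, %d excluded)\n",
                x$sensitivity$s, x$sensitivity$n_predicted,
                x$sensitivity$n_events, x$sensitivity$n_excluded))
  }
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap FPR: %.3f (std %.3f, M = %d)\n",
                x$bootstrap$mean, x$bootstrap$std, x$bootstrap$m))
  }
  if (!is.null(x$wdr)) {
    cat(sprintf("  WDR: %.2f (std %.2f)\n", x$wdr$mean, x$wdr$std))
  }
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional CSV side files)
#'
#' The JSON report echoes the fully resolved configuration, the exclusion
#' report, the patient-level panel, the event-level panel (sensitivity,
#' bootstrap estimates with their means and standard deviations, WDR) and
#' the pooled time profiles. Per-patient burden rows and per-threshold
#' sweep metrics can be written alongside as CSV.
#'
#' @param x An `ews_evaluation`.
#' @param path JSON output path.
#' @param burden_csv,sweep_csv,profile_csv Optional CSV paths.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, burden_csv = NULL, sweep_csv = NULL,
                         profile_csv = NULL) {
  stopifnot(inherits(x, "ews_evaluation"))
  report <- list(
    config = x$config[c("k", "tau", "tau0", "t_mews", "statistic", "m",
                        "seed")],
    exclusions = x$exclusions,
    patient_level = as.list(x$patient),
    sweep = if (!is.null(x$sweep)) list(auroc = x$sweep$auroc,
                                        auprc = x$sweep$auprc),
    event_level = list(
      sensitivity = if (!is.null(x$sensitivity)) as.list(x$sensitivity),
      fpr_bootstrap = if (!is.null(x$bootstrap)) {
        list(mean = x$bootstrap$mean, std = x$bootstrap$std,
             m = x$bootstrap$m, n_controls = x$bootstrap$n_controls)
      },
      derived_metrics = x$bootstrap_metrics,
      wdr = if (!is.null(x$wdr)) as.list(x$wdr)
    ),
    profiles = x$profiles,
    burden_summary = if (nrow(x$burden) > 0) {
      x$burden |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(dplyr::across(c("r", "rho", "r0", "rho0"),
                                       \(v) mean(v[is.finite(v)])),
                         .groups = "drop")
    }
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(burden_csv)) readr::write_csv(x$burden, burden_csv)
  if (!is.null(sweep_csv) && !is.null(x$sweep)) {
    readr::write_csv(x$sweep$metrics, sweep_csv)
  }
  if (!is.null(profile_csv) && !is.null(x$profiles)) {
    readr::write_csv(x$profiles, profile_csv)
  }
  invisible(path)
}
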