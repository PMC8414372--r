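#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold sweep
#'
#' @param x An `ews_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return The per-threshold metric tibble (one row per threshold `k`).
#' @export
tidy.ews_sweep <- function(x, ...) x$metrics

#' @rdname tidy.ews_sweep
#' @return For `glance()`: a one-row tibble with `auroc`, `auprc`,
#'   `n_thresholds`.
#' @export
glance.ews_sweep <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, auprc = x$auprc,
                 n_thresholds = nrow(x$metrics))
}

#' Tidy a bootstrap FPR estimate
#'
#' @param x An `ews_bootstrap` from [bootstrap_fpr()].
#' @param ... Unused.
#' @return Per-control trigger summaries (`patient_id`, `mu_i`,
#'   `sigma_i`).
#' @export
tidy.ews_bootstrap <- function(x, ...) x$per_control

#' @rdname tidy.ews_bootstrap
#' @return For `glance()`: one row with `mean`, `std`, `m`, `n_controls`.
#' @export
glance.ews_bootstrap <- function(x, ...) {
  tibble::tibble(mean = x$mean, std = x$std, m = x$m,
                 n_controls = x$n_controls)
}

#' Tidy an evaluation
#'
#' `tidy()` returns the event-level metric panel in long form (one row
#' per metric with mean and std where bootstrapped); `glance()` returns a
#' one-row summary of the headline numbers.
#'
#' @param x An `ews_evaluation` from [evaluate_cohort()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ews_evaluation <- function(x, ...) {
  rows <- list(
    tibble::tibble(level = "patient", metric = c("tpr", "fpr", "ppv", "npv",
                                                 "acc", "f1", "wdr"),
                   mean = as.numeric(x$patient[1, c("tpr", "fpr", "ppv",
                                                    "npv", "acc", "f1",
                                                    "wdr")]),
                   std = NA_real_)
  )
  if (!is.null(x$sensitivity)) {
    rows <- c(rows, list(tibble::tibble(
      level = "event", metric = "sensitivity",
      mean = x$sensitivity$s, std = NA_real_)))
  }
  if (!is.null(x$bootstrap_metrics)) {
    rows <- c(rows, list(tibble::tibble(
      level = "event", metric = x$bootstrap_metrics$metric,
      mean = x$bootstrap_metrics$mean, std = x$bootstrap_metrics$std)))
  }
  if (!is.null(x$wdr)) {
    rows <- c(rows, list(tibble::tibble(
      level = "event", metric = "wdr", mean = x$wdr$mean,
      std = x$wdr$std)))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.ews_evaluation
#' @export
glance.ews_evaluation <- function(x, ...) {
  tibble::tibble(
    k = x$config$k, tau = x$config$tau, tau0 = x$config$tau0,
    variant = config_variant(x$config),
    patient_tpr = x$patient$tpr, patient_fpr = x$patient$fpr,
    auroc = if (!is.null(x$sweep)) x$sweep$auroc else NA_real_,
    event_s = if (!is.null(x$sensitivity)) x$sensitivity$s else NA_real_,
    fpr_boot = if (!is.null(x$bootstrap)) x$bootstrap$mean else NA_real_,
    wdr = if (!is.null(x$wdr)) x$wdr$mean else NA_real_,
    n_excluded = nrow(x$exclusions)
  )
}
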