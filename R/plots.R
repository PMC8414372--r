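#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC and precision-recall curves of a threshold sweep
#'
#' Plots the 14 discrete operating points of a sweep as a ROC curve
#' (`which = "roc"`, with the chance diagonal dashed) or a
#' precision-recall curve (`which = "prc"`, with the prevalence line
#' dashed). The point at the conventional threshold `k = 4` is
#' highlighted.
#'
#' @param object An `ews_sweep` from [threshold_sweep()].
#' @param which `"roc"` or `"prc"`.
#' @param highlight_k Threshold to highlight (NULL for none).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ews_sweep <- function(object, which = c("roc", "prc"),
                               highlight_k = 4, ...) {
  which <- match.arg(which)
  m <- object$metrics
  if (which == "roc") {
    df <- tibble::tibble(x = c(0, m$fpr, 1), y = c(0, m$tpr, 1))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC over %d thresholds (AUROC = %.3f)",
                        nrow(m), object$auroc))
  } else {
    prev <- (m$tp[1] + m$fn[1]) / (m$tp[1] + m$fp[1] + m$fn[1] + m$tn[1])
    df <- tibble::tibble(x = m$tpr, y = m$ppv)
    p <- ggplot2::ggplot(df[is.finite(df$y), ],
                         ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_hline(yintercept = prev, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "Recall (sensitivity)", y = "Precision",
        title = sprintf("Precision-recall over %d thresholds (AUPRC = %.3f)",
                        nrow(m), object$auprc))
  }
  if (!is.null(highlight_k) && highlight_k %in% m$k) {
    hk <- m[m$k == highlight_k, ]
    hx <- if (which == "roc") hk$fpr else hk$tpr
    hy <- if (which == "roc") hk$tpr else hk$ppv
    p <- p + ggplot2::annotate("point", x = hx, y = hy, colour = "red",
                               size = 2.5)
  }
  p + ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Score trace of one patient
#'
#' Step plot of the MEWS total over the stay, with imputed-only samples
#' (every parameter carried forward) marked.
#'
#' @param object An `ews_scores` tibble.
#' @param patient_id Patient to plot (default: the first one present).
#' @param k Optional threshold to draw as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ews_scores <- function(object, patient_id = NULL, k = NULL, ...) {
  x <- tibble::as_tibble(object)
  if (is.null(patient_id)) patient_id <- x$patient_id[1]
  x <- x[x$patient_id == patient_id, ]
  imp_cols <- c("SBP_imp", "HR_imp", "RR_imp", "TEMP_imp")
  x$all_imputed <- rowSums(!as.matrix(x[imp_cols])) == 0
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$time_h, y = .data$total)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$all_imputed)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "steelblue"),
      labels = c(`FALSE` = "measured", `TRUE` = "fully imputed"),
      name = NULL) +
    ggplot2::labs(x = "Hours since admission", y = "MEWS total",
                  title = paste("Score series:", patient_id)) +
    ggplot2::theme_minimal()
  if (!is.null(k)) {
    p <- p + ggplot2::geom_hline(yintercept = k + 0.5, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Alarm time profile bar chart
#'
#' @param profile Output of [time_profiles()].
#' @param normalization `"per_alarm"` or `"per_event"`.
#' @return A ggplot object.
#' @export
plot_time_profile <- function(profile,
                              normalization = c("per_alarm", "per_event")) {
  normalization <- match.arg(normalization)
  df <- profile[!is.na(profile[[normalization]]), ]
  df$class <- factor(df$class, levels = profile$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                   y = .data[[normalization]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL,
      y = if (normalization == "per_alarm") "Proportion of alarms"
          else "Count per event",
      title = "Alarm time profile") +
    ggplot2::theme_minimal()
}

#' Burden decay across thresholds
#'
#' Line plot of mean alarm/false-alarm rates (or proportions) against the
#' threshold `k`, by patient group.
#'
#' @param cohort An `ews_cohort`.
#' @param scores Matching `ews_scores`.
#' @param config Base [eval_config()]; `k` is swept 0--13.
#' @param measure One of `"r"`, `"rho"`, `"r0"`, `"rho0"`.
#' @return A ggplot object.
#' @export
plot_burden_decay <- function(cohort, scores, config = eval_config(),
                              measure = c("r0", "rho0", "r", "rho")) {
  measure <- match.arg(measure)
  df <- purrr::map(0:13, function(k) {
    cfg <- config
    cfg$k <- as.integer(k)
    alarm_burden(cohort, scores, cfg) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(value = mean(.data[[measure]][is.finite(.data[[measure]])]),
                       .groups = "drop") |>
      dplyr::mutate(k = k)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Threshold k", y = measure,
                  title = "Alarm burden vs threshold") +
    ggplot2::theme_minimal()
}
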