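#' Patient-level confusion counts at a threshold
#'
#' A case patient whose score ever exceeds `k` during the stay is one true
#' positive, regardless of how many times the threshold is crossed; a
#' silent case is a false negative. A control whose score ever exceeds `k`
#' is one false positive; a silent control a true negative.
#'
#' @param cohort An `ews_cohort` tibble (supplies the patient roster).
#' @param scores An `ews_scores` tibble for the same cohort.
#' @param k Integer threshold in 0--13.
#' @return A one-row tibble with columns `k`, `tp`, `fp`, `fn`, `tn`.
#' @export
patient_confusion <- function(cohort, scores, k) {
  pat <- cohort_patients(cohort)
  if (nrow(pat) == 0) stop("empty cohort", call. = FALSE)
  mx <- scores |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(max_total = max(.data$total), .groups = "drop")
  pat <- dplyr::left_join(pat, mx, by = "patient_id")
  alarmed <- !is.na(pat$max_total) & pat$max_total > k
  tibble::tibble(
    k = as.integer(k),
    tp = sum(pat$group == "case" & alarmed),
    fp = sum(pat$group == "control" & alarmed),
    fn = sum(pat$group == "case" & !alarmed),
    tn = sum(pat$group == "control" & !alarmed)
  )
}

#' Scalar metrics from confusion counts
#'
#' Computes, per row of `counts`: sensitivity `tpr = tp/(tp+fn)`,
#' false-positive rate `fpr = fp/(fp+tn)`, precision `ppv = tp/(tp+fp)`,
#' `npv = tn/(tn+fn)`, accuracy, F1 (harmonic mean of precision and
#' sensitivity) and the work-up to detection ratio
#' `wdr = (tp+fp)/tp` -- the number of patients worked up per detected
#' event, akin to a number needed to alert. Ratios with a zero denominator
#' are returned as `NaN` and flagged in the `undefined` column rather than
#' raising, so threshold sweeps never abort at extreme thresholds.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`, `tn` (extra
#'   columns such as `k` are carried through).
#' @return `counts` augmented with `tpr`, `fpr`, `ppv`, `npv`, `acc`,
#'   `f1`, `wdr` and `undefined` (comma-separated names of undefined
#'   metrics, `""` if none).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  x <- tibble::as_tibble(counts)
  div <- function(a, b) ifelse(b > 0, a / b, NaN)
  x$tpr <- div(x$tp, x$tp + x$fn)
  x$fpr <- div(x$fp, x$fp + x$tn)
  x$ppv <- div(x$tp, x$tp + x$fp)
  x$npv <- div(x$tn, x$tn + x$fn)
  x$acc <- div(x$tp + x$tn, x$tp + x$fp + x$fn + x$tn)
  x$f1 <- ifelse(is.finite(x$ppv) & is.finite(x$tpr) & (x$ppv + x$tpr) > 0,
                 2 * x$ppv * x$tpr / (x$ppv + x$tpr), NaN)
  x$wdr <- div(x$tp + x$fp, x$tp)
  mets <- c("tpr", "fpr", "ppv", "npv", "acc", "f1", "wdr")
  x$undefined <- apply(is.na(as.matrix(x[mets])), 1,
                       function(r) paste(mets[r], collapse = ","))
  x
}

trapezoid <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Threshold sweep: ROC and precision-recall over all 14 thresholds
#'
#' Evaluates the patient-level confusion metrics at every threshold
#' `k = 0..13` (the score is an integer in 0--14, so 13 is the largest
#' threshold any sample can exceed). The ROC curve is the set of
#' `(fpr, tpr)` operating points plus the anchors (0,0) and (1,1); areas
#' under the ROC and precision-recall curves are computed by the
#' trapezoidal rule on the sorted points, with no further interpolation.
#'
#' @inheritParams patient_confusion
#' @return An `ews_sweep` object: list with `metrics` (tibble of 14 rows),
#'   `auroc`, `auprc`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
threshold_sweep <- function(cohort, scores) {
  pat <- cohort_patients(cohort)
  if (length(unique(pat$group)) < 2) {
    stop("threshold sweep needs at least one case and one control",
         call. = FALSE)
  }
  metrics <- purrr::map(0:13, \(k) patient_confusion(cohort, scores, k)) |>
    dplyr::bind_rows() |>
    confusion_metrics()

  roc_x <- c(0, metrics$fpr, 1)
  roc_y <- c(0, metrics$tpr, 1)
  auroc <- trapezoid(roc_x, roc_y)

  pr <- metrics[is.finite(metrics$ppv), ]
  pr_x <- pr$tpr
  pr_y <- pr$ppv
  if (length(pr_x) > 0 && min(pr_x) > 0) {
    # extend the curve to recall 0 at the precision of the strictest
    # operating point
    pr_x <- c(0, pr_x)
    pr_y <- c(pr_y[which.min(pr$tpr)], pr_y)
  }
  auprc <- if (length(pr_x) >= 2) trapezoid(pr_x, pr_y) else NA_real_

  structure(list(metrics = metrics, auroc = auroc, auprc = auprc),
            class = "ews_sweep")
}

#' @export
print.ews_sweep <- function(x, ...) {
  cat(sprintf("<ews_sweep> %d thresholds; AUROC = %.3f, AUPRC = %.3f\n",
              nrow(x$metrics), x$auroc, x$auprc))
  print(x$metrics, n = 14)
  invisible(x)
}

#' Export a threshold sweep
#'
#' Writes the per-threshold metric table as CSV and, optionally, the area
#' summary as JSON.
#'
#' @param sweep An `ews_sweep` object.
#' @param path CSV output path.
#' @param json_path Optional JSON path for `{auroc, auprc}`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path, json_path = NULL) {
  readr::write_csv(sweep$metrics, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(auroc = sweep$auroc, auprc = sweep$auprc),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
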