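#' Bootstrapped false-positive ratio over control patients
#'
#' Estimates the probability that a randomly placed window of
#' horizon length `tau` inside a control recording contains at least one
#' alarm. For each eligible control `i` (recording at least `tau` long;
#' shorter recordings are excluded and reported), `m` window start times
#' are drawn uniformly on `[0, T_i - tau]`, sorted in time and indexed by
#' rank `j`; the binary trigger indicator `T_ij` is 1 when any alarm falls
#' in the closed window. The FPR estimate is the grand mean of `T_ij` over
#' all controls and windows.
#'
#' The per-window spread can be composed in two ways (`variance`):
#' `"proportion"` (default) takes the sample standard deviation of the
#' binary indicators across controls within each window index and combines
#' window indices by root mean square -- the standard binomial estimator.
#' `"literal"` instead subtracts the per-window *count* of triggered
#' controls from each binary indicator before squaring, reproducing the
#' printed composition verbatim for comparability even though it mixes a
#' count with a proportion.
#'
#' @param cohort An `ews_cohort` tibble; only its control records are used.
#' @param scores Matching `ews_scores`.
#' @param config An [eval_config()]; uses `k`, `tau`, `m` and `seed`.
#' @param variance `"proportion"` or `"literal"` (see above).
#' @return An `ews_bootstrap` object: list with `mean`, `std`, `m`,
#'   `n_controls`, `per_window_counts` (length-`m` integer vector of
#'   triggered controls per window index), `per_control` (tibble of
#'   `patient_id`, `mu_i`, `sigma_i`), `trigger_matrix` (controls x
#'   windows), and an `exclusions` attribute.
#' @export
bootstrap_fpr <- function(cohort, scores, config,
                          variance = c("proportion", "literal")) {
  variance <- match.arg(variance)
  pat <- cohort_patients(cohort)
  ctrl <- pat[pat$group == "control", ]
  if (nrow(ctrl) == 0) stop("no control patients", call. = FALSE)

  eligible <- ctrl$t_end_h >= config$tau
  excl <- tibble::tibble(
    patient_id = ctrl$patient_id[!eligible],
    reason = "recording shorter than prediction horizon"
  )
  ctrl <- ctrl[eligible, ]
  if (nrow(ctrl) == 0) stop("no control recording is at least tau long",
                            call. = FALSE)

  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
  }

  alarms <- generate_alarms(scores, config$k)
  alarm_times <- split(alarms$time_h, alarms$patient_id)

  n <- nrow(ctrl)
  m <- config$m
  trig <- matrix(0L, n, m, dimnames = list(ctrl$patient_id, NULL))
  for (i in seq_len(n)) {
    a <- sort(alarm_times[[ctrl$patient_id[i]]])
    starts <- sort(stats::runif(m, 0, ctrl$t_end_h[i] - config$tau))
    if (length(a) > 0) {
      hits <- findInterval(starts + config$tau, a) -
        findInterval(starts, a, left.open = TRUE)
      trig[i, ] <- as.integer(hits > 0)
    }
  }

  counts <- colSums(trig)
  mu <- sum(trig) / (n * m)
  if (n > 1) {
    center <- if (variance == "proportion") counts / n else counts
    dev2 <- sweep(trig, 2, center)^2
    sigma_j <- sqrt(colSums(dev2) / (n - 1))
    std <- sqrt(mean(sigma_j^2))
  } else {
    std <- 0
  }
  per_control <- tibble::tibble(
    patient_id = ctrl$patient_id,
    mu_i = rowMeans(trig),
    sigma_i = if (m > 1) apply(trig, 1, stats::sd) else rep(0, n)
  )
  structure(
    list(mean = mu, std = std, m = m, n_controls = n,
         per_window_counts = as.integer(counts),
         per_control = per_control, trigger_matrix = trig,
         k = config$k, tau = config$tau, variance = variance),
    class = "ews_bootstrap", exclusions = excl
  )
}

#' @export
print.ews_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<ews_bootstrap> FPR = %.4f (std %.4f); %d controls x %d windows (tau = %g h, k = %d)\n",
    x$mean, x$std, x$n_controls, x$m, x$tau, x$k))
  invisible(x)
}

#' Bootstrapped derived metrics (accuracy, predictive values, F1)
#'
#' Applies the same bootstrapping scheme as [bootstrap_fpr()] to the
#' derived classification metrics: for each window index `j` a confusion
#' matrix is formed from the fixed case-side outcome (`n_predicted` of
#' `n_events` events preceded by an on-time alarm) and the `j`-th control
#' column (number of triggered controls as false positives, remainder as
#' true negatives); each metric is computed per replicate and summarized
#' by its mean and standard deviation across the `m` replicates. With
#' `m = 1` all standard deviations are 0 by convention. Replicates where a
#' metric's denominator is zero are skipped for that metric; the number
#' skipped is recorded in the `degenerate` column.
#'
#' @param boot An `ews_bootstrap` from [bootstrap_fpr()].
#' @param n_predicted,n_events Case-side outcome counts, e.g. from
#'   [time_dependent_sensitivity()].
#' @return A tibble with columns `metric` (`fpr`, `ppv`, `npv`, `acc`,
#'   `f1`), `mean`, `std`, `degenerate`.
#' @export
bootstrap_metrics <- function(boot, n_predicted, n_events) {
  stopifnot(inherits(boot, "ews_bootstrap"),
            n_predicted >= 0, n_events >= n_predicted)
  n <- boot$n_controls
  conf <- tibble::tibble(
    tp = n_predicted, fn = n_events - n_predicted,
    fp = boot$per_window_counts, tn = n - boot$per_window_counts
  )
  rep_metrics <- confusion_metrics(conf)
  summarise_metric <- function(v) {
    ok <- is.finite(v)
    tibble::tibble(
      mean = if (any(ok)) mean(v[ok]) else NaN,
      std = if (sum(ok) > 1) stats::sd(v[ok]) else 0,
      degenerate = sum(!ok)
    )
  }
  purrr::map(c(fpr = "fpr", ppv = "ppv", npv = "npv",
               acc = "acc", f1 = "f1"),
             \(mname) summarise_metric(rep_metrics[[mname]])) |>
    dplyr::bind_rows(.id = "metric")
}

#' Work-up to detection ratio with bootstrap uncertainty
#'
#' `WDR = (N_case + mu_FP) / N_case`, where `N_case` is the number of case
#' patients with at least one on-time alarm and `mu_FP` the expected
#' number of bootstrap false positives over the controls (the sum of the
#' per-control trigger means). Conceptually the number of patients who
#' receive a work-up before one additional adverse outcome is prevented,
#' similar to a number needed to alert. The standard deviation composes
#' the per-control trigger standard deviations in quadrature.
#'
#' @param n_predicted Number of predicted events (case patients with an
#'   on-time alarm); must be >= 1 for the ratio to be defined.
#' @param boot An `ews_bootstrap` from [bootstrap_fpr()].
#' @return A one-row tibble with `mean`, `std`, `n_case_predicted`,
#'   `mu_fp` and `undefined` (TRUE when `n_predicted` is 0, in which case
#'   `mean` and `std` are `NaN`).
#' @export
wdr <- function(n_predicted, boot) {
  stopifnot(inherits(boot, "ews_bootstrap"))
  mu_fp <- sum(boot$per_control$mu_i)
  if (n_predicted < 1) {
    return(tibble::tibble(mean = NaN, std = NaN, n_case_predicted = 0L,
                          mu_fp = mu_fp, undefined = TRUE))
  }
  tibble::tibble(
    mean = 1 + mu_fp / n_predicted,
    std = sqrt(sum(boot$per_control$sigma_i^2)) / n_predicted,
    n_case_predicted = as.integer(n_predicted),
    mu_fp = mu_fp,
    undefined = FALSE
  )
}
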