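# Fixture builders and independent oracles shared across the test files.

# Build a long-format cohort tibble from per-patient sample tables.
# Each element of `records` is list(id=, group=, t_end=, samples=tibble(
# parameter, time_h, value)).
build_cohort <- function(records, ...) {
  rows <- purrr::map(records, function(r) {
    dplyr::mutate(r$samples, patient_id = r$id, group = r$group,
                  t_end_h = r$t_end)
  })
  as_cohort(dplyr::bind_rows(rows), ...)
}

samples_tbl <- function(parameter, time_h, value) {
  tibble::tibble(parameter = parameter, time_h = time_h, value = value)
}

# One fully-sampled record with every parameter measured at the same times
full_record <- function(id, group = "control", t_end = 24,
                        times = c(1, 6, 12),
                        sbp = 120, hr = 75, rr = 12, temp = 36.8, gcs = 15) {
  vals <- list(SBP = sbp, HR = hr, RR = rr, TEMP = temp, GCS = gcs)
  samples <- dplyr::bind_rows(purrr::imap(vals, function(v, p) {
    samples_tbl(p, times, rep_len(v, length(times)))
  }))
  list(id = id, group = group, t_end = t_end, samples = samples)
}

# Minimal patient roster accepted by functions that only need
# patient_id / group / t_end_h
roster <- function(patient_id, group, t_end_h) {
  tibble::tibble(patient_id = patient_id, group = group, t_end_h = t_end_h)
}

# Hand-built score series (enough columns for the alarm/evaluation layer)
make_scores <- function(patient_id, time_h, total) {
  tibble::tibble(patient_id = patient_id, time_h = time_h,
                 total = as.integer(total))
}

# Exact probability that a uniformly placed closed window [u, u + tau],
# u ~ U[0, t_end - tau], contains at least one alarm time: the measure of
# the union of [a - tau, a] clipped to [0, t_end - tau], divided by the
# start-range length. Independent brute-force oracle for the bootstrap.
window_hit_probability <- function(alarm_times, t_end, tau) {
  stopifnot(t_end > tau)
  lo <- pmax(alarm_times - tau, 0)
  hi <- pmin(alarm_times, t_end - tau)
  keep <- hi >= lo
  if (!any(keep)) return(0)
  iv <- cbind(lo[keep], hi[keep])
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0
  cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] > cur_hi) {
      total <- total + cur_hi - cur_lo
      cur_lo <- iv[i, 1]; cur_hi <- iv[i, 2]
    } else {
      cur_hi <- max(cur_hi, iv[i, 2])
    }
  }
  total <- total + cur_hi - cur_lo
  total / (t_end - tau)
}

# Pairwise Mann-Whitney concordance of per-patient maximum scores
# (ties count 1/2): independent oracle for the trapezoidal AUROC.
concordance_oracle <- function(case_max, control_max) {
  s <- 0
  for (cm in case_max) {
    s <- s + sum(cm > control_max) + 0.5 * sum(cm == control_max)
  }
  s / (length(case_max) * length(control_max))
}

# A small random scoreable cohort with irregular per-parameter sampling
random_cohort <- function(n_case = 3, n_control = 3, t_end_max = 48,
                          gcs = TRUE) {
  recs <- purrr::map(seq_len(n_case + n_control), function(i) {
    group <- if (i <= n_case) "case" else "control"
    t_end <- stats::runif(1, 6, t_end_max)
    params <- c("SBP", "HR", "RR", "TEMP", if (gcs) "GCS")
    samples <- dplyr::bind_rows(purrr::map(params, function(p) {
      n <- 1 + stats::rpois(1, 4)
      v <- switch(p,
        SBP = stats::runif(n, 60, 210),
        HR = stats::runif(n, 30, 150),
        RR = stats::runif(n, 5, 40),
        TEMP = stats::runif(n, 33, 40),
        GCS = sample(3:15, n, replace = TRUE)
      )
      samples_tbl(p, sort(stats::runif(n, 0, t_end)), v)
    }))
    list(id = sprintf("p%02d", i), group = group, t_end = t_end,
         samples = samples)
  })
  build_cohort(recs)
}

COHORT_COLS <- c("patient_id", "group", "parameter", "time_h", "value",
                 "t_end_h")
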