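#' Score a cohort with MEWS
#'
#' Produces a timestamped score series per patient using one of three
#' sampling variants:
#'
#' * `"base"` (event-driven): a new total is computed at every distinct
#'   measurement time, carrying each parameter's last value forward until
#'   refreshed. Scores begin at the first time all mandatory parameters
#'   have been observed at least once.
#' * `"median"` / `"worst"` (interval): totals are stamped at the ends of
#'   regular intervals of length `t_mews` hours (anchored at admission).
#'   Within each interval the available measurements of a parameter are
#'   summarized by the lower element median or by the value attracting the
#'   most points ("worst"); an interval with no new measurement for a
#'   parameter carries the last recorded raw value forward and flags it
#'   imputed.
#'
#' Imputation is last-observation-carried-forward with no expiry by
#' default; `max_carry_h` bounds the age of a carried value (a time point
#' where a mandatory parameter's carried value has expired yields no
#' score).
#'
#' @param cohort An `ews_cohort` tibble (see [as_cohort()]); only scoreable
#'   records should be passed (see [screen_scoreable()]).
#' @param variant `"base"`, `"median"` or `"worst"`.
#' @param t_mews Interval length in hours; required for the interval
#'   variants, ignored for `"base"`.
#' @param table Scoring table, defaulting to [mews_table()].
#' @param max_carry_h Maximum age, in hours, of a carried-forward value
#'   (default `Inf`, i.e. no expiry).
#' @return An `ews_scores` tibble with columns `patient_id`, `time_h`,
#'   per-parameter point columns (`SBP_pts`, `HR_pts`, `RR_pts`,
#'   `TEMP_pts`, `AVPU_pts`), `total`, and per-parameter imputation flags
#'   (`SBP_imp`, ..., `GCS_imp`; `NA` while a parameter has no value yet).
#' @export
score_cohort <- function(cohort, variant = c("base", "median", "worst"),
                         t_mews = NULL, table = mews_table(),
                         max_carry_h = Inf) {
  variant <- match.arg(variant)
  if (variant != "base") {
    if (is.null(t_mews) || !is.numeric(t_mews) || t_mews <= 0) {
      stop("the '", variant, "' variant requires t_mews > 0", call. = FALSE)
    }
  }
  validate_mews_table(table)
  pat <- cohort_patients(cohort)
  samples <- split(tibble::as_tibble(cohort), cohort$patient_id)

  res <- purrr::map(pat$patient_id, function(id) {
    s <- samples[[id]]
    t_end <- pat$t_end_h[pat$patient_id == id]
    ser <- if (variant == "base") {
      series_base(s, table, max_carry_h)
    } else {
      series_interval(s, t_end, t_mews, variant, table, max_carry_h)
    }
    if (nrow(ser) > 0) ser$patient_id <- id
    ser
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0) {
    out <- dplyr::relocate(out, "patient_id")
  } else {
    out <- empty_scores()
  }
  structure(out, class = c("ews_scores", class(out)),
            variant = variant, t_mews = if (variant == "base") NULL else t_mews)
}

empty_scores <- function() {
  tibble::tibble(
    patient_id = character(), time_h = double(),
    SBP_pts = integer(), HR_pts = integer(), RR_pts = integer(),
    TEMP_pts = integer(), AVPU_pts = integer(), total = integer(),
    SBP_imp = logical(), HR_imp = logical(), RR_imp = logical(),
    TEMP_imp = logical(), GCS_imp = logical()
  )
}

locf <- function(v) {
  idx <- cumsum(!is.na(v))
  c(NA, v[!is.na(v)])[idx + 1]
}

# lower element median: always one of the observed values
lmedian <- function(x) sort(x)[ceiling(length(x) / 2)]

# measurement matrix at the given grid of times; cells NA where the
# parameter was not measured at that exact time (later duplicates win)
measured_matrix <- function(s, times) {
  params <- vital_parameters()
  m <- matrix(NA_real_, length(times), length(params),
              dimnames = list(NULL, params))
  for (p in intersect(unique(s$parameter), params)) {
    sp <- s[s$parameter == p, ]
    m[match(sp$time_h, times), p] <- sp$value
  }
  m
}

assemble_series <- function(times, val, meas_na, table) {
  # val: filled value matrix; meas_na: TRUE where the value was not newly
  # measured at that step (carried forward)
  keep <- !is.na(val[, "SBP"]) & !is.na(val[, "HR"]) &
    !is.na(val[, "RR"]) & !is.na(val[, "TEMP"])
  if (!any(keep)) return(empty_scores()[0, -1])
  times <- times[keep]
  val <- val[keep, , drop = FALSE]
  meas_na <- meas_na[keep, , drop = FALSE]
  n <- length(times)

  col <- function(m, p) unname(m[, p])
  pts <- compute_mews(col(val, "SBP"), col(val, "HR"), col(val, "RR"),
                      col(val, "TEMP"), gcs = col(val, "GCS"), table = table)
  tibble::tibble(
    time_h = unname(times),
    SBP_pts = pts$SBP_pts, HR_pts = pts$HR_pts, RR_pts = pts$RR_pts,
    TEMP_pts = pts$TEMP_pts, AVPU_pts = pts$AVPU_pts, total = pts$total,
    SBP_imp = col(meas_na, "SBP"), HR_imp = col(meas_na, "HR"),
    RR_imp = col(meas_na, "RR"), TEMP_imp = col(meas_na, "TEMP"),
    GCS_imp = ifelse(is.na(col(val, "GCS")), NA, col(meas_na, "GCS"))
  )
}

series_base <- function(s, table, max_carry_h) {
  times <- sort(unique(s$time_h))
  if (length(times) == 0) return(empty_scores()[0, -1])
  m <- measured_matrix(s, times)
  val <- apply(m, 2, locf)
  if (length(times) == 1) val <- matrix(val, 1, dimnames = list(NULL, colnames(m)))
  if (is.finite(max_carry_h)) {
    mt <- apply(ifelse(is.na(m), NA_real_, times), 2, locf)
    if (length(times) == 1) mt <- matrix(mt, 1, dimnames = list(NULL, colnames(m)))
    val[!is.na(val) & (times - mt) > max_carry_h] <- NA_real_
  }
  assemble_series(times, val, is.na(m), table)
}

series_interval <- function(s, t_end, t_mews, statistic, table, max_carry_h) {
  n_int <- floor(t_end / t_mews + 1e-9)
  if (n_int < 1 || nrow(s) == 0) return(empty_scores()[0, -1])
  grid <- t_mews * seq_len(n_int)
  params <- vital_parameters()

  s <- s[s$time_h <= grid[n_int] + 1e-9, , drop = FALSE]
  j <- pmax(1L, as.integer(ceiling(s$time_h / t_mews - 1e-9)))

  val <- matrix(NA_real_, n_int, length(params),
                dimnames = list(NULL, params))
  meas_na <- matrix(TRUE, n_int, length(params),
                    dimnames = list(NULL, params))
  for (p in intersect(unique(s$parameter), params)) {
    sel <- s$parameter == p
    sp <- s[sel, ]
    jp <- j[sel]
    o <- order(sp$time_h)
    sp <- sp[o, ]
    jp <- jp[o]
    if (statistic == "median") {
      agg <- vapply(split(sp$value, jp), lmedian, numeric(1))
    } else {
      pts <- subscore(rep(p, nrow(sp)), sp$value, table)
      agg <- vapply(split(seq_len(nrow(sp)), jp), function(idx) {
        best <- idx[pts[idx] == max(pts[idx])]
        sp$value[best[which.max(sp$time_h[best])]]
      }, numeric(1))
    }
    jj <- as.integer(names(agg))
    val[jj, p] <- agg
    meas_na[jj, p] <- FALSE
    # empty intervals: carry the last recorded raw value forward
    carry <- locf(replace(rep(NA_real_, n_int), jj,
                          vapply(split(sp$value, jp), function(v) v[length(v)],
                                 numeric(1))))
    # carried cell value is the latest raw measurement, not the summary
    raw_last_t <- locf(replace(rep(NA_real_, n_int), jj,
                               vapply(split(sp$time_h, jp), max, numeric(1))))
    empty <- is.na(val[, p]) & !is.na(carry)
    if (is.finite(max_carry_h)) {
      empty <- empty & (grid - raw_last_t) <= max_carry_h
    }
    val[empty, p] <- carry[empty]
  }
  assemble_series(grid, val, meas_na, table)
}

#' @export
print.ews_scores <- function(x, ...) {
  cat(sprintf("<ews_scores> variant = %s%s; %d score samples, %d patients\n",
              attr(x, "variant"),
              if (is.null(attr(x, "t_mews"))) "" else
                paste0(" (t_mews = ", attr(x, "t_mews"), " h)"),
              nrow(x), dplyr::n_distinct(x$patient_id)))
  NextMethod()
}

#' Write a score series to CSV
#'
#' @param scores An `ews_scores` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(tibble::as_tibble(scores), path)
  invisible(path)
}

#' Read a score series written by [write_scores()]
#'
#' @param path Path to the CSV file.
#' @param variant,t_mews Optional provenance attributes to restore.
#' @return An `ews_scores` tibble.
#' @export
read_scores <- function(path, variant = NULL, t_mews = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- names(empty_scores())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("score file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(tibble::as_tibble(x)[need],
            class = c("ews_scores", class(x)),
            variant = variant, t_mews = t_mews)
}
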