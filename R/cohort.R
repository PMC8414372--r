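#' Vital-sign parameters
#'
#' Names of the physiological parameters a cohort may contain. The first four
#' (systolic blood pressure, heart rate, respiratory rate, temperature) are
#' mandatory for scoring; the Glasgow Coma Score is optional and contributes
#' the consciousness (AVPU) term when present.
#'
#' @return Character vector of parameter codes.
#' @export
vital_parameters <- function() c("SBP", "HR", "RR", "TEMP", "GCS")

#' @rdname vital_parameters
#' @export
mandatory_parameters <- function() c("SBP", "HR", "RR", "TEMP")

#' Default physiological validation bounds
#'
#' Plausibility bounds used when reading or validating a cohort. Values
#' outside these ranges are treated as recording errors, not extreme
#' physiology. The bounds are configurable: pass an edited copy of this
#' tibble to [read_cohort()] or [validate_cohort()].
#'
#' @return A tibble with columns `parameter`, `min`, `max`, `integer`.
#' @export
default_bounds <- function() {
  tibble::tibble(
    parameter = c("SBP", "HR", "RR", "TEMP", "GCS"),
    min = c(20, 0, 0, 25, 3),
    max = c(300, 300, 80, 45, 15),
    integer = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

cohort_columns <- function() {
  c("patient_id", "group", "parameter", "time_h", "value", "t_end_h")
}

#' Construct a cohort from a long-format data frame
#'
#' A cohort is a long-format tibble with one row per vital-sign measurement:
#' `patient_id`, `group` (`"case"` or `"control"`), `parameter` (see
#' [vital_parameters()]), `time_h` (hours since admission), `value`, and
#' `t_end_h` (recording end: event time for cases, discharge for controls).
#' Rows are sorted by patient, parameter and time; sorting is stable so
#' equal timestamps preserve input order.
#'
#' @param x A data frame with the columns above.
#' @param validation `"error"` to fail on invalid rows, `"drop"` to remove
#'   them with a warning.
#' @param bounds Validation bounds, as returned by [default_bounds()].
#' @param duplicates How to treat duplicate (patient, parameter, time) rows:
#'   `"keep_last"` (default, late rows are EHR corrections) or `"keep_all"`.
#' @return An `ews_cohort` tibble.
#' @export
as_cohort <- function(x, validation = c("error", "drop"),
                      bounds = default_bounds(),
                      duplicates = c("keep_last", "keep_all")) {
  validation <- match.arg(validation)
  duplicates <- match.arg(duplicates)
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[cohort_columns()]
  x$patient_id <- as.character(x$patient_id)
  x$group <- as.character(x$group)
  x$parameter <- as.character(x$parameter)

  x <- validate_cohort(x, bounds = bounds, action = validation)

  if (duplicates == "keep_last") {
    dup <- duplicated(x[c("patient_id", "parameter", "time_h")],
                      fromLast = TRUE)
    if (any(dup)) {
      message(sum(dup), " duplicate (patient, parameter, time) row(s); ",
              "keeping the last occurrence")
      x <- x[!dup, ]
    }
  }

  x <- dplyr::arrange(x, .data$patient_id, .data$parameter, .data$time_h)
  new_cohort(x)
}

new_cohort <- function(x, metadata = list()) {
  x <- tibble::as_tibble(x)
  class(x) <- c("ews_cohort", class(x))
  attr(x, "metadata") <- metadata
  x
}

#' Validate cohort rows against schema and physiological bounds
#'
#' @inheritParams as_cohort
#' @param action `"error"` or `"drop"`.
#' @return The validated (possibly filtered) tibble.
#' @export
validate_cohort <- function(x, bounds = default_bounds(),
                            action = c("error", "drop")) {
  action <- match.arg(action)

  bad_group <- !x$group %in% c("case", "control")
  if (any(bad_group)) {
    stop("invalid group label(s): ",
         paste(unique(x$group[bad_group]), collapse = ", "), call. = FALSE)
  }
  bad_param <- !x$parameter %in% vital_parameters()
  if (any(bad_param)) {
    stop("unknown parameter(s): ",
         paste(unique(x$parameter[bad_param]), collapse = ", "), call. = FALSE)
  }
  amb <- dplyr::distinct(x, .data$patient_id, .data$group, .data$t_end_h)
  if (anyDuplicated(amb$patient_id) > 0) {
    stop("patient(s) with inconsistent group/t_end_h: ",
         paste(unique(amb$patient_id[duplicated(amb$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$t_end_h)) || any(x$t_end_h <= 0)) {
    stop("every record needs a positive t_end_h (event time for cases, ",
         "discharge for controls)", call. = FALSE)
  }

  b <- bounds[match(x$parameter, bounds$parameter), ]
  bad <- !is.finite(x$value) | x$value < b$min | x$value > b$max |
    (b$integer & x$value != round(x$value)) |
    !is.finite(x$time_h) | x$time_h < 0 | x$time_h > x$t_end_h
  if (any(bad)) {
    rows <- which(bad)
    desc <- paste0("row ", utils::head(rows, 5), ": ",
                   x$parameter[utils::head(rows, 5)], " = ",
                   x$value[utils::head(rows, 5)], " at t = ",
                   x$time_h[utils::head(rows, 5)], " h",
                   collapse = "; ")
    if (action == "error") {
      stop(sum(bad), " row(s) violate validation bounds (", desc, ")",
           call. = FALSE)
    }
    warning("dropping ", sum(bad), " invalid row(s) (", desc, ")",
            call. = FALSE)
    x <- x[!bad, ]
  }
  x
}

#' Read a cohort from long-format CSV
#'
#' Expects a comma-separated, UTF-8, `.`-decimal file with header columns
#' `patient_id, group, parameter, time_h, value, t_end_h` and one row per
#' measurement.
#'
#' @param path Path to the CSV file.
#' @inheritParams as_cohort
#' @return An `ews_cohort` tibble.
#' @export
read_cohort <- function(path, validation = c("error", "drop"),
                        bounds = default_bounds(),
                        duplicates = c("keep_last", "keep_all")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$time_h <- as.numeric(x$time_h)
  x$value <- as.numeric(x$value)
  x$t_end_h <- as.numeric(x$t_end_h)
  co <- as_cohort(x, validation = validation, bounds = bounds,
                  duplicates = duplicates)
  attr(co, "metadata") <- list(source = path)
  co
}

#' Write a cohort to long-format CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(co, p))` reproduces
#' the cohort exactly (times, values, labels).
#'
#' @param cohort An `ews_cohort` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns() %in% names(cohort)))
  readr::write_csv(tibble::as_tibble(cohort)[cohort_columns()], path)
  invisible(path)
}

#' Screen a cohort for scoreable records
#'
#' A record is scoreable when every mandatory parameter (SBP, HR, RR, TEMP)
#' has at least one measurement; GCS may be absent, in which case the
#' consciousness term is omitted from the score. Non-scoreable records are
#' removed and reported.
#'
#' @param cohort An `ews_cohort` tibble.
#' @return The screened cohort, with an `exclusions` attribute holding a
#'   tibble of `patient_id`, `reason`; retrieve it with [exclusions()].
#' @export
screen_scoreable <- function(cohort) {
  present <- cohort |>
    dplyr::distinct(.data$patient_id, .data$parameter) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      missing = list(setdiff(mandatory_parameters(), .data$parameter)),
      .groups = "drop"
    )
  excl <- present |>
    dplyr::filter(lengths(.data$missing) > 0) |>
    dplyr::mutate(reason = purrr::map_chr(
      .data$missing,
      \(m) paste0("no ", paste(m, collapse = "/"), " measurements")
    )) |>
    dplyr::select("patient_id", "reason")

  out <- dplyr::filter(cohort, !.data$patient_id %in% excl$patient_id)
  out <- new_cohort(out, metadata = attr(cohort, "metadata"))
  attr(out, "exclusions") <- excl
  out
}

#' Exclusion report of a screened or evaluated object
#'
#' @param x An object carrying an `exclusions` attribute, e.g. the result of
#'   [screen_scoreable()].
#' @return A tibble with columns `patient_id`, `reason` (empty if nothing was
#'   excluded).
#' @export
exclusions <- function(x) {
  ex <- attr(x, "exclusions")
  if (is.null(ex)) {
    ex <- tibble::tibble(patient_id = character(), reason = character())
  }
  ex
}

#' Per-patient roster of a cohort
#'
#' One row per patient with its group label and recording end.
#'
#' @param cohort An `ews_cohort` tibble.
#' @return A tibble with columns `patient_id`, `group`, `t_end_h`.
#' @export
cohort_patients <- function(cohort) {
  dplyr::distinct(tibble::as_tibble(cohort),
                  .data$patient_id, .data$group, .data$t_end_h)
}

#' @export
print.ews_cohort <- function(x, ...) {
  pat <- cohort_patients(x)
  cat(sprintf("<ews_cohort> %d patients (%d case, %d control), %d measurements\n",
              nrow(pat), sum(pat$group == "case"),
              sum(pat$group == "control"), nrow(x)))
  NextMethod()
}
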