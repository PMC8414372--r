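#' The MEWS point-assignment table
#'
#' Band definitions mapping each physiological parameter to points in
#' 0--3. The printed clinical table leaves one-unit gaps between integer
#' band labels (e.g. systolic blood pressure 70--71); bands here are made
#' contiguous over the reals by treating the lower-severity band as
#' half-open at its shared edge, so every finite value receives exactly one
#' point assignment:
#'
#' * SBP (mmHg): `<=70` 3, `(70,80]` 2, `(80,100]` 1, `(100,200)` 0, `>=200` 2
#' * HR (bpm): `<=40` 2, `(40,50]` 1, `(50,100]` 0, `(100,110]` 1,
#'   `(110,130)` 2, `>=130` 3
#' * RR (breaths/min): `<9` 2, `[9,15)` 0, `[15,21)` 1, `[21,30)` 2, `>=30` 3
#' * TEMP (deg C): `<35` 2, `[35,38.5)` 0, `>=38.5` 2
#'
#' The consciousness term is scored from the AVPU scale (see
#' [map_gcs_to_avpu()]): Alert 0, Voice 1, Pain 2, Unresponsive 3. The
#' maximum achievable total is therefore 3+3+3+2+3 = 14.
#'
#' Alternative scoring systems can be expressed by editing the returned
#' tibble and passing it wherever a `table` argument is accepted.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`,
#'   `lower_incl`, `upper_incl`, `points`.
#' @export
mews_table <- function() {
  band <- function(parameter, lower, upper, lower_incl, upper_incl, points) {
    tibble::tibble(parameter = parameter, lower = lower, upper = upper,
                   lower_incl = lower_incl, upper_incl = upper_incl,
                   points = as.integer(points))
  }
  dplyr::bind_rows(
    band("SBP", -Inf, 70, FALSE, TRUE, 3),
    band("SBP", 70, 80, FALSE, TRUE, 2),
    band("SBP", 80, 100, FALSE, TRUE, 1),
    band("SBP", 100, 200, FALSE, FALSE, 0),
    band("SBP", 200, Inf, TRUE, FALSE, 2),
    band("HR", -Inf, 40, FALSE, TRUE, 2),
    band("HR", 40, 50, FALSE, TRUE, 1),
    band("HR", 50, 100, FALSE, TRUE, 0),
    band("HR", 100, 110, FALSE, TRUE, 1),
    band("HR", 110, 130, FALSE, FALSE, 2),
    band("HR", 130, Inf, TRUE, FALSE, 3),
    band("RR", -Inf, 9, FALSE, FALSE, 2),
    band("RR", 9, 15, TRUE, FALSE, 0),
    band("RR", 15, 21, TRUE, FALSE, 1),
    band("RR", 21, 30, TRUE, FALSE, 2),
    band("RR", 30, Inf, TRUE, FALSE, 3),
    band("TEMP", -Inf, 35, FALSE, FALSE, 2),
    band("TEMP", 35, 38.5, TRUE, FALSE, 0),
    band("TEMP", 38.5, Inf, TRUE, FALSE, 2)
  )
}

#' Check a scoring table for coverage and overlap
#'
#' Verifies that, per parameter, bands are non-overlapping and jointly cover
#' the whole real line.
#'
#' @param table A scoring table in the format of [mews_table()].
#' @return `table`, invisibly; errors on defects.
#' @export
validate_mews_table <- function(table) {
  for (p in unique(table$parameter)) {
    b <- dplyr::arrange(table[table$parameter == p, ], .data$lower)
    if (!is.infinite(b$lower[1]) || !is.infinite(b$upper[nrow(b)])) {
      stop("bands for ", p, " do not span the real line", call. = FALSE)
    }
    if (nrow(b) > 1) {
      lo <- b$lower[-1]; hi <- b$upper[-nrow(b)]
      ok <- lo == hi & (b$lower_incl[-1] != b$upper_incl[-nrow(b)])
      if (!all(ok)) {
        stop("bands for ", p, " overlap or leave gaps", call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' Map Glasgow Coma Score to the AVPU consciousness scale
#'
#' One-to-one correspondence used for the consciousness term:
#' Alert = GCS 14--15; reacting to Voice = GCS 10--13; reacting to Pain =
#' GCS 4--9; Unresponsive = GCS 3.
#'
#' @param gcs Integer vector in 3--15 (NA allowed, propagated).
#' @return Factor with levels `Alert`, `Voice`, `Pain`, `Unresponsive`.
#' @export
map_gcs_to_avpu <- function(gcs) {
  bad <- !is.na(gcs) & (gcs < 3 | gcs > 15 | gcs != round(gcs))
  if (any(bad)) {
    stop("GCS must be an integer in [3, 15]; got ",
         paste(unique(gcs[bad]), collapse = ", "), call. = FALSE)
  }
  lev <- c("Alert", "Voice", "Pain", "Unresponsive")
  idx <- dplyr::case_when(
    is.na(gcs) ~ NA_integer_,
    gcs >= 14 ~ 1L,
    gcs >= 10 ~ 2L,
    gcs >= 4 ~ 3L,
    TRUE ~ 4L
  )
  factor(lev[idx], levels = lev)
}

#' Points contributed by an AVPU level
#'
#' @param avpu Factor or character vector of AVPU levels.
#' @return Integer points 0--3 (NA propagated).
#' @export
avpu_points <- function(avpu) {
  pts <- c(Alert = 0L, Voice = 1L, Pain = 2L, Unresponsive = 3L)
  unname(pts[as.character(avpu)])
}

#' Points for one parameter value
#'
#' Vectorized band lookup in a scoring table. GCS values are first mapped
#' to AVPU.
#'
#' @param parameter Character vector of parameter codes ("SBP", "HR", "RR",
#'   "TEMP", "GCS").
#' @param value Numeric vector of the same length.
#' @param table Scoring table, defaulting to [mews_table()].
#' @return Integer points in 0--3; NA values yield NA points.
#' @export
subscore <- function(parameter, value, table = mews_table()) {
  stopifnot(length(parameter) == length(value))
  if (any(!is.na(value) & !is.finite(value))) {
    stop("non-finite physiological value", call. = FALSE)
  }
  pts <- rep(NA_integer_, length(value))
  gcs <- parameter == "GCS"
  if (any(gcs)) pts[gcs] <- avpu_points(map_gcs_to_avpu(value[gcs]))
  for (i in seq_len(nrow(table))) {
    b <- table[i, ]
    hit <- !gcs & parameter == b$parameter & !is.na(value) &
      (value > b$lower | (b$lower_incl & value == b$lower)) &
      (value < b$upper | (b$upper_incl & value == b$upper))
    pts[hit] <- b$points
  }
  unknown <- !gcs & !parameter %in% table$parameter
  if (any(unknown)) {
    stop("no scoring bands for parameter(s): ",
         paste(unique(parameter[unknown]), collapse = ", "), call. = FALSE)
  }
  pts
}

#' Total MEWS from one set of parameter values
#'
#' Sums the per-parameter point assignments. SBP, HR, RR and TEMP are
#' mandatory; GCS is optional and, when absent, the consciousness term is
#' omitted (capping the total at 11 instead of 14).
#'
#' @param sbp,hr,rr,temp Numeric vectors (recycled to a common length).
#' @param gcs Optional integer vector (NA = not recorded).
#' @param table Scoring table.
#' @return A tibble with per-parameter point columns (`SBP_pts`, `HR_pts`,
#'   `RR_pts`, `TEMP_pts`, `AVPU_pts`) and `total`.
#' @export
compute_mews <- function(sbp, hr, rr, temp, gcs = NA, table = mews_table()) {
  n <- max(lengths(list(sbp, hr, rr, temp, gcs)))
  v <- tibble::tibble(
    sbp = rep_len(sbp, n), hr = rep_len(hr, n), rr = rep_len(rr, n),
    temp = rep_len(temp, n), gcs = rep_len(gcs, n)
  )
  if (any(is.na(v$sbp) | is.na(v$hr) | is.na(v$rr) | is.na(v$temp))) {
    stop("SBP, HR, RR and TEMP are mandatory for a MEWS total", call. = FALSE)
  }
  out <- tibble::tibble(
    SBP_pts = subscore(rep("SBP", n), v$sbp, table),
    HR_pts = subscore(rep("HR", n), v$hr, table),
    RR_pts = subscore(rep("RR", n), v$rr, table),
    TEMP_pts = subscore(rep("TEMP", n), v$temp, table),
    AVPU_pts = subscore(rep("GCS", n), v$gcs, table)
  )
  out$total <- rowSums(out[1:4]) +
    ifelse(is.na(out$AVPU_pts), 0L, out$AVPU_pts)
  out$total <- as.integer(out$total)
  out
}
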