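#' Evaluation configuration
#'
#' Bundles every parameter of an alarm evaluation run:
#'
#' @param k Integer alarm threshold in 0--13; an alarm is raised whenever
#'   the total score strictly exceeds `k`. The default 4 is the threshold
#'   commonly used in clinical practice.
#' @param tau Prediction horizon length in hours (default 12, a typical
#'   ICU nursing shift): alarms within the window
#'   `[t_event - tau0 - tau, t_event - tau0]` count as true (actionable)
#'   alarms.
#' @param tau0 Lead time in hours (default 0): the interval
#'   `(t_event - tau0, t_event)` reserved for intervention; alarms there
#'   are "late" and count as false.
#' @param t_mews Interval length in hours for the interval score variants,
#'   or `NULL` for the event-driven variant.
#' @param statistic `"median"`, `"worst"` or `NULL` (event-driven variant).
#' @param m Number of bootstrap windows per control patient (default 1000).
#' @param seed RNG seed for the bootstrap (`NULL` = use the current RNG
#'   state).
#' @return An `ews_config` list.
#' @export
eval_config <- function(k = 4, tau = 12, tau0 = 0, t_mews = NULL,
                        statistic = NULL, m = 1000, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 0 || k > 13) {
    stop("k must be an integer in [0, 13]", call. = FALSE)
  }
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (!is.numeric(tau0) || tau0 < 0) stop("tau0 must be >= 0", call. = FALSE)
  if (!is.numeric(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  if (!is.null(statistic)) statistic <- match.arg(statistic, c("median", "worst"))
  if (!is.null(statistic) && is.null(t_mews)) {
    stop("statistic = '", statistic, "' requires t_mews", call. = FALSE)
  }
  if (!is.null(t_mews) && (!is.numeric(t_mews) || t_mews <= 0)) {
    stop("t_mews must be > 0", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), tau = as.numeric(tau), tau0 = as.numeric(tau0),
         t_mews = t_mews, statistic = statistic, m = as.integer(m),
         seed = seed),
    class = "ews_config"
  )
}

#' @export
print.ews_config <- function(x, ...) {
  cat("<ews_config>\n")
  cat(sprintf("  threshold k       : %d (alarm when total > k)\n", x$k))
  cat(sprintf("  horizon tau       : %g h\n", x$tau))
  cat(sprintf("  lead time tau0    : %g h\n", x$tau0))
  cat(sprintf("  score variant     : %s\n",
              if (is.null(x$statistic)) "base (event-driven)" else
                sprintf("%s over t_mews = %g h", x$statistic, x$t_mews)))
  cat(sprintf("  bootstrap windows : %d%s\n", x$m,
              if (is.null(x$seed)) "" else sprintf(" (seed %s)", x$seed)))
  invisible(x)
}

config_variant <- function(config) {
  if (is.null(config$statistic)) "base" else config$statistic
}
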