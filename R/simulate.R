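#' Specification for a synthetic vital-sign cohort
#'
#' Describes the study conditions a simulated cohort emulates: right-skewed
#' ICU length-of-stay distributions (log-normal, moment-matched to a
#' median of 86.3 h with IQR 245.9 h for cases and 160.9 h with IQR
#' 193.2 h for controls), irregular per-parameter Poisson sampling at
#' group-specific mean rates (cases are measured roughly 2.5 times more
#' often than controls), stationary baseline physiology centred in the
#' zero-point scoring bands, and -- for cases -- a plantable pre-event
#' deterioration: a piecewise-linear drift of every parameter toward an
#' abnormal target over a window positioned relative to the event time,
#' with additive Gaussian noise throughout.
#'
#' @param n_case,n_control Number of case / control patients.
#' @param los Per-group length-of-stay targets: list with `case` and
#'   `control`, each `list(median_h=, iqr_h=)`.
#' @param sampling_rates Tibble `parameter`, `case`, `control` of mean
#'   measurements per hour.
#' @param baseline Tibble `parameter`, `mean`, `sd`, `between_sd` of the
#'   stationary distribution: each patient draws a persistent offset from
#'   `N(0, between_sd)` (between-patient heterogeneity -- some ICU
#'   patients run chronically low blood pressure or reduced
#'   consciousness, giving controls a realistic nonzero alarm base rate)
#'   and fluctuates around it with SD `sd` (GCS is rounded to an
#'   integer).
#' @param targets Named vector of abnormal values each parameter drifts
#'   toward during deterioration.
#' @param det_start_h,det_end_h Deterioration window, in hours *before*
#'   the event: drift is active on `[t_event - det_start_h,
#'   t_event - det_end_h]`. Values revert to baseline after the window
#'   ends (relevant when `det_end_h > 0`).
#' @param ramp_frac Fraction of the window spent ramping linearly from
#'   baseline to target (the remainder holds the target).
#' @param magnitude Deterioration strength in `[0, 1]`; 0 disables the
#'   drift (cases become distributionally identical to controls apart from
#'   stay length).
#' @param noise_sd Named vector of additive Gaussian noise SDs during
#'   deterioration.
#' @param dropout Named vector of whole-record dropout probabilities per
#'   parameter (a dropped parameter has no measurements in that record).
#' @param min_stay_h Minimum stay length; shorter draws are resampled.
#' @param ar1 Lag-1 autocorrelation of baseline fluctuations (0 = i.i.d.
#'   draws; nonzero only for robustness experiments).
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return An `ews_genspec` list.
#' @export
generator_spec <- function(
    n_case = 50, n_control = 50,
    los = list(case = list(median_h = 86.3, iqr_h = 245.9),
               control = list(median_h = 160.9, iqr_h = 193.2)),
    sampling_rates = tibble::tibble(
      parameter = c("GCS", "TEMP", "SBP", "RR", "HR"),
      case = c(0.3, 1, 1.2, 2, 2.2),
      control = c(0.1, 0.4, 0.5, 0.7, 0.8)
    ),
    baseline = tibble::tibble(
      parameter = c("SBP", "HR", "RR", "TEMP", "GCS"),
      mean = c(120, 75, 12, 36.8, 15),
      sd = c(10, 8, 1.5, 0.3, 0.5),
      between_sd = c(15, 12, 2.5, 0.4, 1.5)
    ),
    targets = c(SBP = 65, HR = 135, RR = 32, TEMP = 38.8, GCS = 3),
    det_start_h = 10, det_end_h = 0, ramp_frac = 0.3, magnitude = 1,
    noise_sd = c(SBP = 5, HR = 4, RR = 1, TEMP = 0.2, GCS = 0),
    dropout = c(SBP = 0, HR = 0, RR = 0, TEMP = 0, GCS = 0.1),
    min_stay_h = 0.5, ar1 = 0, seed = NULL) {
  stopifnot(n_case >= 0, n_control >= 0, n_case + n_control > 0)
  # partial named vectors override the defaults entry-wise
  merge_named <- function(user, default) {
    unknown <- setdiff(names(user), names(default))
    if (length(unknown) > 0) {
      stop("unknown parameter(s) ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    default[names(user)] <- user
    default
  }
  defaults <- formals()
  targets <- merge_named(targets, eval(defaults$targets))
  noise_sd <- merge_named(noise_sd, eval(defaults$noise_sd))
  dropout <- merge_named(dropout, eval(defaults$dropout))
  if (any(c(sampling_rates$case, sampling_rates$control) <= 0)) {
    stop("sampling rates must be > 0", call. = FALSE)
  }
  if (det_start_h < det_end_h || det_end_h < 0) {
    stop("need det_start_h >= det_end_h >= 0", call. = FALSE)
  }
  if (magnitude < 0 || magnitude > 1) {
    stop("magnitude must be in [0, 1]", call. = FALSE)
  }
  if (any(dropout < 0 | dropout > 1)) {
    stop("dropout probabilities must be in [0, 1]", call. = FALSE)
  }
  if (ramp_frac < 0 || ramp_frac > 1) {
    stop("ramp_frac must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_case = n_case, n_control = n_control, los = los,
         sampling_rates = sampling_rates, baseline = baseline,
         targets = targets, det_start_h = det_start_h,
         det_end_h = det_end_h, ramp_frac = ramp_frac,
         magnitude = magnitude, noise_sd = noise_sd, dropout = dropout,
         min_stay_h = min_stay_h, ar1 = ar1, seed = seed),
    class = "ews_genspec"
  )
}

#' Log-normal parameters matching a printed median and IQR
#'
#' The median fixes `meanlog = log(median)`; the IQR fixes `sdlog` through
#' `median * (exp(q75 * sdlog) - exp(-q75 * sdlog)) = IQR` with
#' `q75 = qnorm(0.75)`, solved numerically.
#'
#' @param median_h,iqr_h Target median and interquartile range.
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_from_median_iqr <- function(median_h, iqr_h) {
  stopifnot(median_h > 0, iqr_h > 0)
  q <- stats::qnorm(0.75)
  f <- function(s) median_h * (exp(q * s) - exp(-q * s)) - iqr_h
  sdlog <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  list(meanlog = log(median_h), sdlog = sdlog)
}

ar1_noise <- function(n, rho) {
  z <- stats::rnorm(n)
  if (rho == 0 || n < 2) return(z)
  e <- numeric(n)
  e[1] <- z[1]
  for (i in 2:n) e[i] <- rho * e[i - 1] + sqrt(1 - rho^2) * z[i]
  e
}

simulate_patient <- function(id, group, spec, los_par) {
  stay <- 0
  for (try in 1:50) {
    stay <- stats::rlnorm(1, los_par$meanlog, los_par$sdlog)
    if (stay >= spec$min_stay_h) break
  }
  stay <- max(stay, spec$min_stay_h)

  rows <- list()
  for (p in spec$sampling_rates$parameter) {
    if (stats::runif(1) < spec$dropout[[p]]) next
    rate <- spec$sampling_rates[[group]][spec$sampling_rates$parameter == p]
    n <- stats::rpois(1, rate * stay)
    if (n == 0) next
    t <- sort(stats::runif(n, 0, stay))
    b <- spec$baseline[spec$baseline$parameter == p, ]
    between <- if ("between_sd" %in% names(b)) b$between_sd else 0
    mu_p <- b$mean + between * stats::rnorm(1)
    v <- mu_p + b$sd * ar1_noise(n, spec$ar1)

    if (group == "case" && spec$magnitude > 0) {
      win_lo <- max(0, stay - spec$det_start_h)
      win_hi <- max(0, stay - spec$det_end_h)
      if (win_hi > win_lo) {
        ramp_end <- win_lo + spec$ramp_frac * (win_hi - win_lo)
        f <- rep(0, n)
        inside <- t >= win_lo & t <= win_hi
        f[inside] <- ifelse(t[inside] < ramp_end & ramp_end > win_lo,
                            (t[inside] - win_lo) / (ramp_end - win_lo), 1)
        f <- f * spec$magnitude
        v <- (1 - f) * v + f * spec$targets[[p]] +
          ifelse(f > 0, stats::rnorm(n, 0, spec$noise_sd[[p]]), 0)
      }
    }
    bounds <- default_bounds()
    bd <- bounds[bounds$parameter == p, ]
    v <- pmin(pmax(v, bd$min), bd$max)
    if (p == "GCS") v <- round(v)
    rows[[p]] <- tibble::tibble(
      patient_id = id, group = group, parameter = p, time_h = t,
      value = v, t_end_h = stay
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort of case and control patients per a [generator_spec()].
#' Identical `spec` and `seed` produce identical cohorts.
#'
#' @param spec An `ews_genspec`.
#' @param seed RNG seed; defaults to `spec$seed` (`NULL` = current RNG
#'   state).
#' @return An `ews_cohort` tibble with generation metadata (seed, spec
#'   hash) attached.
#' @export
simulate_cohort <- function(spec = generator_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "ews_genspec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lp_case <- lognormal_from_median_iqr(spec$los$case$median_h,
                                       spec$los$case$iqr_h)
  lp_ctrl <- lognormal_from_median_iqr(spec$los$control$median_h,
                                       spec$los$control$iqr_h)
  ids_case <- sprintf("case_%03d", seq_len(spec$n_case))
  ids_ctrl <- sprintf("ctrl_%03d", seq_len(spec$n_control))
  rows <- c(
    purrr::map(ids_case, \(id) simulate_patient(id, "case", spec, lp_case)),
    purrr::map(ids_ctrl, \(id) simulate_patient(id, "control", spec, lp_ctrl))
  )
  x <- dplyr::bind_rows(rows)
  new_cohort(
    dplyr::arrange(x, .data$patient_id, .data$parameter, .data$time_h),
    metadata = list(source = "synthetic", seed = seed,
                    spec_hash = rlang::hash(spec))
  )
}

#' Position the planted deterioration relative to the prediction horizon
#'
#' Returns a copy of `spec` whose case deterioration window lies strictly
#' inside the prediction horizon `[t_event - tau0 - tau, t_event - tau0]`
#' (`placement = "inside_horizon"`) or strictly before it
#' (`"before_horizon"`), for sensitivity-recovery experiments. The minimum
#' stay is raised so every case can contain the window.
#'
#' @param spec An `ews_genspec`.
#' @param config An [eval_config()] supplying `tau` and `tau0`.
#' @param placement `"inside_horizon"` or `"before_horizon"`.
#' @param margin_h Gap, in hours, kept between the deterioration window
#'   and the horizon edges (and, for `"before_horizon"`, time for fresh
#'   baseline measurements to displace carried-forward abnormal values
#'   before the horizon opens).
#' @return A modified `ews_genspec`.
#' @export
plant_window_signal <- function(spec, config,
                                placement = c("inside_horizon",
                                              "before_horizon"),
                                margin_h = 2) {
  placement <- match.arg(placement)
  stopifnot(inherits(spec, "ews_genspec"))
  if (config$tau <= 2 * margin_h) {
    stop("tau too short to place a window strictly inside the horizon",
         call. = FALSE)
  }
  if (placement == "inside_horizon") {
    spec$det_start_h <- config$tau0 + config$tau - margin_h
    spec$det_end_h <- config$tau0 + margin_h
  } else {
    # leave enough room after the drift for every parameter -- including
    # the most sparsely sampled one -- to be remeasured at baseline, so
    # carried-forward abnormal values have decayed before the horizon opens
    refresh_gap <- max(margin_h, 3 / min(spec$sampling_rates$case))
    spec$det_end_h <- config$tau0 + config$tau + refresh_gap
    spec$det_start_h <- spec$det_end_h + 0.8 * config$tau
  }
  spec$min_stay_h <- max(spec$min_stay_h, spec$det_start_h + 1)
  lp <- lognormal_from_median_iqr(spec$los$case$median_h,
                                  spec$los$case$iqr_h)
  if (stats::plnorm(spec$min_stay_h, lp$meanlog, lp$sdlog) > 0.99) {
    stop("tau + tau0 exceeds virtually every case stay under the ",
         "length-of-stay distribution", call. = FALSE)
  }
  spec
}
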