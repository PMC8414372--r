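test_that("time-dependent sensitivity counts on-time-predicted events", {
  co <- roster(sprintf("c%d", 1:4), "case", rep(100, 4))
  cfg <- eval_config(k = 4, tau = 12, tau0 = 0)
  # two cases alarm inside the horizon, one too early, one never
  s <- dplyr::bind_rows(
    make_scores("c1", 95, 9),
    make_scores("c2", 90, 7),
    make_scores("c3", 20, 9),
    make_scores("c4", 95, 2)
  )
  res <- time_dependent_sensitivity(co, s, cfg)
  expect_equal(res$s, 0.5)
  expect_equal(res$n_predicted, 2L)
  expect_equal(res$n_events, 4L)
})

test_that("cases shorter than tau + tau0 are excluded from sensitivity", {
  co <- roster(c("c1", "c2"), "case", c(10, 100))
  cfg <- eval_config(k = 4, tau = 12, tau0 = 1)
  s <- dplyr::bind_rows(make_scores("c1", 5, 9), make_scores("c2", 90, 9))
  res <- time_dependent_sensitivity(co, s, cfg)
  expect_equal(res$n_events, 1L)
  expect_equal(res$n_excluded, 1L)
  expect_equal(attr(res, "exclusions")$patient_id, "c1")
  keep <- time_dependent_sensitivity(co, s, cfg, exclude_short_stays = FALSE)
  expect_equal(keep$n_events, 2L)
})

test_that("a lead time pushing the window before all alarms zeroes S", {
  co <- roster("c1", "case", 100)
  s <- make_scores("c1", c(95, 98), c(9, 9))
  cfg0 <- eval_config(k = 4, tau = 10, tau0 = 0)
  expect_equal(time_dependent_sensitivity(co, s, cfg0)$s, 1)
  cfg_late <- eval_config(k = 4, tau = 10, tau0 = 20)
  expect_equal(time_dependent_sensitivity(co, s, cfg_late,
                                          exclude_short_stays = FALSE)$s, 0)
})

test_that("whole-stay horizon sensitivity equals patient-level TPR", {
  withr::with_seed(57, {
    for (rep in 1:10) {
      co <- random_cohort(n_case = 4, n_control = 2)
      s <- score_cohort(co, "base")
      tau <- max(cohort_patients(co)$t_end_h) + 1
      cfg <- eval_config(k = 4, tau = tau, tau0 = 0, m = 10)
      sens <- time_dependent_sensitivity(co, s, cfg,
                                         exclude_short_stays = FALSE)
      cc <- confusion_metrics(patient_confusion(co, s, 4))
      expect_identical(sens$s, cc$tpr)
    }
  })
})

make_control_cohort <- function(t_ends) {
  roster(sprintf("k%d", seq_along(t_ends)), "control", t_ends)
}

test_that("bootstrap FPR handles the degenerate alarm patterns", {
  co <- make_control_cohort(c(48, 48))
  cfg <- eval_config(k = 4, tau = 12, m = 50, seed = 5)
  silent <- dplyr::bind_rows(make_scores("k1", seq(1, 47, 2), 0),
                             make_scores("k2", seq(1, 47, 2), 0))
  b0 <- bootstrap_fpr(co, silent, cfg)
  expect_equal(b0$mean, 0)
  expect_equal(b0$std, 0)
  # alarms everywhere, densely sampled
  dense <- dplyr::bind_rows(make_scores("k1", seq(0, 48, 0.5), 9),
                            make_scores("k2", seq(0, 48, 0.5), 9))
  b1 <- bootstrap_fpr(co, dense, cfg)
  expect_equal(b1$mean, 1)
  # controls shorter than tau are excluded
  co2 <- make_control_cohort(c(48, 5))
  b2 <- bootstrap_fpr(co2, silent, cfg)
  expect_equal(b2$n_controls, 1)
  expect_equal(attr(b2, "exclusions")$patient_id, "k2")
})

test_that("bootstrap FPR converges to the exact window-hit probability", {
  # five controls with hand-placed alarm patterns; oracle integrates the
  # alarm indicator over all window positions
  specs <- list(
    list(t_end = 60, alarms = c(3, 10, 40)),
    list(t_end = 100, alarms = c(50)),
    list(t_end = 80, alarms = c(5, 6, 7, 70)),
    list(t_end = 50, alarms = numeric(0)),
    list(t_end = 120, alarms = seq(10, 110, 25))
  )
  tau <- 5
  co <- make_control_cohort(vapply(specs, `[[`, numeric(1), "t_end"))
  s <- dplyr::bind_rows(purrr::imap(specs, function(sp, i) {
    times <- c(sp$alarms, sp$t_end - 0.5)
    totals <- c(rep(9, length(sp$alarms)), 0)
    make_scores(sprintf("k%d", i), times, totals)
  }))
  m <- 2000
  cfg <- eval_config(k = 4, tau = tau, m = m, seed = 77)
  b <- bootstrap_fpr(co, s, cfg)
  p_exact <- vapply(specs, function(sp) {
    window_hit_probability(sp$alarms, sp$t_end, tau)
  }, numeric(1))
  mc_se <- sqrt(sum(p_exact * (1 - p_exact) / m)) / length(specs)
  expect_lt(abs(b$mean - mean(p_exact)), 3 * mc_se + 1e-9)
  # per-control means converge too
  for (i in seq_along(specs)) {
    se_i <- sqrt(p_exact[i] * (1 - p_exact[i]) / m)
    expect_lt(abs(b$per_control$mu_i[i] - p_exact[i]), 3 * se_i + 1e-9)
  }
})

test_that("bootstrap results are reproducible from the seed", {
  withr::with_seed(3, {
    co <- random_cohort(n_case = 0, n_control = 5, t_end_max = 60)
  })
  s <- score_cohort(co, "base")
  cfg <- eval_config(k = 2, tau = 4, m = 100, seed = 123)
  b1 <- bootstrap_fpr(co, s, cfg)
  b2 <- bootstrap_fpr(co, s, cfg)
  expect_identical(b1$trigger_matrix, b2$trigger_matrix)
  expect_identical(b1$mean, b2$mean)
  expect_identical(b1$std, b2$std)
})

test_that("the literal variance composition differs but the mean does not", {
  withr::with_seed(9, {
    co <- random_cohort(n_case = 0, n_control = 6, t_end_max = 60)
  })
  s <- score_cohort(co, "base")
  cfg <- eval_config(k = 1, tau = 6, m = 50, seed = 31)
  bp <- bootstrap_fpr(co, s, cfg, variance = "proportion")
  bl <- bootstrap_fpr(co, s, cfg, variance = "literal")
  expect_identical(bp$mean, bl$mean)
  expect_true(bp$std >= 0)
  # the printed composition subtracts a count from a binary indicator,
  # so once any window triggers more than one control it inflates
  if (any(bp$per_window_counts > 1)) expect_gt(bl$std, bp$std)
})

test_that("derived bootstrap metrics follow the replicate construction", {
  co <- make_control_cohort(c(48, 48, 48))
  cfg <- eval_config(k = 4, tau = 12, m = 40, seed = 8)
  silent <- dplyr::bind_rows(purrr::map(1:3, function(i) {
    make_scores(sprintf("k%d", i), seq(1, 47, 2), 0)
  }))
  b <- bootstrap_fpr(co, silent, cfg)
  pm <- bootstrap_metrics(b, n_predicted = 4, n_events = 5)
  expect_equal(pm$mean[pm$metric == "fpr"], 0)
  expect_equal(pm$mean[pm$metric == "ppv"], 1)
  # independent recomputation from the trigger matrix
  trig <- b$trigger_matrix
  fp_j <- colSums(trig)
  acc_j <- (4 + (3 - fp_j)) / (5 + 3)
  expect_equal(pm$mean[pm$metric == "acc"], mean(acc_j))
  # single replicate: stds are zero by convention
  cfg1 <- eval_config(k = 4, tau = 12, m = 1, seed = 8)
  b1 <- bootstrap_fpr(co, silent, cfg1)
  pm1 <- bootstrap_metrics(b1, n_predicted = 4, n_events = 5)
  expect_true(all(pm1$std == 0))
})

test_that("WDR composes the per-control bootstrap moments", {
  co <- make_control_cohort(c(60, 60))
  cfg <- eval_config(k = 4, tau = 10, m = 200, seed = 21)
  silent <- dplyr::bind_rows(make_scores("k1", seq(1, 59, 2), 0),
                             make_scores("k2", seq(1, 59, 2), 0))
  b <- bootstrap_fpr(co, silent, cfg)
  w <- wdr(10, b)
  expect_equal(w$mean, 1)  # no false positives anywhere
  expect_equal(w$std, 0)

  withr::with_seed(15, {
    co2 <- random_cohort(n_case = 0, n_control = 8, t_end_max = 80)
  })
  s2 <- score_cohort(co2, "base")
  b2 <- bootstrap_fpr(co2, s2, eval_config(k = 1, tau = 8, m = 100, seed = 4))
  w2 <- wdr(6, b2)
  expect_equal(w2$mean, (6 + sum(b2$per_control$mu_i)) / 6)
  expect_equal(w2$std, sqrt(sum(b2$per_control$sigma_i^2)) / 6)
  expect_true(wdr(0, b2)$undefined)
})

test_that("burden rates and proportions follow their formulas", {
  # control: 6 alarms in 24 h, 48 score samples
  co <- roster("k1", "control", 24)
  totals <- rep(0L, 48); totals[seq(1, 48, 8)] <- 9L
  s <- make_scores("k1", seq(0.5, 24, by = 0.5), totals)
  cfg <- eval_config(k = 4, tau = 12, tau0 = 0)
  b <- alarm_burden(co, s, cfg)
  expect_equal(b$r, 0.25)
  expect_equal(b$rho, 0.125)
  expect_equal(b$r0, 0.25)   # all control alarms are false
  expect_equal(b$rho0, 0.125)

  # case: T = 36 h, tau = 12, alarms outside the horizon are false
  co2 <- roster("c1", "case", 36)
  s2 <- make_scores("c1", c(2, 5, 8, 11, 30), c(9, 9, 9, 9, 9))
  b2 <- alarm_burden(co2, s2, cfg)
  expect_equal(b2$n_false, 4L)  # the alarm at t = 30 is on time
  expect_equal(b2$r0, 4 / 24)
  expect_equal(b2$n_alarms, 5L)

  # with tau = tau0 = 0 every alarm is false: r0 = r and rho0 = rho
  cfg0 <- eval_config(k = 4, tau = 0, tau0 = 0)
  b3 <- alarm_burden(co2, s2, cfg0)
  expect_equal(b3$r0, b3$r)
  expect_equal(b3$rho0, b3$rho)

  # a case recording not exceeding tau has no r0 denominator
  co3 <- roster("c2", "case", 10)
  s3 <- make_scores("c2", 5, 9)
  b4 <- alarm_burden(co3, s3, cfg)
  expect_true(b4$r0_undefined)
  expect_true(is.nan(b4$r0))
})

test_that("time profiles pool, normalize and count missed events", {
  co <- roster(c("c1", "c2"), "case", c(100, 100))
  cfg <- eval_config(k = 4, tau = 12, tau0 = 1)
  # c1: 3 early + 1 on-time; c2: nothing on time
  s <- dplyr::bind_rows(
    make_scores("c1", c(10, 20, 30, 90), rep(9, 4)),
    make_scores("c2", 50, 9)
  )
  al <- classify_alarms(generate_alarms(s, 4), co, cfg)
  tp <- time_profiles(al, co)
  expect_equal(tp$count[tp$class == "early"], 4L)
  expect_equal(tp$count[tp$class == "on_time"], 1L)
  expect_equal(tp$count[tp$class == "missed_event"], 1L)
  pa <- tp$per_alarm[tp$class %in% c("early", "on_time", "late")]
  expect_equal(sum(pa), 1)
  expect_equal(pa, c(0.8, 0.2, 0))
  # per-event profile times the number of events recovers raw counts
  n_events <- 2
  expect_equal(tp$per_event * n_events, as.numeric(tp$count))

  # single case, 3 early + 1 on-time
  co1 <- roster("c1", "case", 100)
  al1 <- classify_alarms(
    generate_alarms(make_scores("c1", c(10, 20, 30, 90), rep(9, 4)), 4),
    co1, cfg)
  tp1 <- time_profiles(al1, co1)
  expect_equal(tp1$per_alarm[tp1$class %in% c("early", "on_time", "late")],
               c(0.75, 0.25, 0))
})

test_that("S and all burden measures decay monotonically in k", {
  co <- simulate_cohort(generator_spec(n_case = 15, n_control = 15,
                                       seed = 19))
  s <- score_cohort(screen_scoreable(co), "base")
  svals <- rvals <- rhovals <- r0vals <- rho0vals <- numeric(14)
  for (k in 0:13) {
    cfg <- eval_config(k = k, tau = 12, tau0 = 0, m = 10, seed = 1)
    svals[k + 1] <- time_dependent_sensitivity(co, s, cfg)$s
    b <- alarm_burden(co, s, cfg)
    rvals[k + 1] <- mean(b$r)
    rhovals[k + 1] <- mean(b$rho)
    r0vals[k + 1] <- mean(b$r0[is.finite(b$r0)])
    rho0vals[k + 1] <- mean(b$rho0)
  }
  for (v in list(svals, rvals, rhovals, r0vals, rho0vals)) {
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("relative change utilities agree with direct arithmetic", {
  expect_equal(relative_change(0.09, 0.23), (0.23 - 0.09) / 0.09)
  expect_equal(relative_reduction(10.7, 5.3), (10.7 - 5.3) / 10.7)
  expect_equal(relative_reduction(100, 100), 0)
})
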